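#' Monte Carlo null model of randomly scattered mutations
#'
#' Under the null, mutations are placed uniformly over the concatenated
#' genome with no regard to sequence context. The null distribution of
#' intermutational distances validates the distal ("singlet") IMD group, and
#' the frequency with which random scatter produces a called cluster bounds
#' the false-positive probability of cluster calls.
#'
#' @name null_model
NULL

# distinct uniform positions over the concatenated genome, mapped to
# (chrom, pos); cum = c(0, cumsum(lengths))
draw_positions <- function(genome, n) {
  L <- genome$total_length
  if (n > L) stop("more mutations requested than genome positions")
  # distinct by construction; hashing avoids materializing 1..L
  g <- if (n <= L / 2) sample.int(L, n, useHash = TRUE) else sample.int(L, n)
  cum <- c(0, cumsum(genome$chroms$length))
  ci <- findInterval(g - 1, cum, rightmost.closed = FALSE)  # 1..nchrom
  data.frame(chrom = genome$chroms$name[ci],
             pos = as.integer(g - cum[ci]))
}

#' Simulate a catalog of uniformly scattered mutations
#'
#' Positions are distinct uniform draws over the concatenated genome, so a
#' chromosome receives mutations in proportion to its length. When the
#' genome carries sequence, `ref` is the genome base and `alt` its
#' transition partner; otherwise a placeholder C>T is recorded.
#'
#' @param genome a [genome_model()].
#' @param n_mutations number of mutations (>= 0).
#' @param clone_id clone label for the simulated genome.
#' @param seed optional integer seed.
#' @return a [mutation_catalog()].
#' @export
simulate_random_catalog <- function(genome, n_mutations, clone_id = "sim",
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_mutations < 0) stop("n_mutations must be >= 0")
  if (n_mutations == 0L) {
    return(mutation_catalog(
      data.frame(clone = character(0), chrom = character(0),
                 pos = integer(0), ref = character(0), alt = character(0)),
      genome = genome, provenance = "null simulation"))
  }
  dp <- draw_positions(genome, n_mutations)
  if (!is.null(genome$sequence)) {
    ref <- genome_base(genome, dp$chrom, dp$pos)
    alt <- chartr("ACGT", "GTAC", ref)   # transition partner
  } else {
    ref <- rep("C", n_mutations)
    alt <- rep("T", n_mutations)
  }
  mutation_catalog(data.frame(clone = clone_id, chrom = dp$chrom,
                              pos = dp$pos, ref = ref, alt = alt),
                   genome = genome, provenance = "null simulation")
}

# batch of n_reps independent clones in one catalog; placeholder alleles
simulate_null_batch <- function(genome, n_mutations, n_reps,
                                clone_prefix = "null") {
  parts <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    dp <- draw_positions(genome, n_mutations)
    dp$clone <- sprintf("%s%06d", clone_prefix, r)
    parts[[r]] <- dp
  }
  df <- do.call(rbind, parts)
  df$ref <- "C"
  df$alt <- "T"
  mutation_catalog(df[c("clone", "chrom", "pos", "ref", "alt")],
                   genome = genome, provenance = "null batch")
}

#' Null distribution of intermutational distances
#'
#' Pools the IMDs of `n_reps` independent simulated clones, each with
#' `n_mutations` uniformly scattered mutations. In the sparse limit the
#' spacing distribution approaches an exponential with rate
#' `n_mutations / total_length`.
#'
#' @param genome a [genome_model()].
#' @param n_mutations mutations per simulated clone.
#' @param n_reps number of replicate clones (>= 1).
#' @param seed integer seed.
#' @return a list: `imds` (pooled vector), `quantiles`, and the parameters.
#'   Compare to an observed IMD set with [stats::ks.test()].
#' @export
imd_null_distribution <- function(genome, n_mutations, n_reps = 100,
                                  seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cat_all <- simulate_null_batch(genome, n_mutations, n_reps)
  imds <- compute_imds(cat_all)$entries$imd
  list(imds = imds,
       quantiles = stats::quantile(imds, c(0.01, 0.25, 0.5, 0.75, 0.99)),
       mean = mean(imds),
       params = list(n_mutations = n_mutations, n_reps = n_reps,
                     total_length = genome$total_length))
}

#' Estimate the probability that random scatter yields a cluster call
#'
#' Simulates clones of uniformly scattered mutations and runs the same
#' [call_clusters()] code path used on real catalogs, reporting the fraction
#' of clones in which at least one cluster is called, with an exact binomial
#' 95% confidence interval. Clones are simulated in batches that share one
#' catalog (distinct clone ids); cluster calling is per clone, so batching
#' does not change any call.
#'
#' @param genome a [genome_model()].
#' @param n_mutations mutations per simulated clone.
#' @param threshold calling threshold in bp.
#' @param min_mutations minimum cluster size.
#' @param n_reps number of simulated clones (>= 1; >= 1000 recommended for a
#'   stable estimate, smaller values draw a warning).
#' @param seed integer seed.
#' @param batch_size clones per batch (memory/speed trade-off).
#' @return a `null_estimate` list: `probability`, `ci95`, `n_hits`,
#'   `n_reps`, `params`.
#' @export
estimate_cluster_probability <- function(genome, n_mutations, threshold,
                                         min_mutations = 5L, n_reps = 10000L,
                                         seed = NULL, batch_size = 2000L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (n_reps < 1000) warning("n_reps < 1000 gives an unstable estimate")
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  if (min_mutations <= n_mutations) {
    done <- 0L
    b <- 0L
    while (done < n_reps) {
      b <- b + 1L
      take <- min(batch_size, n_reps - done)
      cat_b <- simulate_null_batch(genome, n_mutations, take,
                                   clone_prefix = sprintf("b%04d_", b))
      calls <- call_clusters(cat_b, threshold, min_mutations)
      hits <- hits + length(unique(calls$clone))
      done <- done + take
    }
  }
  ci <- stats::binom.test(hits, n_reps)$conf.int
  structure(list(probability = hits / n_reps,
                 ci95 = as.numeric(ci), n_hits = hits, n_reps = n_reps,
                 params = list(total_length = genome$total_length,
                               n_chrom = nrow(genome$chroms),
                               n_mutations = n_mutations,
                               threshold = threshold,
                               min_mutations = min_mutations,
                               seed = seed)),
            class = "null_estimate")
}

#' @export
print.null_estimate <- function(x, ...) {
  cat(sprintf(paste0("null cluster probability: %.3g ",
                     "(%d/%d clones; 95%% CI %.3g-%.3g)\n"),
              x$probability, x$n_hits, x$n_reps, x$ci95[1], x$ci95[2]))
  p <- x$params
  cat(sprintf("  %d mutations/clone, threshold %s bp, min %d, genome %s bp\n",
              p$n_mutations, format(p$threshold, big.mark = ","),
              p$min_mutations, format(p$total_length, big.mark = ",")))
  invisible(x)
}
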