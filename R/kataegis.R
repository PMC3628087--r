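#' Fit the kataegis detection model to a mutation catalog
#'
#' Runs the full detection chain: intermutational distances
#' ([compute_imds()]), two-group k-means split of log10 IMDs
#' ([partition_imds()]), derivation of the calling threshold as the distal
#' quantile excluding `exclusion` of the distal group ([derive_threshold()]),
#' and calling of maximal sub-threshold runs of at least `min_mutations`
#' mutations ([call_clusters()]). The threshold is estimated from the pooled
#' IMD set of the whole catalog (all clones of a genotype together), not per
#' clone.
#'
#' @param catalog a [mutation_catalog()] or a data frame coercible to one.
#' @param genome optional [genome_model()] used for validation and for the
#'   [simulate()] method.
#' @param exclusion fraction of distal IMDs the threshold must exclude
#'   (default 0.99).
#' @param min_mutations minimum cluster size (default 5).
#' @param threshold optional fixed calling threshold in bp; when given, the
#'   partition step is skipped and the threshold is used as-is.
#' @return an object of class `kataegis` with components `catalog`, `imd`,
#'   `partition` (NULL when a fixed threshold was supplied), `threshold`,
#'   `clusters`, `burden`, and the call parameters.
#' @examples
#' cat <- data.frame(clone = "c1", chrom = "chr1",
#'                   pos = c(100, 600, 1100, 1600, 2100, 50000, 250000,
#'                           500000, 700000),
#'                   ref = "C", alt = "T")
#' fit <- kataegis(cat, threshold = 1000)
#' fit$clusters$n_mutations
#' @export
kataegis <- function(catalog, genome = NULL, exclusion = 0.99,
                     min_mutations = 5L, threshold = NULL) {
  if (!inherits(catalog, "mutation_catalog")) {
    catalog <- mutation_catalog(catalog, genome = genome)
  }
  if (is.null(genome)) genome <- attr(catalog, "genome")
  if (nrow(catalog) < 2L) {
    stop("insufficient IMDs: the catalog holds fewer than 2 mutations")
  }
  imd <- compute_imds(catalog)
  partition <- NULL
  if (is.null(threshold)) {
    partition <- partition_imds(imd)
    threshold <- derive_threshold(partition, exclusion = exclusion)
    partition$threshold <- threshold
    partition$exclusion <- exclusion
  }
  clusters <- call_clusters(catalog, threshold, min_mutations)
  structure(list(catalog = catalog, genome = genome, imd = imd,
                 partition = partition, threshold = threshold,
                 exclusion = exclusion, min_mutations = min_mutations,
                 clusters = clusters,
                 burden = cluster_burden(clusters, catalog)),
            class = "kataegis")
}

#' @export
print.kataegis <- function(x, ...) {
  b <- x$burden
  cat("kataegis fit\n")
  cat(sprintf("  %d mutations in %d clone(s); %d IMD(s)\n",
              b$n_mutations, b$n_clones, nrow(x$imd$entries)))
  if (!is.null(x$partition)) {
    cat(sprintf("  proximal/distal medians: %s / %s bp\n",
                format(x$partition$median_proximal, big.mark = ","),
                format(x$partition$median_distal, big.mark = ",")))
  }
  cat(sprintf("  calling threshold: %s bp (min %d mutations)\n",
              format(round(x$threshold, 1), big.mark = ","),
              x$min_mutations))
  cat(sprintf("  %d cluster(s) covering %d mutation(s) in %d clone(s)\n",
              b$n_clusters, b$n_clustered, b$clones_with_cluster))
  invisible(x)
}

#' @export
summary.kataegis <- function(object, ...) {
  cl <- object$clusters
  per_clone <- do.call(rbind, lapply(unique(object$catalog$clone), function(cid) {
    data.frame(clone = cid,
               n_mutations = sum(object$catalog$clone == cid),
               n_clusters = sum(cl$clone == cid),
               n_clustered = sum(cl$n_mutations[cl$clone == cid]))
  }))
  agg_polarity <- if (nrow(cl)) {
    sum(cl$polarity * cl$n_mutations) / sum(cl$n_mutations)
  } else NA_real_
  structure(list(fit = object, per_clone = per_clone,
                 aggregate_polarity = agg_polarity),
            class = "summary.kataegis")
}

#' @export
print.summary.kataegis <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$partition)) print(x$fit$partition)
  if (!is.na(x$aggregate_polarity)) {
    cat(sprintf("  aggregate strand coordination: %.1f%%\n",
                100 * x$aggregate_polarity))
  }
  cat("\nper-clone burden:\n")
  print(x$per_clone, row.names = FALSE)
  invisible(x)
}

#' @export
coef.kataegis <- function(object, ...) {
  c(threshold = object$threshold,
    median_proximal = if (is.null(object$partition)) NA_real_ else
      object$partition$median_proximal,
    median_distal = if (is.null(object$partition)) NA_real_ else
      object$partition$median_distal)
}

#' Apply a fitted kataegis model to new data
#'
#' With `type = "clusters"` (default), `newdata` is a mutation catalog and
#' cluster calls are made with the fitted threshold and minimum size. With
#' `type = "imd_class"`, `newdata` is a numeric vector of IMDs classified
#' proximal/distal by the fitted k-means boundary (midpoint of the log10
#' centers).
#'
#' @param object a [kataegis()] fit.
#' @param newdata a catalog (or coercible data frame), or numeric IMDs.
#' @param type `"clusters"` or `"imd_class"`.
#' @param ... unused.
#' @export
predict.kataegis <- function(object, newdata,
                             type = c("clusters", "imd_class"), ...) {
  type <- match.arg(type)
  if (type == "clusters") {
    if (!inherits(newdata, "mutation_catalog")) {
      newdata <- mutation_catalog(newdata, genome = object$genome)
    }
    return(call_clusters(newdata, object$threshold, object$min_mutations))
  }
  if (is.null(object$partition)) {
    stop("fit was made with a fixed threshold; no partition boundary")
  }
  boundary <- mean(object$partition$centers_log10)
  factor(ifelse(log10(as.numeric(newdata)) < boundary, "proximal", "distal"),
         levels = c("proximal", "distal"))
}

#' Rainfall plot of a kataegis fit
#'
#' Mutations are laid out sequentially along the concatenated genome per
#' clone with the log10 IMD on the y axis; clustered mutations are
#' highlighted and the calling threshold drawn as a horizontal line.
#'
#' @param x a [kataegis()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kataegis <- function(x, ...) {
  cat_df <- as.data.frame(x$catalog)
  n <- nrow(cat_df)
  imd <- rep(NA_real_, n)
  if (n > 1) {
    same <- cat_df$clone[-1] == cat_df$clone[-n] &
      cat_df$chrom[-1] == cat_df$chrom[-n]
    imd[c(same, FALSE)] <- diff(cat_df$pos)[same]
  }
  idx <- which(!is.na(imd))
  if (!length(idx)) stop("no IMDs to plot")
  clustered <- rep(FALSE, n)
  if (nrow(x$clusters)) clustered[unlist(x$clusters$members)] <- TRUE
  cols <- ifelse(clustered[idx], "firebrick", "grey40")
  graphics::plot(idx, log10(imd[idx]), col = cols, pch = 16, cex = 0.6,
                 xlab = "mutation index (genome order per clone)",
                 ylab = "log10 IMD (bp)", ...)
  graphics::abline(h = log10(x$threshold), lty = 2)
  cb <- cumsum(table(factor(cat_df$clone, levels = unique(cat_df$clone))))
  graphics::abline(v = cb[-length(cb)] + 0.5, col = "grey85")
  invisible(x)
}

#' Simulate null catalogs matched to a kataegis fit
#'
#' Draws `nsim` replicate catalogs in which each observed clone's mutation
#' count is scattered uniformly over the fitted genome (per-clone counts are
#' preserved, since IMDs are clone-conditional), using the same random
#' placement as [simulate_random_catalog()].
#'
#' @param object a [kataegis()] fit carrying a genome model.
#' @param nsim number of replicate catalogs.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` [mutation_catalog()] objects.
#' @export
simulate.kataegis <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$genome)) {
    stop("simulate() needs a genome model attached to the fit")
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- table(object$catalog$clone)
  lapply(seq_len(nsim), function(r) {
    parts <- lapply(names(counts), function(cid) {
      sim <- simulate_random_catalog(object$genome, counts[[cid]],
                                     clone_id = cid)
      as.data.frame(sim)[c("clone", "chrom", "pos", "ref", "alt")]
    })
    mutation_catalog(do.call(rbind, parts), genome = object$genome,
                     provenance = sprintf("null replicate %d", r))
  })
}
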