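#' Intermutational distances and cluster calling
#'
#' The intermutational distance (IMD) of a mutation is the distance in bp to
#' the next downstream mutation on the same chromosome within the same clone.
#' On a rainfall plot the IMD distribution of AID/APOBEC-mutagenized genomes
#' is bimodal: a distal ("singlet") group whose spacing matches random
#' scatter, and a proximal group of closely spaced mutations that make up the
#' kataegic clusters. The workflow is [compute_imds()] ->
#' [partition_imds()] -> [derive_threshold()] -> [call_clusters()], wrapped
#' by [kataegis()].
#'
#' @name imd
NULL

group_key <- function(catalog) paste(catalog$clone, catalog$chrom, sep = "\r")

#' Compute intermutational distances
#'
#' For every consecutive same-clone, same-chromosome pair of mutations
#' (p_i, p_{i+1}) one entry is produced with `imd = p_{i+1} - p_i`, attached
#' to the upstream position. The most downstream mutation of each multiply
#' mutated chromosome contributes no entry (counted in
#' `n_excluded_terminal`), nor does a mutation alone on its chromosome
#' (`n_excluded_singleton_chrom`).
#'
#' @param catalog a validated [mutation_catalog()].
#' @return an `imd_series` list: `entries` (data frame clone, chrom, pos,
#'   imd), the two exclusion counters, and `n_total` mutations.
#' @export
compute_imds <- function(catalog) {
  n <- nrow(catalog)
  key <- group_key(catalog)
  if (n == 0L) {
    entries <- data.frame(clone = character(0), chrom = character(0),
                          pos = integer(0), imd = integer(0))
    return(structure(list(entries = entries, n_excluded_terminal = 0L,
                          n_excluded_singleton_chrom = 0L, n_total = 0L),
                     class = "imd_series"))
  }
  r <- rle(key)
  same <- if (n > 1) key[-1] == key[-n] else logical(0)
  d <- if (n > 1) diff(catalog$pos) else integer(0)
  keep <- same
  if (any(keep & d <= 0L)) stop("duplicate or unsorted positions in catalog")
  entries <- data.frame(clone = catalog$clone[c(keep, FALSE)],
                        chrom = catalog$chrom[c(keep, FALSE)],
                        pos = catalog$pos[c(keep, FALSE)],
                        imd = d[keep])
  structure(list(entries = entries,
                 n_excluded_terminal = sum(r$lengths >= 2L),
                 n_excluded_singleton_chrom = sum(r$lengths == 1L),
                 n_total = n),
            class = "imd_series")
}

#' @export
print.imd_series <- function(x, ...) {
  cat("IMD series:", nrow(x$entries), "distances from", x$n_total,
      "mutations\n")
  cat("excluded:", x$n_excluded_terminal, "terminal,",
      x$n_excluded_singleton_chrom, "singleton-chromosome\n")
  if (nrow(x$entries)) {
    cat("median IMD:", stats::median(x$entries$imd), "bp\n")
  }
  invisible(x)
}

#' Split intermutational distances into proximal and distal groups
#'
#' One-dimensional 2-means on log10(IMD) (Lloyd iteration) with
#' deterministic initialization at the 10th and 90th percentiles, so the
#' result does not depend on a random start. The group with the smaller
#' median is labelled proximal. IMDs of randomly scattered mutations fall in
#' the distal group; kataegic spacings fall in the proximal group.
#'
#' @param imds an [compute_imds()] result, or a bare numeric vector of IMDs.
#' @param seed accepted for interface stability; unused, since the
#'   initialization is deterministic.
#' @return an `imd_partition`: `labels` (factor proximal/distal per entry),
#'   group medians in bp, the raw `imd` vector, group sizes, and slots for
#'   the calling `threshold` and `exclusion` filled by [derive_threshold()].
#' @export
partition_imds <- function(imds, seed = NULL) {
  imd <- if (inherits(imds, "imd_series")) imds$entries$imd else as.numeric(imds)
  if (length(imd) < 4L) stop("need at least 4 IMD entries to partition")
  if (length(unique(imd)) < 2L) {
    stop("degenerate partition: all IMDs identical")
  }
  x <- log10(imd)
  init <- stats::quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  if (init[1] == init[2]) init <- range(x)
  km <- suppressWarnings(
    stats::kmeans(x, centers = matrix(init, ncol = 1),
                  algorithm = "Lloyd", iter.max = 200))
  med <- tapply(imd, km$cluster, stats::median)
  prox_cl <- as.integer(names(med)[which.min(med)])
  labels <- factor(ifelse(km$cluster == prox_cl, "proximal", "distal"),
                   levels = c("proximal", "distal"))
  structure(list(labels = labels, imd = imd,
                 median_proximal = unname(min(med)),
                 median_distal = unname(max(med)),
                 n_proximal = sum(labels == "proximal"),
                 n_distal = sum(labels == "distal"),
                 centers_log10 = sort(as.numeric(km$centers)),
                 threshold = NA_real_, exclusion = NA_real_),
            class = "imd_partition")
}

#' @export
print.imd_partition <- function(x, ...) {
  cat("IMD partition:", x$n_proximal, "proximal /", x$n_distal, "distal\n")
  cat(sprintf("median IMD: proximal %s bp, distal %s bp\n",
              format(x$median_proximal, big.mark = ","),
              format(x$median_distal, big.mark = ",")))
  if (!is.na(x$threshold)) {
    cat(sprintf("calling threshold: %s bp (excludes %.1f%% of distal IMDs)\n",
                format(round(x$threshold, 1), big.mark = ","),
                100 * x$exclusion))
  }
  invisible(x)
}

#' Derive the cluster-calling threshold from the distal group
#'
#' The threshold is the empirical `(1 - exclusion)` quantile of the
#' distal-group IMDs (linear interpolation between order statistics), i.e.
#' the distance below which at most `1 - exclusion` of the distal (randomly
#' scattered) spacings fall. With the default `exclusion = 0.99`, 99% of the
#' distal IMDs exceed the threshold.
#'
#' @param partition an [partition_imds()] result.
#' @param exclusion fraction of the distal group the threshold must exclude,
#'   in (0, 1).
#' @return the threshold in bp.
#' @export
derive_threshold <- function(partition, exclusion = 0.99) {
  if (!inherits(partition, "imd_partition")) stop("need an imd_partition")
  if (!is.numeric(exclusion) || exclusion <= 0 || exclusion >= 1) {
    stop("exclusion must lie strictly between 0 and 1")
  }
  distal <- partition$imd[partition$labels == "distal"]
  if (!length(distal)) stop("distal group is empty")
  as.numeric(stats::quantile(distal, probs = 1 - exclusion, type = 7,
                             names = FALSE))
}

#' Call kataegic clusters
#'
#' A cluster is a maximal run, within one clone and one chromosome, of at
#' least `min_mutations` consecutive mutations whose every internal gap is
#' strictly below `threshold`. A gap equal to the threshold breaks the run.
#' Each call carries its span, member indices (rows of `catalog`), strand
#' polarity (fraction of members presenting the majority reference base of
#' the mutated C:G pair) and pyrimidine-oriented substitution spectrum.
#'
#' @param catalog a validated [mutation_catalog()].
#' @param threshold calling threshold in bp (> 0).
#' @param min_mutations minimum run size (>= 2; default 5).
#' @return a `cluster_calls` data frame sorted by (clone, chrom, start) with
#'   columns clone, chrom, start, end, length (= end - start), n_mutations,
#'   polarity, majority_base, n_CtoT/n_CtoG/n_CtoA/n_at_pairs, cluster_id,
#'   and a `members` list column of catalog row indices.
#' @export
call_clusters <- function(catalog, threshold, min_mutations = 5L) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  if (min_mutations < 2L) stop("min_mutations must be >= 2")
  n <- nrow(catalog)
  empty <- data.frame(clone = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), n_mutations = integer(0),
                      polarity = numeric(0), majority_base = character(0),
                      n_CtoT = integer(0), n_CtoG = integer(0),
                      n_CtoA = integer(0), n_at_pairs = integer(0),
                      cluster_id = character(0))
  empty$members <- list()
  cls <- function(d) structure(d, class = c("cluster_calls", "data.frame"),
                               threshold = threshold,
                               min_mutations = min_mutations)
  if (n < min_mutations) return(cls(empty))
  key <- group_key(catalog)
  ok <- key[-1] == key[-n] & diff(catalog$pos) < threshold
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= (min_mutations - 1L))
  if (!length(runs)) return(cls(empty))
  out <- vector("list", length(runs))
  for (j in seq_along(runs)) {
    i1 <- starts[runs[j]]           # first ok-edge -> members i1 .. i2+1
    i2 <- ends[runs[j]]
    members <- i1:(i2 + 1L)
    refs <- catalog$ref[members]
    alts <- catalog$alt[members]
    nC <- sum(refs == "C"); nG <- sum(refs == "G")
    maj <- if (nC >= nG) "C" else "G"
    ch <- ifelse(refs == "C", paste0("C>", alts),
          ifelse(refs == "G", paste0("C>", complement_base(alts)), NA))
    row <- data.frame(clone = catalog$clone[i1], chrom = catalog$chrom[i1],
                      start = catalog$pos[i1], end = catalog$pos[i2 + 1L],
                      length = catalog$pos[i2 + 1L] - catalog$pos[i1],
                      n_mutations = length(members),
                      polarity = max(nC, nG) / length(members),
                      majority_base = maj,
                      n_CtoT = sum(ch == "C>T", na.rm = TRUE),
                      n_CtoG = sum(ch == "C>G", na.rm = TRUE),
                      n_CtoA = sum(ch == "C>A", na.rm = TRUE),
                      n_at_pairs = sum(is.na(ch)),
                      cluster_id = sprintf("%s_%s_%d", catalog$clone[i1],
                                           catalog$chrom[i1],
                                           catalog$pos[i1]))
    row$members <- list(members)
    out[[j]] <- row
  }
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$clone, calls$chrom, calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  cls(calls)
}

#' @export
print.cluster_calls <- function(x, ...) {
  cat("cluster calls:", nrow(x), "cluster(s) at threshold",
      format(attr(x, "threshold"), big.mark = ","), "bp, min",
      attr(x, "min_mutations"), "mutations\n")
  if (nrow(x)) {
    print(as.data.frame(x)[, c("clone", "chrom", "start", "end",
                               "n_mutations", "polarity", "majority_base")])
  }
  invisible(x)
}

#' Summarize the cluster burden of a catalog
#'
#' @param clusters a [call_clusters()] result.
#' @param catalog the catalog the calls derive from.
#' @return a list: total mutations, clustered mutations, number of clusters,
#'   clones carrying at least one cluster, mean clustered mutations per
#'   clone, and the mean internal IMD within clusters.
#' @export
cluster_burden <- function(clusters, catalog) {
  n_clones <- length(unique(catalog$clone))
  clustered <- if (nrow(clusters)) sum(clusters$n_mutations) else 0L
  intra <- if (nrow(clusters)) {
    unlist(lapply(clusters$members, function(m) diff(catalog$pos[m])))
  } else numeric(0)
  list(n_mutations = nrow(catalog),
       n_clustered = clustered,
       n_clusters = nrow(clusters),
       n_clones = n_clones,
       clones_with_cluster = length(unique(clusters$clone)),
       mean_clustered_per_clone = if (n_clones) clustered / n_clones else 0,
       mean_intra_cluster_imd = if (length(intra)) mean(intra) else NA_real_)
}
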