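# Independent brute-force oracles used to cross-check the implementation.

# catalog constructor shorthand (supports zero rows)
cat_df <- function(pos, clone = "c1", chrom = "chr1", ref = "C", alt = "T") {
  n <- length(pos)
  data.frame(clone = rep(clone, length.out = n),
             chrom = rep(chrom, length.out = n), pos = pos,
             ref = rep(ref, length.out = n),
             alt = rep(alt, length.out = n), stringsAsFactors = FALSE)
}

# an imd_partition with known group membership, bypassing the k-means fit,
# so threshold derivation can be tested in isolation
fake_partition <- function(proximal, distal) {
  structure(list(
    labels = factor(rep(c("proximal", "distal"),
                        c(length(proximal), length(distal))),
                    levels = c("proximal", "distal")),
    imd = c(proximal, distal),
    median_proximal = stats::median(proximal),
    median_distal = stats::median(distal),
    n_proximal = length(proximal), n_distal = length(distal),
    centers_log10 = c(mean(log10(proximal)), mean(log10(distal))),
    threshold = NA_real_, exclusion = NA_real_),
    class = "imd_partition")
}

# exhaustive enumeration of maximal sub-threshold runs: for every
# clone/chromosome, test every window [i, j] for (a) all internal gaps
# strictly below threshold, (b) size, (c) maximality at both flanks
brute_clusters <- function(catalog, threshold, min_mutations) {
  out <- list()
  for (cid in unique(catalog$clone)) {
    for (ch in unique(catalog$chrom[catalog$clone == cid])) {
      pos <- sort(catalog$pos[catalog$clone == cid & catalog$chrom == ch])
      n <- length(pos)
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (j - i + 1 < min_mutations) next
          gaps <- diff(pos[i:j])
          if (any(gaps >= threshold)) next
          left_max <- i == 1 || (pos[i] - pos[i - 1]) >= threshold
          right_max <- j == n || (pos[j + 1] - pos[j]) >= threshold
          if (left_max && right_max) {
            out[[length(out) + 1]] <- data.frame(
              clone = cid, chrom = ch, start = pos[i], end = pos[j],
              n_mutations = j - i + 1)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(clone = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_mutations = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$clone, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# order-statistic interpolation at rank (n - 1) * p, from first principles
brute_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

# exact optimal 1-D 2-partition of x by within-group sum of squares,
# searching every split point of the sorted values
exact_two_partition <- function(x) {
  s <- sort(x)
  n <- length(s)
  best <- NULL
  best_ss <- Inf
  for (k in seq_len(n - 1)) {
    a <- s[1:k]; b <- s[(k + 1):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best_ss) {
      best_ss <- ss
      best <- s[k]   # boundary: values <= best in the lower group
    }
  }
  list(boundary = best, ss = best_ss)
}

# exhaustive both-strand scan for pyrimidine-motif context composition:
# walk every position; a site is a C preceded (5', pyrimidine strand) by
# the motif prefix; tally the base at `offset` on that strand
brute_background <- function(s, offset, motif = "TC") {
  comp <- function(b) chartr("ACGT", "TGCA", b)
  n <- nchar(s)
  base_at <- function(i) substring(s, i, i)
  counts <- setNames(numeric(4), c("A", "C", "G", "T"))
  prefix <- substring(motif, 1, nchar(motif) - 1)
  plen <- nchar(prefix)
  for (i in seq_len(n)) {
    # plus strand: C at i with prefix immediately 5'
    if (base_at(i) == "C" && i - plen >= 1 &&
        substring(s, i - plen, i - 1) == prefix) {
      t <- i + offset
      if (t >= 1 && t <= n) counts[base_at(t)] <- counts[base_at(t)] + 1
    }
    # minus strand: C on minus = G on plus; prefix runs 3'-ward on plus,
    # complemented and reversed
    if (base_at(i) == "G" && i + plen <= n) {
      up <- sapply(seq_len(plen), function(k) comp(base_at(i + k)))
      if (paste(rev(up), collapse = "") == prefix) {
        t <- i - offset
        if (t >= 1 && t <= n) {
          b <- comp(base_at(t))
          counts[b] <- counts[b] + 1
        }
      }
    }
  }
  counts
}

# shared mid-size fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

shared_genome <- function() {
  if (is.null(.fixtures$genome)) {
    p <- synthetic_params(
      chrom_lengths = setNames(c(9e5, 7e5, 5e5, 5e5, 4e5, 3e5, 3e5, 2e5),
                               paste0("chr", 1:8)),
      seed = 101)
    .fixtures$genome <- generate_genome(p)
    .fixtures$genome_params <- p
  }
  .fixtures$genome
}

shared_sim <- function() {
  if (is.null(.fixtures$sim)) {
    g <- shared_genome()
    p <- kataegis_preset("AID_star",
                         chrom_lengths = .fixtures$genome_params$chrom_lengths,
                         n_clones = 30, seed = 202)
    .fixtures$sim <- generate_catalog(g, p)
  }
  .fixtures$sim
}
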