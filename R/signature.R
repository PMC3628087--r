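#' Pyrimidine-oriented spectra, strand polarity and context signatures
#'
#' AID/APOBEC deaminases act on cytosine in single-stranded DNA, so every
#' mutation at a C:G pair is represented as a change at C: a record whose
#' reference base is G is complemented onto the minus (pyrimidine) strand.
#' Transitions are C>T; transversions are C>G and C>A (abasic-site bypass
#' products). Flanking-sequence preference is summarized as a position
#' frequency matrix (PFM) over the bases 5' of the mutated C (default
#' offsets -2, -1 on the pyrimidine strand), optionally normalized to the
#' genomic background composition, and PFMs are compared with the
#' Sandelin-Wasserman column similarity.
#'
#' @name signature
NULL

#' Orient mutations to the pyrimidine strand
#'
#' C:G-pair records are mapped to a change at C: records with reference C
#' keep strand `plus`, records with reference G are complemented onto strand
#' `minus` (G>A becomes C>T, and so on). Mutations at A:T pairs are flagged
#' and excluded from C-context analyses but retained in totals. Orienting an
#' already oriented table is a no-op.
#'
#' @param catalog a [mutation_catalog()] or data frame with clone, chrom,
#'   pos, ref, alt.
#' @return the input with added columns `pyr_strand` (`"plus"`/`"minus"`,
#'   `NA` for A:T pairs), `change` (`"C>T"`, `"C>G"`, `"C>A"`, `NA`) and
#'   logical `at_pair`.
#' @export
orient_to_pyrimidine <- function(catalog) {
  df <- as.data.frame(catalog)
  if (all(c("pyr_strand", "change", "at_pair") %in% names(df))) return(df)
  at <- df$ref %in% c("A", "T")
  strand <- ifelse(at, NA, ifelse(df$ref == "C", "plus", "minus"))
  change <- rep(NA_character_, nrow(df))
  change[!at] <- ifelse(df$ref[!at] == "C",
                        paste0("C>", df$alt[!at]),
                        paste0("C>", complement_base(df$alt[!at])))
  df$pyr_strand <- strand
  df$change <- change
  df$at_pair <- at
  df
}

#' Substitution spectrum at C:G pairs
#'
#' Counts and percentages of C>T (transition), C>G and C>A (transversions)
#' after pyrimidine orientation. Percentages are over the three C-changes
#' only; A:T-pair mutations are tallied separately.
#'
#' @param x a catalog, an oriented data frame, or a subset of rows (e.g.
#'   cluster members).
#' @param stratum free-text label (e.g. `"kataegic"`, `"unclustered"`).
#' @return a `spectrum_summary` list with `counts`, `percent` (NA when the
#'   stratum holds no C:G mutation), `n_total`, `n_at_pairs`, `stratum`.
#' @export
spectrum <- function(x, stratum = "all") {
  df <- orient_to_pyrimidine(x)
  counts <- c("C>T" = sum(df$change == "C>T", na.rm = TRUE),
              "C>G" = sum(df$change == "C>G", na.rm = TRUE),
              "C>A" = sum(df$change == "C>A", na.rm = TRUE))
  ncg <- sum(counts)
  structure(list(counts = counts,
                 percent = if (ncg) 100 * counts / ncg else
                   stats::setNames(rep(NA_real_, 3), names(counts)),
                 transition_pct = if (ncg) 100 * counts[["C>T"]] / ncg else NA_real_,
                 transversion_pct = if (ncg)
                   100 * (counts[["C>G"]] + counts[["C>A"]]) / ncg else NA_real_,
                 n_total = nrow(df), n_at_pairs = sum(df$at_pair),
                 stratum = stratum),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("substitution spectrum [%s]: n = %d (%d at A:T pairs)\n",
              x$stratum, x$n_total, x$n_at_pairs))
  if (all(is.na(x$percent))) {
    cat("  no C:G-pair mutations in stratum\n")
  } else {
    cat(sprintf("  C>T %.1f%%  C>G %.1f%%  C>A %.1f%%  (Tv %.1f%%)\n",
                x$percent[1], x$percent[2], x$percent[3], x$transversion_pct))
  }
  invisible(x)
}

#' Strand coordination of cluster calls
#'
#' A cluster's polarity is the fraction of its members whose mutated C:G
#' pair presents the majority reference base (C or G): deamination of one
#' exposed single strand makes clusters strand coordinated. The aggregate
#' is the fraction of all clustered mutations lying on their cluster's
#' majority strand.
#'
#' @param clusters a [call_clusters()] result.
#' @return a list: `per_call` data frame (cluster_id, polarity,
#'   majority_base), `aggregate`, `n_clusters`.
#' @export
strand_coordination <- function(clusters) {
  if (!nrow(clusters)) {
    return(list(per_call = data.frame(cluster_id = character(0),
                                      polarity = numeric(0),
                                      majority_base = character(0)),
                aggregate = NA_real_, n_clusters = 0L))
  }
  list(per_call = data.frame(cluster_id = clusters$cluster_id,
                             polarity = clusters$polarity,
                             majority_base = clusters$majority_base),
       aggregate = sum(clusters$polarity * clusters$n_mutations) /
         sum(clusters$n_mutations),
       n_clusters = nrow(clusters))
}

#' Extract 5'-flanking contexts of mutated C bases
#'
#' For each C:G-pair mutation the bases at the requested offsets relative to
#' the mutated C on the pyrimidine strand are read from the genome: on the
#' plus strand the base at `pos + offset`, on the minus strand the
#' complement of the base at `pos - offset` (offsets are 5'-relative on the
#' pyrimidine strand). Sites whose context would run off a chromosome end
#' are skipped and counted.
#'
#' @param catalog a [mutation_catalog()] (or oriented data frame).
#' @param genome a [genome_model()] with sequence.
#' @param offsets integer offsets, default `c(-2, -1)`.
#' @return a list: `contexts` data frame (one column per offset plus
#'   `context` string in offset order), `n_sites`, `n_skipped_boundary`,
#'   `n_at_pairs`, `offsets`.
#' @export
extract_contexts <- function(catalog, genome, offsets = c(-2L, -1L)) {
  if (is.null(genome$sequence)) stop("genome model carries no sequence")
  offsets <- as.integer(offsets)
  df <- orient_to_pyrimidine(catalog)
  cg <- df[!df$at_pair, , drop = FALSE]
  len <- genome$chroms$length[match(cg$chrom, genome$chroms$name)]
  ctx <- matrix(NA_character_, nrow(cg), length(offsets))
  keep <- rep(TRUE, nrow(cg))
  for (j in seq_along(offsets)) {
    off <- offsets[j]
    tgt <- ifelse(cg$pyr_strand == "plus", cg$pos + off, cg$pos - off)
    ok <- tgt >= 1 & tgt <= len
    keep <- keep & ok
    b <- rep(NA_character_, nrow(cg))
    if (any(ok)) b[ok] <- genome_base(genome, cg$chrom[ok], tgt[ok])
    minus <- cg$pyr_strand == "minus"
    b[minus] <- complement_base(b[minus])
    ctx[, j] <- b
  }
  out <- as.data.frame(ctx[keep, , drop = FALSE])
  names(out) <- paste0("off", offsets)
  out$context <- if (nrow(out)) {
    apply(ctx[keep, , drop = FALSE], 1, paste, collapse = "")
  } else character(0)
  list(contexts = out, n_sites = sum(keep),
       n_skipped_boundary = sum(!keep), n_at_pairs = sum(df$at_pair),
       offsets = offsets)
}

#' Build a position frequency matrix from contexts
#'
#' Per-offset base frequencies over A, C, G, T. When a background
#' composition is supplied, each frequency is divided by its background
#' frequency and the column renormalized to 1 (so an observed composition
#' equal to the background becomes uniform).
#'
#' @param contexts an [extract_contexts()] result, or a character vector of
#'   equal-width context strings.
#' @param offsets offsets labelling the columns (required when `contexts`
#'   is a bare character vector).
#' @param background optional background: a probability vector over
#'   A/C/G/T, or a matrix with one column per offset.
#' @return a `context_pfm`: `matrix` (4 x width, rows A/C/G/T, columns sum
#'   to 1), `offsets`, `n_sites`, `normalized`.
#' @export
build_pfm <- function(contexts, offsets = NULL, background = NULL) {
  if (is.list(contexts) && !is.null(contexts$contexts)) {
    strs <- contexts$contexts$context
    if (is.null(offsets)) offsets <- contexts$offsets
  } else {
    strs <- as.character(contexts)
  }
  if (!length(strs)) stop("need at least one context")
  w <- unique(nchar(strs))
  if (length(w) != 1L) stop("context strings must share one width")
  if (is.null(offsets)) offsets <- seq(-w, -1L)
  if (length(offsets) != w) stop("offsets do not match context width")
  chars <- matrix(unlist(strsplit(strs, "", fixed = TRUE)), ncol = w,
                  byrow = TRUE)
  m <- sapply(seq_len(w), function(j) {
    tab <- table(factor(chars[, j], levels = BASES))
    as.numeric(tab) / sum(tab)
  })
  m <- matrix(m, nrow = 4, dimnames = list(BASES, paste0("off", offsets)))
  normalized <- FALSE
  if (!is.null(background)) {
    bg <- if (is.matrix(background)) background else
      matrix(background, nrow = 4, ncol = w, dimnames = list(BASES, NULL))
    if (any(bg <= 0)) stop("background frequencies must be positive")
    m <- m / bg
    m <- sweep(m, 2, colSums(m), "/")
    normalized <- TRUE
  }
  structure(list(matrix = m, offsets = offsets, n_sites = length(strs),
                 normalized = normalized),
            class = "context_pfm")
}

#' @export
print.context_pfm <- function(x, ...) {
  cat(sprintf("context PFM over %d site(s)%s, offsets %s\n", x$n_sites,
              if (x$normalized) " (background-normalized)" else "",
              paste(x$offsets, collapse = ", ")))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Construct a PFM from a bare probability matrix
#'
#' @param m 4-row matrix (rows A/C/G/T) of per-offset base probabilities;
#'   columns are renormalized to sum to 1.
#' @param offsets offsets labelling the columns.
#' @param n_sites nominal site count.
#' @export
pfm_from_matrix <- function(m, offsets = c(-2L, -1L), n_sites = 0L) {
  m <- as.matrix(m)
  if (nrow(m) != 4L) stop("PFM matrix needs 4 rows (A, C, G, T)")
  rownames(m) <- BASES
  colnames(m) <- paste0("off", offsets)
  m <- sweep(m, 2, colSums(m), "/")
  structure(list(matrix = m, offsets = as.integer(offsets),
                 n_sites = n_sites, normalized = FALSE),
            class = "context_pfm")
}

#' Genomic background composition at an offset from a pyrimidine motif
#'
#' Scans both strands of the genome for occurrences of `motif` (written 5'
#' to 3' on the pyrimidine strand, with the mutable C as its last base; the
#' default `"TC"` targets every TC dinucleotide, which on the minus strand
#' appears as GA on the plus sequence) and tallies the base at `offset`
#' relative to the C on the pyrimidine strand.
#'
#' @param genome a [genome_model()] with sequence.
#' @param offset integer offset (default -2).
#' @param motif pyrimidine-strand motif ending in C (default `"TC"`); use
#'   `"C"` for all cytosines.
#' @return a list: `composition` (probability vector over A/C/G/T),
#'   `counts`, `n_sites`.
#' @export
genomic_background <- function(genome, offset = -2L, motif = "TC") {
  if (is.null(genome$sequence)) stop("genome model carries no sequence")
  motif <- toupper(motif)
  if (substring(motif, nchar(motif)) != "C") {
    stop("motif must end in the mutable C")
  }
  offset <- as.integer(offset)
  counts <- stats::setNames(numeric(4), BASES)
  rc <- revcomp(motif)
  mlen <- nchar(motif)
  for (ch in genome$chroms$name) {
    s <- genome$sequence[[ch]]
    slen <- nchar(s)
    # plus strand: C sits at match_start + mlen - 1; context base at C + offset
    # lookahead so overlapping occurrences (e.g. CC in CCC) all count
    hits <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
    if (hits[1] != -1L) {
      cpos <- as.integer(hits) + mlen - 1L
      tgt <- cpos + offset
      tgt <- tgt[tgt >= 1 & tgt <= slen]
      if (length(tgt)) {
        b <- substring(s, tgt, tgt)
        tb <- table(factor(b, levels = BASES))
        counts <- counts + as.numeric(tb)
      }
    }
    # minus strand: motif appears as revcomp(motif) on plus; the C maps to
    # the first base of the plus-strand match; context base is the
    # complement of the plus base at cpos - offset
    hits <- gregexpr(paste0("(?=", rc, ")"), s, perl = TRUE)[[1]]
    if (hits[1] != -1L) {
      cpos <- as.integer(hits)
      tgt <- cpos - offset
      tgt <- tgt[tgt >= 1 & tgt <= slen]
      if (length(tgt)) {
        b <- complement_base(substring(s, tgt, tgt))
        tb <- table(factor(b, levels = BASES))
        counts <- counts + as.numeric(tb)
      }
    }
  }
  n <- sum(counts)
  list(composition = if (n) counts / n else
         stats::setNames(rep(NA_real_, 4), BASES),
       counts = counts, n_sites = n)
}

#' Sandelin-Wasserman similarity between two PFMs
#'
#' The column score is `2 - sum_b (p1(b) - p2(b))^2`, summed over aligned
#' columns; identical motifs of width w score 2w, maximally disjoint single
#' columns score 0.
#'
#' @param pfm1,pfm2 `context_pfm` objects over the same offsets.
#' @return numeric score.
#' @export
sw_similarity <- function(pfm1, pfm2) {
  if (!identical(pfm1$offsets, pfm2$offsets)) {
    stop("PFMs must share the same offsets")
  }
  sum(2 - colSums((pfm1$matrix - pfm2$matrix)^2))
}

#' Permutation p-value for a Sandelin-Wasserman comparison
#'
#' The null replaces the second motif by random motifs whose columns are
#' Dirichlet perturbations of the background composition (concentration
#' `concentration * background`, so the null columns scatter around the
#' background); the p-value is `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param pfm1,pfm2 `context_pfm` objects over the same offsets.
#' @param background probability vector over A/C/G/T (default uniform).
#' @param n_perm number of permutations (>= 1; >= 100 recommended).
#' @param seed integer seed.
#' @param concentration Dirichlet concentration scale (default 20).
#' @return a `similarity_result`: `score`, `p_value`, `n_perm`, `seed`.
#' @export
sw_pvalue <- function(pfm1, pfm2, background = rep(0.25, 4), n_perm = 1000L,
                      seed = NULL, concentration = 20) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
  if (!is.null(seed)) set.seed(seed)
  obs <- sw_similarity(pfm1, pfm2)
  w <- length(pfm1$offsets)
  alpha <- concentration * background / sum(background)
  null_scores <- vapply(seq_len(n_perm), function(i) {
    g <- matrix(stats::rgamma(4 * w, shape = alpha), nrow = 4)
    m <- sweep(g, 2, colSums(g), "/")
    sum(2 - colSums((pfm1$matrix - m)^2))
  }, numeric(1))
  structure(list(score = obs,
                 p_value = (1 + sum(null_scores >= obs)) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("Sandelin-Wasserman similarity %.4f, p = %.4g (%d permutations)\n",
              x$score, x$p_value, x$n_perm))
  invisible(x)
}

#' Write / read a PFM in a minimal motif-matrix text format
#'
#' Four labelled rows (A, C, G, T), one tab-separated column per position;
#' a `#offsets` comment line records the offsets.
#'
#' @param pfm a `context_pfm`.
#' @param path file path.
#' @export
write_pfm <- function(pfm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#offsets\t", paste(pfm$offsets, collapse = "\t")), con)
  for (b in BASES) {
    writeLines(paste(c(b, format(pfm$matrix[b, ], digits = 10)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pfm
#' @export
read_pfm <- function(path) {
  lines <- readLines(path)
  offs <- as.integer(strsplit(sub("^#offsets\t", "", lines[1]), "\t")[[1]])
  rows <- strsplit(lines[-1], "\t")
  m <- t(vapply(rows, function(r) as.numeric(r[-1]),
                numeric(length(offs))))
  m <- matrix(m, nrow = 4, dimnames = list(vapply(rows, `[`, "", 1), NULL))
  pfm_from_matrix(m[BASES, , drop = FALSE], offsets = offs)
}
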