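#' Synthetic AID/APOBEC mutation catalogs with planted kataegic clusters
#'
#' The generator emulates the statistical structure of deaminase-mutagenized
#' yeast genomes: a 16-chromosome ~12.1-Mb genome, per-clone singlet
#' mutations scattered uniformly over C/G sites (mean load 25), and planted
#' clusters of 5-26 same-strand mutations whose intra-cluster spacings are
#' log-normal with median 727 bp, whose spans fall in 1.8-30 kb, whose
#' members follow a deaminase -2/-1 context preference, and whose strand
#' coordination is 0.88. Substitution mixes per stratum follow the
#' genotype presets. Ground-truth labels are returned for every mutation.
#'
#' @name synthetic
NULL

# sacCer3 nuclear chromosome lengths (bp), chrI..chrXVI
SACCER3_LENGTHS <- c(
  chrI = 230218, chrII = 813184, chrIII = 316620, chrIV = 1531933,
  chrV = 576874, chrVI = 270161, chrVII = 1090940, chrVIII = 562643,
  chrIX = 439888, chrX = 745751, chrXI = 666816, chrXII = 1078177,
  chrXIII = 924431, chrXIV = 784333, chrXV = 1091291, chrXVI = 948066)

#' Parameter bundle for the synthetic generator
#'
#' Defaults reproduce the wild-type hyperactive-AID study conditions; use
#' [kataegis_preset()] for the genotype presets.
#'
#' @param chrom_lengths named vector of chromosome lengths (default the 16
#'   sacCer3 nuclear chromosomes, ~12.07 Mb total).
#' @param gc_content genome GC fraction (default 0.38, yeast-like).
#' @param n_clones number of clones to simulate.
#' @param singlet_load per-clone Poisson mean of scattered mutations
#'   (default 25).
#' @param cluster_rate per-clone Poisson mean of planted clusters
#'   (default 0.65, i.e. 26 clusters per 40 clones).
#' @param cluster_size_range inclusive member-count range (default 5-26).
#' @param cluster_size_decay geometric weight decay across the size range
#'   (default 0.8; smaller clusters are more common).
#' @param cluster_span_range accepted span range in bp (default 1800-30000).
#' @param gap_median median intra-cluster spacing in bp (default 727).
#' @param gap_sdlog log-sd of the log-normal spacing; the default
#'   `sqrt(2 * log(1220/727))` makes the mean/median ratio match the
#'   observed 1220/727.
#' @param strand_coordination probability a member lies on the cluster's
#'   planted strand (default 0.88).
#' @param context_pfm a `context_pfm` over offsets (-2, -1) giving the
#'   deaminase flanking preference for cluster members.
#' @param spectrum_kataegic,spectrum_unclustered percentages of
#'   (C>T, C>G, C>A) for the two strata (must sum to 100).
#' @param at_pair_rate fraction of singlets placed at A:T pairs
#'   (default 14/1078).
#' @param genotype label echoed into clone ids and provenance.
#' @param seed integer seed.
#' @return a `synthetic_params` list.
#' @export
synthetic_params <- function(chrom_lengths = SACCER3_LENGTHS,
                             gc_content = 0.38,
                             n_clones = 40L,
                             singlet_load = 25,
                             cluster_rate = 0.65,
                             cluster_size_range = c(5L, 26L),
                             cluster_size_decay = 0.8,
                             cluster_span_range = c(1800, 30000),
                             gap_median = 727,
                             gap_sdlog = sqrt(2 * log(1220 / 727)),
                             strand_coordination = 0.88,
                             context_pfm = NULL,
                             spectrum_kataegic = c(46, 47, 7),
                             spectrum_unclustered = c(87, 11, 2),
                             at_pair_rate = 14 / 1078,
                             genotype = "AID_star",
                             seed = 1L) {
  if (is.null(context_pfm)) {
    # 5'-WRC: W (A/T) at -2, R (A/G) at -1
    context_pfm <- pfm_from_matrix(
      cbind(c(0.40, 0.10, 0.10, 0.40), c(0.45, 0.05, 0.45, 0.05)))
  }
  stopifnot(gc_content >= 0, gc_content <= 1,
            strand_coordination >= 0, strand_coordination <= 1,
            at_pair_rate >= 0, at_pair_rate <= 1,
            all(cluster_span_range > 0),
            abs(sum(spectrum_kataegic) - 100) < 1e-6,
            abs(sum(spectrum_unclustered) - 100) < 1e-6)
  structure(list(chrom_lengths = chrom_lengths, gc_content = gc_content,
                 n_clones = as.integer(n_clones),
                 singlet_load = singlet_load, cluster_rate = cluster_rate,
                 cluster_size_range = as.integer(cluster_size_range),
                 cluster_size_decay = cluster_size_decay,
                 cluster_span_range = cluster_span_range,
                 gap_median = gap_median, gap_sdlog = gap_sdlog,
                 strand_coordination = strand_coordination,
                 context_pfm = context_pfm,
                 spectrum_kataegic = spectrum_kataegic,
                 spectrum_unclustered = spectrum_unclustered,
                 at_pair_rate = at_pair_rate, genotype = genotype,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Genotype presets for the synthetic generator
#'
#' Bundles the genotype-specific substitution mixes and deaminase context
#' preferences: `AID_star` (hyperactive AID, 5'-WRC, kataegic mix 46:47:7,
#' unclustered 87:11:2), `A3A` (5'-TC, -2 weights A:C:G:T = 25:26:7:42,
#' 91% T at -1), `A3B` (-2 weights 35:14:20:31), `A3G_star` (5'-CCC),
#' `ung1_delta` (UNG-deficient: mix 99.3:0.2:0.5, fourfold mutation load,
#' strongly diminished clustering) and `rev1_delta` (REV1-deficient: pure
#' C>T).
#'
#' @param name one of `AID_star`, `A3A`, `A3B`, `A3G_star`, `ung1_delta`,
#'   `rev1_delta`.
#' @param ... overrides passed to [synthetic_params()].
#' @return a `synthetic_params` list.
#' @export
kataegis_preset <- function(name, ...) {
  presets <- list(
    AID_star = list(),
    A3A = list(
      context_pfm = pfm_from_matrix(
        cbind(c(0.25, 0.26, 0.07, 0.42), c(0.03, 0.03, 0.03, 0.91))),
      spectrum_kataegic = c(79, 17, 4),
      spectrum_unclustered = c(79, 17, 4)),
    A3B = list(
      context_pfm = pfm_from_matrix(
        cbind(c(0.35, 0.14, 0.20, 0.31), c(0.03, 0.03, 0.03, 0.91))),
      spectrum_kataegic = c(81, 16, 3),
      spectrum_unclustered = c(81, 16, 3)),
    A3G_star = list(
      context_pfm = pfm_from_matrix(
        cbind(c(0.10, 0.70, 0.10, 0.10), c(0.05, 0.85, 0.05, 0.05))),
      spectrum_kataegic = c(78, 20, 2),
      spectrum_unclustered = c(78, 20, 2),
      cluster_rate = 0.3),
    ung1_delta = list(
      singlet_load = 100, cluster_rate = 4 / 19,
      spectrum_kataegic = c(99.3, 0.2, 0.5),
      spectrum_unclustered = c(99.3, 0.2, 0.5)),
    rev1_delta = list(
      singlet_load = 15, cluster_rate = 0.4,
      spectrum_kataegic = c(100, 0, 0),
      spectrum_unclustered = c(100, 0, 0)))
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  args <- utils::modifyList(c(presets[[name]], list(genotype = name)),
                            list(...))
  do.call(synthetic_params, args)
}

#' Generate a random genome with sequence
#'
#' Bases are i.i.d. at the stated GC content (C and G each `gc/2`, A and T
#' each `(1-gc)/2`).
#'
#' @param params a [synthetic_params()], or a named length vector via
#'   `chrom_lengths`.
#' @param chrom_lengths optional named lengths overriding `params`.
#' @param gc_content optional GC fraction overriding `params`.
#' @param seed integer seed (defaults to `params$seed`).
#' @return a [genome_model()] with sequence.
#' @export
generate_genome <- function(params = synthetic_params(),
                            chrom_lengths = NULL, gc_content = NULL,
                            seed = NULL) {
  lens <- if (!is.null(chrom_lengths)) chrom_lengths else params$chrom_lengths
  gc <- if (!is.null(gc_content)) gc_content else params$gc_content
  if (is.null(seed)) seed <- params$seed
  if (is.null(names(lens))) names(lens) <- paste0("chr", seq_along(lens))
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sequence <- vapply(lens, function(L) {
    paste(sample(BASES, L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  genome_model(data.frame(name = names(lens), length = as.numeric(lens)),
               sequence = sequence)
}

# per-chromosome positions of a base set, from the raw byte representation
site_index <- function(genome, bases) {
  codes <- sapply(bases, function(b) as.integer(charToRaw(b)))
  lapply(genome$sequence, function(s) {
    which(as.integer(charToRaw(s)) %in% codes)
  })
}

sample_change <- function(n, mix) {
  sample(c("C>T", "C>G", "C>A"), n, replace = TRUE, prob = mix / 100)
}

alt_for <- function(ref, change) {
  x <- substring(change, 3, 3)               # pyrimidine-strand alt
  ifelse(ref == "C", x, complement_base(x))
}

# nearest position in a window of `s` (1-based chromosome coords
# [lo, hi]) matching the triplet context for a mutated base on `strand`
# ("C" = ref C, context 5' on plus; "G" = ref G, context on minus), not in
# `used`. Returns NA when no admissible site exists.
find_context_site <- function(s, lo, hi, target, strand, b2, b1, used) {
  win <- substring(s, lo, hi)
  pat <- if (strand == "C") paste0(b2, b1, "C") else
    paste0("G", complement_base(b1), complement_base(b2))
  hits <- gregexpr(paste0("(?=", pat, ")"), win, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(NA_integer_)
  cand <- as.integer(hits) + lo - 1L          # position of first pattern base
  if (strand == "C") cand <- cand + 2L        # the C is the third base
  cand <- setdiff(cand, used)
  if (!length(cand)) return(NA_integer_)
  cand[which.min(abs(cand - target))]
}

#' Generate a synthetic mutation catalog with ground truth
#'
#' Singlets are placed uniformly over C/G sites (a fraction `at_pair_rate`
#' at A/T sites) with alternate alleles drawn from the unclustered spectrum
#' mix. Each planted cluster draws a chromosome (proportional to length), a
#' planted strand, a member count, and log-normal intra-member gaps
#' (resampled until the span falls in `cluster_span_range`); each member
#' lies on the planted strand with probability `strand_coordination`, its
#' -2/-1 context is sampled from the preset PFM and the nearest site with
#' that context is used (falling back to the nearest C/G site when the
#' context is absent nearby), and its alternate allele follows the kataegic
#' spectrum mix.
#'
#' @param genome a [generate_genome()] result (sequence required).
#' @param params a [synthetic_params()].
#' @param seed integer seed (defaults to `params$seed + 1`, so genome and
#'   catalog draws are decoupled).
#' @return a list: `catalog` ([mutation_catalog()]), `truth` (per-mutation
#'   data frame clone/chrom/pos/label/cluster_id), `clusters` (planted
#'   intervals with strand and size), `params`.
#' @export
generate_catalog <- function(genome, params = synthetic_params(),
                             seed = NULL) {
  if (is.null(genome$sequence)) stop("generator needs genome sequence")
  if (is.null(seed)) seed <- params$seed + 1L
  set.seed(seed)
  cg_sites <- site_index(genome, c("C", "G"))
  at_sites <- site_index(genome, c("A", "T"))
  cg_counts <- vapply(cg_sites, length, integer(1))
  at_counts <- vapply(at_sites, length, integer(1))
  chroms <- genome$chroms$name
  lens <- genome$chroms$length
  pfm <- params$context_pfm$matrix
  szr <- params$cluster_size_range
  sizes <- szr[1]:szr[2]
  size_w <- params$cluster_size_decay^(sizes - szr[1])

  rows <- list()
  truth_rows <- list()
  cluster_rows <- list()
  ri <- 0L
  add_row <- function(clone, chrom, pos, ref, alt, label, cid) {
    ri <<- ri + 1L
    rows[[ri]] <<- data.frame(clone = clone, chrom = chrom, pos = pos,
                              ref = ref, alt = alt)
    truth_rows[[ri]] <<- data.frame(clone = clone, chrom = chrom, pos = pos,
                                    label = label, cluster_id = cid)
  }

  for (ci in seq_len(params$n_clones)) {
    clone <- sprintf("%s_c%03d", params$genotype, ci)
    used <- lapply(chroms, function(x) integer(0))
    names(used) <- chroms

    # planted clusters
    k <- stats::rpois(1, params$cluster_rate)
    for (j in seq_len(k)) {
      m <- if (length(sizes) == 1L) sizes else sample(sizes, 1, prob = size_w)
      gaps <- NULL
      for (try in seq_len(50)) {
        g <- stats::rlnorm(m - 1, log(params$gap_median), params$gap_sdlog)
        if (sum(g) >= params$cluster_span_range[1] &&
            sum(g) <= params$cluster_span_range[2]) { gaps <- g; break }
      }
      if (is.null(gaps)) {
        stop("could not draw a cluster span within range after 50 tries ",
             "(check gap/span parameters)")
      }
      span <- sum(gaps)
      ok_chrom <- which(lens > span + 4000)
      if (!length(ok_chrom)) stop("no chromosome long enough for span ", span)
      ch_i <- if (length(ok_chrom) == 1L) ok_chrom else
        sample(ok_chrom, 1, prob = lens[ok_chrom])
      ch <- chroms[ch_i]
      planted <- sample(c("C", "G"), 1)
      anchor <- floor(stats::runif(1, 2001, lens[ch_i] - span - 2000))
      targets <- round(anchor + c(0, cumsum(gaps)))
      members <- integer(0)
      for (t in targets) {
        strand <- if (stats::runif(1) < params$strand_coordination) planted
                  else setdiff(c("C", "G"), planted)
        b2 <- sample(BASES, 1, prob = pfm[, 1])
        b1 <- sample(BASES, 1, prob = pfm[, 2])
        pos <- NA_integer_
        for (w in c(500L, 2000L)) {
          pos <- find_context_site(genome$sequence[[ch]],
                                   max(1L, t - w), min(lens[ch_i], t + w),
                                   t, strand, b2, b1, used[[ch]])
          if (!is.na(pos)) break
        }
        if (is.na(pos)) {
          # fall back to the nearest unused site of the right base
          cand <- setdiff(cg_sites[[ch]], used[[ch]])
          cand <- cand[genome_base(genome, rep(ch, length(cand)), cand) ==
                         strand]
          if (!length(cand)) next
          pos <- cand[which.min(abs(cand - t))]
        }
        used[[ch]] <- c(used[[ch]], pos)
        members <- c(members, pos)
        change <- sample_change(1, params$spectrum_kataegic)
        add_row(clone, ch, pos, strand, alt_for(strand, change),
                "cluster", sprintf("%s_k%d", clone, j))
      }
      if (length(members)) {
        cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
          clone = clone, chrom = ch, start = min(members),
          end = max(members), n_members = length(members),
          planted_strand = planted,
          cluster_id = sprintf("%s_k%d", clone, j))
      }
    }

    # scattered singlets
    n_s <- stats::rpois(1, params$singlet_load)
    for (j in seq_len(n_s)) {
      at <- stats::runif(1) < params$at_pair_rate
      idx <- if (at) at_sites else cg_sites
      wts <- if (at) at_counts else cg_counts
      for (try in seq_len(20)) {
        ch_i <- sample(seq_along(chroms), 1, prob = wts)
        ch <- chroms[ch_i]
        pos <- idx[[ch]][sample.int(length(idx[[ch]]), 1)]
        if (!(pos %in% used[[ch]])) break
        pos <- NA_integer_
      }
      if (is.na(pos)) next
      used[[ch]] <- c(used[[ch]], pos)
      ref <- substring(genome$sequence[[ch]], pos, pos)
      alt <- if (at) sample(setdiff(BASES, ref), 1) else
        alt_for(ref, sample_change(1, params$spectrum_unclustered))
      add_row(clone, ch, pos, ref, alt, "singlet", NA_character_)
    }
  }

  df <- do.call(rbind, rows)
  truth <- do.call(rbind, truth_rows)
  catalog <- mutation_catalog(df, genome = genome,
                              provenance = paste0("synthetic:",
                                                  params$genotype))
  key <- paste(catalog$clone, catalog$chrom, catalog$pos, sep = "\r")
  tkey <- paste(truth$clone, truth$chrom, truth$pos, sep = "\r")
  truth <- truth[match(key, tkey), , drop = FALSE]
  rownames(truth) <- NULL
  clusters <- if (length(cluster_rows)) do.call(rbind, cluster_rows) else
    data.frame(clone = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               n_members = integer(0), planted_strand = character(0),
               cluster_id = character(0))
  list(catalog = catalog, truth = truth, clusters = clusters,
       params = params)
}

#' Write the ground-truth table of a synthetic catalog
#'
#' @param truth the `truth` element of [generate_catalog()].
#' @param path output TSV (`clone chrom pos label cluster_id`).
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
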