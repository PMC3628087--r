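test_that("pyrimidine orientation follows the complement rule", {
  df <- orient_to_pyrimidine(rbind(cat_df(100, ref = "G", alt = "A"),
                                   cat_df(200, ref = "C", alt = "G"),
                                   cat_df(300, ref = "A", alt = "T")))
  expect_equal(df$change[df$pos == 100], "C>T")
  expect_equal(df$pyr_strand[df$pos == 100], "minus")
  expect_equal(df$change[df$pos == 200], "C>G")
  expect_equal(df$pyr_strand[df$pos == 200], "plus")
  expect_true(df$at_pair[df$pos == 300])
  expect_true(is.na(df$change[df$pos == 300]))

  # idempotent: orienting an oriented table is a no-op
  expect_identical(orient_to_pyrimidine(df), df)
  # complement is an involution
  b <- c("A", "C", "G", "T")
  expect_equal(kataegisr:::complement_base(kataegisr:::complement_base(b)), b)
})

test_that("spectra count C-changes and flag empty strata", {
  df <- rbind(cat_df(100, ref = "C", alt = "T"),
              cat_df(200, ref = "G", alt = "A"),   # C>T on minus
              cat_df(300, ref = "C", alt = "G"),
              cat_df(400, ref = "C", alt = "A"))
  sp <- spectrum(df, "demo")
  expect_equal(unname(sp$counts), c(2L, 1L, 1L))
  expect_equal(unname(sp$percent), c(50, 25, 25))
  expect_equal(sp$transversion_pct, 50)
  expect_equal(sum(sp$percent), 100)

  sp0 <- spectrum(cat_df(integer(0)), "empty")
  expect_true(all(is.na(sp0$percent)))
  expect_equal(sp0$n_total, 0L)

  # A:T-pair mutations excluded from C percentages but kept in totals
  sp_at <- spectrum(rbind(df, cat_df(500, ref = "A", alt = "G")))
  expect_equal(sp_at$n_total, 5L)
  expect_equal(sp_at$n_at_pairs, 1L)
  expect_equal(sum(sp_at$counts), 4L)
})

test_that("strand polarity of calls", {
  df <- cat_df(c(100, 600, 1100, 1600, 2100),
               ref = c("C", "C", "G", "C", "C"),
               alt = c("T", "T", "A", "T", "T"))
  cl <- call_clusters(mutation_catalog(df), 1000, 5)
  expect_equal(cl$polarity, 0.8)
  expect_equal(cl$majority_base, "C")

  df2 <- cat_df(c(100, 600, 1100, 1600, 2100), ref = "G", alt = "A")
  cl2 <- call_clusters(mutation_catalog(df2), 1000, 5)
  expect_equal(cl2$polarity, 1.0)
  expect_equal(cl2$majority_base, "G")

  sc <- strand_coordination(rbind(cl, cl2))
  expect_equal(sc$aggregate, (0.8 * 5 + 1.0 * 5) / 10)
  expect_true(is.na(strand_coordination(call_clusters(
    mutation_catalog(df), 10, 5))$aggregate))
})

test_that("context extraction is 5'-relative on the pyrimidine strand", {
  g <- genome_model(data.frame(name = "chr1", length = 5),
                    sequence = c(chr1 = "ATTCG"))
  ctx <- extract_contexts(cat_df(4, ref = "C", alt = "T"), g)
  expect_equal(ctx$contexts$context, "TT")

  # G>A at pos 3 of ACGAA: minus-strand context = complements of plus 4, 5
  g2 <- genome_model(data.frame(name = "chr1", length = 5),
                     sequence = c(chr1 = "ACGAA"))
  ctx2 <- extract_contexts(cat_df(3, ref = "G", alt = "A"), g2)
  expect_equal(ctx2$contexts[["off-1"]], "T")
  expect_equal(ctx2$contexts[["off-2"]], "T")
  expect_equal(ctx2$contexts$context, "TT")

  # a site too close to the chromosome start is skipped and tallied
  g3 <- genome_model(data.frame(name = "chr1", length = 5),
                     sequence = c(chr1 = "CCCCC"))
  ctx3 <- extract_contexts(cat_df(c(1, 4), ref = "C", alt = "T"), g3)
  expect_equal(ctx3$n_sites, 1L)
  expect_equal(ctx3$n_skipped_boundary, 1L)

  # A:T-pair records never enter context extraction
  ctx4 <- extract_contexts(cat_df(3, ref = "A", alt = "G"), g2)
  expect_equal(ctx4$n_sites, 0L)
  expect_equal(ctx4$n_at_pairs, 1L)
})

test_that("PFMs count, normalize, and round-trip through text", {
  pfm <- build_pfm(c("TT", "TA"), offsets = c(-2L, -1L))
  expect_equal(pfm$matrix["T", "off-2"], 1)
  expect_equal(pfm$matrix["T", "off-1"], 0.5)
  expect_equal(pfm$matrix["A", "off-1"], 0.5)
  expect_equal(unname(colSums(pfm$matrix)), c(1, 1), tolerance = 1e-9)

  # observed composition equal to the background normalizes to uniform
  bg <- c(A = 0.5, C = 0.2, G = 0.2, T = 0.1)
  ctxs <- rep(c("A", "C", "G", "T"), round(bg * 100))
  pfm_n <- build_pfm(ctxs, offsets = -1L, background = bg)
  expect_equal(unname(pfm_n$matrix[, 1]), rep(0.25, 4), tolerance = 1e-9)

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_pfm(pfm, tf)
  back <- read_pfm(tf)
  expect_equal(back$matrix, pfm$matrix, tolerance = 1e-9)
  expect_equal(back$offsets, pfm$offsets)

  expect_error(build_pfm(character(0)), "at least one context")
})

test_that("genomic background matches an exhaustive two-strand scan", {
  s <- "GATCAGATTCGGAC"
  g <- genome_model(data.frame(name = "chr1", length = nchar(s)),
                    sequence = c(chr1 = s))
  for (off in c(-2L, -1L, 1L)) {
    got <- genomic_background(g, offset = off, motif = "TC")
    want <- brute_background(s, off, "TC")
    expect_equal(got$counts, want, ignore_attr = TRUE)
  }
  # overlapping pyrimidine motifs all count (CC in CCC)
  s2 <- "ACCCA"
  g2 <- genome_model(data.frame(name = "chr1", length = 5),
                     sequence = c(chr1 = s2))
  got2 <- genomic_background(g2, offset = -1L, motif = "CC")
  expect_equal(got2$counts, brute_background(s2, -1L, "CC"),
               ignore_attr = TRUE)

  # homopolymer without any TC site is flagged empty
  gT <- genome_model(data.frame(name = "chr1", length = 8),
                     sequence = c(chr1 = "TTTTTTTT"))
  bgT <- genomic_background(gT, motif = "TC")
  expect_equal(bgT$n_sites, 0)
  expect_true(all(is.na(bgT$composition)))

  # i.i.d. uniform sequence: composition near 0.25 each
  set.seed(8)
  su <- paste(sample(c("A", "C", "G", "T"), 4e4, TRUE), collapse = "")
  gu <- genome_model(data.frame(name = "chr1", length = 4e4),
                     sequence = c(chr1 = su))
  bgu <- genomic_background(gu, offset = -2L, motif = "TC")
  expect_true(all(abs(bgu$composition - 0.25) < 0.03))
})

test_that("Sandelin-Wasserman similarity: formula, symmetry, bounds", {
  p1 <- pfm_from_matrix(cbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  expect_equal(sw_similarity(p1, p1), 4.0)

  a <- pfm_from_matrix(matrix(c(1, 0, 0, 0), ncol = 1), offsets = -1L)
  b <- pfm_from_matrix(matrix(c(0, 1, 0, 0), ncol = 1), offsets = -1L)
  expect_equal(sw_similarity(a, b), 0.0)

  x <- pfm_from_matrix(matrix(c(0.03, 0.03, 0.03, 0.91), ncol = 1),
                       offsets = -1L)
  u <- pfm_from_matrix(matrix(rep(0.25, 4), ncol = 1), offsets = -1L)
  expect_equal(sw_similarity(x, u), 2 - (3 * 0.22^2 + 0.66^2))
  expect_equal(sw_similarity(x, u), sw_similarity(u, x))

  set.seed(14)
  for (rep in 1:20) {
    m1 <- matrix(stats::rgamma(8, 1), nrow = 4)
    m2 <- matrix(stats::rgamma(8, 1), nrow = 4)
    q1 <- pfm_from_matrix(m1); q2 <- pfm_from_matrix(m2)
    s12 <- sw_similarity(q1, q2)
    expect_equal(s12, sw_similarity(q2, q1))
    expect_gte(s12, 0)
    expect_lte(s12, 4)
  }
  expect_error(sw_similarity(a, p1), "same offsets")
})

test_that("permutation p-values behave at the extremes and under the null", {
  p1 <- pfm_from_matrix(cbind(c(0.05, 0.05, 0.05, 0.85),
                              c(0.8, 0.1, 0.05, 0.05)))
  self <- sw_pvalue(p1, p1, n_perm = 199, seed = 1)
  expect_equal(self$p_value, 1 / 200)
  expect_equal(self$score, 4.0)

  expect_error(sw_pvalue(p1, p1, n_perm = 0), "n_perm")

  # comparing background-like motifs to background-perturbation nulls
  # gives roughly uniform p-values across seeds
  set.seed(21)
  ps <- vapply(1:120, function(i) {
    g1 <- matrix(stats::rgamma(8, 20 * 0.25), nrow = 4)
    g2 <- matrix(stats::rgamma(8, 20 * 0.25), nrow = 4)
    sw_pvalue(pfm_from_matrix(g1), pfm_from_matrix(g2),
              n_perm = 199, seed = 1000 + i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
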