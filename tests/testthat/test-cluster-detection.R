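test_that("intermutational distances follow the downstream-neighbour rule", {
  cc <- mutation_catalog(cat_df(c(100, 600, 2600)))
  s <- compute_imds(cc)
  expect_equal(s$entries$imd, c(500L, 2000L))
  expect_equal(s$entries$pos, c(100L, 600L))   # attached to the upstream site
  expect_equal(s$n_excluded_terminal, 1L)
  expect_equal(s$n_excluded_singleton_chrom, 0L)

  # a lone mutation on its chromosome contributes nothing
  s2 <- compute_imds(mutation_catalog(cat_df(500, chrom = "chr2")))
  expect_equal(nrow(s2$entries), 0L)
  expect_equal(s2$n_excluded_singleton_chrom, 1L)

  # no IMD across chromosomes
  s3 <- compute_imds(mutation_catalog(
    rbind(cat_df(500), cat_df(600, chrom = "chr2"))))
  expect_equal(nrow(s3$entries), 0L)
  expect_equal(s3$n_excluded_singleton_chrom, 2L)
})

test_that("IMD bookkeeping identity holds on random catalogs", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:60, 1)
    df <- cat_df(sample.int(5e5, n),
                 clone = sample(c("a", "b"), n, TRUE),
                 chrom = sample(paste0("chr", 1:4), n, TRUE))
    s <- compute_imds(mutation_catalog(df))
    expect_equal(nrow(s$entries),
                 s$n_total - s$n_excluded_terminal -
                   s$n_excluded_singleton_chrom)
    expect_true(all(s$entries$imd >= 1))
  }
})

test_that("two-group split matches the exact 1-D partition and labels by median", {
  p <- partition_imds(c(100, 101, 99, 100000, 100001))
  expect_equal(sum(p$labels == "proximal"), 3L)
  expect_equal(p$median_proximal, 100)
  expect_equal(p$median_distal, 100000.5)
  expect_lt(p$median_proximal, p$median_distal)

  # agreement with the exhaustive optimal split on log10 values
  set.seed(5)
  for (rep in 1:10) {
    x <- c(stats::rlnorm(30, log(700), 0.6), stats::rlnorm(30, log(8e4), 0.6))
    p2 <- partition_imds(x)
    ex <- exact_two_partition(log10(x))
    expect_equal(p2$labels == "proximal", log10(x) <= ex$boundary)
  }

  expect_error(partition_imds(rep(5000, 10)), "degenerate")
  expect_error(partition_imds(c(10, 20, 30)), "at least 4")
})

test_that("bimodal IMD mixtures are recovered across seeds", {
  # components emulate observed spacings: proximal median 727 bp,
  # distal median 156 kb, moderate spread
  for (seed in 1:10) {
    set.seed(seed)
    truth <- rep(c("proximal", "distal"), each = 500)
    x <- c(stats::rlnorm(500, log(727), 0.8),
           stats::rlnorm(500, log(156000), 0.8))
    p <- partition_imds(x)
    expect_gte(mean(as.character(p$labels) == truth), 0.99)
    expect_lt(abs(p$median_proximal - 727) / 727, 0.2)
    expect_lt(abs(p$median_distal - 156000) / 156000, 0.2)
  }
})

test_that("threshold is the interpolated distal quantile", {
  p <- fake_partition(c(10, 20, 30, 40), seq(1000, 100000, by = 1000))
  expect_equal(derive_threshold(p, 0.99), 1990)
  expect_equal(derive_threshold(p, 0.99),
               brute_quantile(seq(1000, 100000, by = 1000), 0.01))

  # random distal sets against the first-principles order statistic
  set.seed(9)
  for (rep in 1:20) {
    d <- stats::rlnorm(sample(50:200, 1), log(5e4), 0.5)
    p2 <- fake_partition(c(10, 20, 30, 40), d)
    excl <- stats::runif(1, 0.9, 0.999)
    expect_equal(derive_threshold(p2, excl), brute_quantile(d, 1 - excl))
  }

  # constant distal sample collapses to the constant
  p3 <- fake_partition(c(10, 20, 30, 40), rep(50000, 10))
  expect_equal(derive_threshold(p3, 0.99), 50000)

  expect_error(derive_threshold(p, 0), "between 0 and 1")
  expect_error(derive_threshold(p, 1), "between 0 and 1")
})

test_that("cluster calling enforces run size, maximality and strictness", {
  pos5 <- c(100, 600, 1100, 1600, 2100)
  cl <- call_clusters(mutation_catalog(cat_df(pos5)), 1000, 5)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_mutations, 5L)
  expect_equal(cl$start, 100L)
  expect_equal(cl$end, 2100L)
  expect_equal(cl$length, 2000L)

  # 4 < 5: size gate
  expect_equal(nrow(call_clusters(mutation_catalog(cat_df(pos5[1:4])),
                                  1000, 5)), 0L)

  # an internal gap splits the run into two sub-minimum runs
  pos6 <- c(100, 600, 1100, 20000, 20500, 21000)
  expect_equal(nrow(call_clusters(mutation_catalog(cat_df(pos6)), 1000, 5)),
               0L)

  # a gap exactly at the threshold breaks the run (strict inequality)
  pos_tie <- c(100, 1100, 2100, 3100, 4100)
  expect_equal(nrow(call_clusters(mutation_catalog(cat_df(pos_tie)),
                                  1000, 5)), 0L)
  expect_equal(nrow(call_clusters(mutation_catalog(cat_df(pos_tie)),
                                  1001, 5)), 1L)
})

test_that("cluster calls match exhaustive enumeration on random catalogs", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    df <- cat_df(sample.int(2e5, n),
                 clone = sample(c("a", "b"), n, TRUE),
                 chrom = sample(c("chr1", "chr2"), n, TRUE))
    cc <- mutation_catalog(df)
    thr <- sample(c(500, 2000, 10000, 50000), 1)
    minm <- sample(2:6, 1)
    got <- call_clusters(cc, thr, minm)
    want <- brute_clusters(cc, thr, minm)
    expect_equal(as.data.frame(got)[c("clone", "chrom", "start", "end",
                                      "n_mutations")],
                 want, ignore_attr = TRUE)
  }
})

test_that("calling is monotone in threshold and min_mutations", {
  set.seed(12)
  df <- cat_df(sort(sample.int(3e5, 80)))
  cc <- mutation_catalog(df)
  clustered <- function(thr, minm) {
    cl <- call_clusters(cc, thr, minm)
    if (nrow(cl)) sum(cl$n_mutations) else 0L
  }
  thrs <- c(200, 1000, 5000, 20000, 1e5)
  for (minm in c(3, 5)) {
    counts <- vapply(thrs, clustered, integer(1), minm = minm)
    expect_true(all(diff(counts) >= 0))
  }
  for (thr in thrs) {
    counts <- vapply(c(2, 3, 5, 8), function(m) clustered(thr, m), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("calls do not overlap and members are mutually close", {
  set.seed(31)
  for (rep in 1:20) {
    cc <- mutation_catalog(cat_df(sample.int(2e5, 60)))
    cl <- call_clusters(cc, 5000, 3)
    if (!nrow(cl)) next
    for (k in seq_len(nrow(cl))) {
      gaps <- diff(cc$pos[cl$members[[k]]])
      expect_true(all(gaps < 5000))
    }
    # no two calls within a clone share a mutation
    expect_false(any(duplicated(unlist(cl$members))))
  }
})

test_that("cluster burden arithmetic", {
  df <- rbind(cat_df(c(100, 600, 1100, 1600, 2100, 5e5, 6e5, 7e5, 8e5, 9e5),
                     clone = "c1"),
              cat_df(seq(1e5, 1e6, by = 1e5), clone = "c2"))
  cc <- mutation_catalog(df)
  cl <- call_clusters(cc, 1000, 5)
  b <- cluster_burden(cl, cc)
  expect_equal(b$n_mutations, 20L)
  expect_equal(b$n_clustered, 5L)
  expect_equal(b$clones_with_cluster, 1L)
  expect_equal(b$mean_clustered_per_clone, 2.5)
  expect_equal(b$mean_intra_cluster_imd, 500)

  b0 <- cluster_burden(call_clusters(cc, 10, 5), cc)
  expect_equal(b0$n_clusters, 0L)
  expect_equal(b0$n_clustered, 0L)
})

test_that("the kataegis fit object wires the stages together", {
  sim <- shared_sim()
  fit <- kataegis(sim$catalog, genome = shared_genome())
  expect_s3_class(fit, "kataegis")
  expect_equal(fit$partition$threshold, fit$threshold)
  expect_gt(fit$threshold, 0)
  expect_equal(fit$burden$n_mutations, nrow(sim$catalog))
  co <- coef(fit)
  expect_lt(co["median_proximal"], co["median_distal"])

  # predict on the same catalog reproduces the fitted calls
  again <- predict(fit, sim$catalog)
  expect_equal(as.data.frame(again)[c("clone", "chrom", "start", "end")],
               as.data.frame(fit$clusters)[c("clone", "chrom", "start",
                                             "end")])
  # IMD classification respects the k-means boundary direction
  cls <- predict(fit, c(100, 1e6), type = "imd_class")
  expect_equal(as.character(cls), c("proximal", "distal"))

  expect_error(kataegis(cat_df(100)), "insufficient IMDs")

  s <- summary(fit)
  expect_s3_class(s, "summary.kataegis")
  expect_equal(sum(s$per_clone$n_mutations), nrow(sim$catalog))

  # fixed-threshold fit skips the partition
  fit2 <- kataegis(sim$catalog, threshold = 8500)
  expect_null(fit2$partition)
  expect_equal(fit2$threshold, 8500)
})
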