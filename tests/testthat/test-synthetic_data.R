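test_that("the same seed reproduces a sample byte-for-byte", {
  g <- small_genome()
  cfg <- sim_config(g, n_fragments = 20000L, fetal_fraction = 0.1,
                    trisomy = "chr21", seed = 123L)
  s1 <- simulate_sample(cfg)
  s2 <- simulate_sample(cfg)
  expect_identical(s1$fragments, s2$fragments)
  expect_identical(s1$truth, s2$truth)
})

test_that("zero fetal fraction makes a trisomic sample indistinguishable from euploid", {
  g <- small_genome()
  c1 <- sim_config(g, n_fragments = 20000L, fetal_fraction = 0,
                   trisomy = "chr21", seed = 5L)
  c2 <- sim_config(g, n_fragments = 20000L, trisomy = "none", seed = 5L)
  expect_identical(simulate_sample(c1)$fragments,
                   simulate_sample(c2)$fragments)
})

test_that("no simulated fragment falls inside a masked interval", {
  g <- small_genome()
  sm <- simulate_sample(sim_config(g, n_fragments = 50000L, seed = 9L))
  fr <- sm$fragments
  for (i in seq_len(nrow(g$masks))) {
    m <- g$masks[i]
    inside <- fr$chrom == m$chrom & fr$pos > m$start & fr$pos <= m$end
    expect_equal(sum(inside), 0)
  }
})

test_that("trisomy raises the affected chromosome's share by 1 + f/2", {
  g <- small_genome()
  bins <- make_bins(g)
  f <- 0.10
  share <- function(trisomy, seed) {
    cfg <- sim_config(g, n_fragments = 100000L, fetal_fraction = f,
                      trisomy = trisomy, seed = seed)
    fr <- simulate_sample(cfg, bins)$fragments
    mean(fr$chrom == "chr21")
  }
  reps <- 50
  tri <- vapply(seq_len(reps), function(i) share("chr21", 1000L + i),
                numeric(1))
  eup <- vapply(seq_len(reps), function(i) share("none", 1000L + i),
                numeric(1))
  ratio <- mean(tri) / mean(eup)
  # Monte-Carlo s.e. of the ratio is ~0.003 at this depth; 1.05 expected
  # (slightly shrunk by renormalization of the other chromosomes)
  expected <- (1 + f / 2) / (1 + f / 2 * mean(eup))
  expect_equal(ratio, expected, tolerance = 0.01)
})

test_that("maternal CNV bins gain coverage in proportion to copy ratio", {
  g <- small_genome()
  bins <- make_bins(g)
  cnv <- list(chrom = "chr2", start = 10e6, end = 15e6, copy_ratio = 1.5)
  counts_in <- function(seed, cnv_specs) {
    cfg <- sim_config(g, n_fragments = 200000L, cnv_specs = cnv_specs,
                      seed = seed)
    fr <- simulate_sample(cfg, bins)$fragments
    on_cnv <- fr$chrom == "chr2" & fr$pos > 10e6 & fr$pos <= 15e6
    flank <- fr$chrom == "chr2" & fr$pos <= 5e6
    c(cnv = sum(on_cnv), flank = sum(flank))
  }
  with_cnv <- rowMeans(vapply(1:10, counts_in, numeric(2),
                              cnv_specs = list(cnv)))
  without <- rowMeans(vapply(1:10, counts_in, numeric(2),
                             cnv_specs = list()))
  ratio_cnv <- with_cnv["cnv"] / without["cnv"]
  ratio_flank <- with_cnv["flank"] / without["flank"]
  expect_equal(unname(ratio_cnv / ratio_flank), 1.5, tolerance = 0.03)
})

test_that("cohort labels follow the prevalence proportions", {
  g <- small_genome()
  des <- cohort_design(1000, c(chr21 = 0.073, chr18 = 0.025, chr13 = 0.007),
                       base_seed = 77L)
  counts <- table(factor(des$trisomy,
                         levels = c("chr21", "chr18", "chr13", "none")))
  # binomial 99.9% bounds around expectations 73 / 25 / 7
  expect_true(abs(counts[["chr21"]] - 73) < 3.3 * sqrt(1000 * 0.073 * 0.927))
  expect_true(abs(counts[["chr18"]] - 25) < 3.3 * sqrt(1000 * 0.025 * 0.975))
  expect_true(abs(counts[["chr13"]] - 7) < 3.3 * sqrt(1000 * 0.007 * 0.993))
  expect_true(all(des$fetal_fraction >= 0.04 & des$fetal_fraction <= 0.20))
})

test_that("all-zero prevalence yields an all-euploid cohort, reproducibly", {
  g <- small_genome()
  base <- sim_config(g, n_fragments = 2000L, seed = 3L)
  co1 <- simulate_cohort(10, c(chr21 = 0), base)
  expect_true(all(co1$design$trisomy == "none"))
  co2 <- simulate_cohort(10, c(chr21 = 0), base)
  expect_identical(co1$design, co2$design)
  for (i in 1:10)
    expect_identical(co1$samples[[i]]$fragments, co2$samples[[i]]$fragments)
  expect_error(simulate_cohort(0, c(chr21 = 0), base), "positive")
})

test_that("halving depth doubles the median fragment distance", {
  g <- small_genome()
  bins <- make_bins(g)
  med_fd <- function(n) {
    cfg <- sim_config(g, n_fragments = n, seed = 13L)
    ft <- fd_features(simulate_sample(cfg, bins)$fragments, bins)
    stats::median(ft$chrom_med_fd, na.rm = TRUE)
  }
  m1 <- med_fd(50000L)
  m2 <- med_fd(100000L)
  expect_equal(m1 / m2, 2, tolerance = 0.05)
})

test_that("dosage recovery: chromosome-share ratio regresses on f with slope 1/2", {
  g <- small_genome()
  bins <- make_bins(g)
  ff <- seq(0.02, 0.20, length.out = 12)
  logratio <- vapply(seq_along(ff), function(i) {
    cfg <- sim_config(g, n_fragments = 150000L, fetal_fraction = ff[i],
                      trisomy = "chr21", seed = 400L + i)
    fr <- simulate_sample(cfg, bins)$fragments
    ref <- simulate_sample(sim_config(g, n_fragments = 150000L,
                                      seed = 400L + i), bins)$fragments
    log(mean(fr$chrom == "chr21") / mean(ref$chrom == "chr21"))
  }, numeric(1))
  slope <- stats::coef(stats::lm(logratio ~ ff))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.15)
})

test_that("junk records are injected only to be filtered out again", {
  g <- small_genome()
  cfg <- sim_config(g, n_fragments = 10000L, seed = 6L,
                    prop_dup = 0.05, prop_low_mapq = 0.05)
  fr <- simulate_sample(cfg)$fragments
  expect_equal(nrow(fr), 11000)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(fr, f)
  expect_equal(nrow(load_fragments(f)), 10000)
})
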