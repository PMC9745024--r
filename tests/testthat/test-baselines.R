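# two-pass mean/SD oracle, independent of stats::sd
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

mk_count_table <- function(counts, gc = NULL, mapp = NULL,
                           chroms = NULL) {
  n <- length(counts)
  data.table::data.table(
    chrom = if (is.null(chroms)) rep("chr1", n) else chroms,
    start = (seq_len(n) - 1) * 1e6, end = seq_len(n) * 1e6,
    fc = counts,
    gc = if (is.null(gc)) rep(40, n) else gc,
    mappability = if (is.null(mapp)) rep(100, n) else mapp,
    retained = TRUE)
}

test_that("adjustment is the identity when GC and mappability are uniform", {
  bt <- mk_count_table(rep(250, 40))
  adj <- adjust_counts(bt)
  expect_equal(adj$adj_count, rep(250, 40))
  expect_error(adjust_counts(mk_count_table(rep(0, 40))), "all-zero")
})

test_that("a mappability-50 bin is doubled relative to mappability 100", {
  bt <- mk_count_table(rep(100, 20), mapp = c(50, rep(100, 19)))
  adj <- adjust_counts(bt)
  expect_equal(adj$adj_count[1] / adj$adj_count[2], 2)
})

test_that("loess adjustment removes the simulator's quadratic GC bias", {
  g <- small_genome()
  bins <- make_bins(g)
  cfg <- sim_config(g, n_fragments = 300000L, seed = 8L)
  ft <- fd_features(simulate_sample(cfg, bins)$fragments, bins)
  raw <- ft$bin_table[ft$bin_table$retained]
  slope_raw <- stats::coef(stats::lm(fc ~ gc, data = raw))[2]
  adj <- adjust_counts(ft$bin_table)
  ok <- adj[adj$retained]
  slope_adj <- stats::coef(stats::lm(adj_count ~ gc, data = ok))[2]
  # the injected bias produces a clear raw trend; adjustment flattens it
  expect_gt(abs(slope_raw), 5 * abs(slope_adj))
})

test_that("chromosome fractions are shares of the genome-wide sum", {
  counts <- rep(100, 44)
  chroms <- rep(paste0("chr", 1:22), each = 2)
  bt <- mk_count_table(counts, chroms = chroms)
  fr <- chrom_fraction(adjust_counts(bt))
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["chr21"]), 1 / 22)
})

test_that("reference statistics match a two-pass oracle and reject degenerate cohorts", {
  set.seed(10)
  m <- cbind(chr21 = rnorm(100, 0.013, 4e-4),
             chr18 = rnorm(100, 0.025, 6e-4),
             chr13 = rnorm(100, 0.031, 7e-4))
  ref <- build_reference(m, "z")
  for (tg in colnames(m)) {
    expect_equal(ref$mean[[tg]], sum(m[, tg]) / 100)
    expect_equal(ref$sd[[tg]], two_pass_sd(m[, tg]))
  }
  expect_equal(ref$n, 100)
  expect_error(build_reference(m[1, , drop = FALSE], "z"), "at least 2")
  const <- matrix(0.013, 10, 3,
                  dimnames = list(NULL, c("chr21", "chr18", "chr13")))
  expect_error(build_reference(const, "z"), "degenerate")
})

test_that("reference cohort standardizes itself to mean 0, SD 1", {
  set.seed(12)
  m <- cbind(chr21 = rnorm(200, 0.013, 4e-4),
             chr18 = rnorm(200, 0.025, 6e-4),
             chr13 = rnorm(200, 0.031, 7e-4))
  ref <- build_reference(m, "z")
  z <- vapply(seq_len(200), function(i)
    z_score(as.list(m[i, ]), ref, "chr21")$score, numeric(1))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(z), 1, tolerance = 1e-10)
})

test_that("Z and NCV scores ignore a global rescaling of the counts", {
  g <- small_genome()
  bins <- make_bins(g)
  cfg <- sim_config(g, n_fragments = 100000L, seed = 14L)
  ft <- fd_features(simulate_sample(cfg, bins)$fragments, bins)
  adj1 <- adjust_counts(ft$bin_table)
  bt2 <- data.table::copy(ft$bin_table)
  bt2[, fc := fc * 5L]
  adj2 <- adjust_counts(bt2)
  f1 <- chrom_fraction(adj1); f2 <- chrom_fraction(adj2)
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_equal(ncv_ratio(adj1, "chr21"), ncv_ratio(adj2, "chr21"),
               tolerance = 1e-12)
})

test_that("a sample at the reference mean scores 0 and is negative; 2.57 is negative", {
  ref <- structure(list(method = "z", mean = c(chr21 = 0.013),
                        sd = c(chr21 = 5e-4), n = 994),
                   class = "ReferenceStats")
  at_mean <- z_score(c(chr21 = 0.013), ref, "chr21")
  expect_equal(at_mean$score, 0)
  expect_false(at_mean$call)
  # the borderline clinical false negative: score below 3 is not called
  s257 <- z_score(c(chr21 = 0.013 + 2.57 * 5e-4), ref, "chr21")
  expect_equal(s257$score, 2.57)
  expect_false(s257$call)
  # boundary: a score of exactly 3 is called positive
  ref0 <- structure(list(method = "z", mean = c(chr21 = 0),
                         sd = c(chr21 = 5e-4), n = 994),
                    class = "ReferenceStats")
  expect_true(z_score(c(chr21 = 1.5e-3), ref0, "chr21")$call)
})

test_that("NCV uses the designated denominators (manual-sum oracle)", {
  counts <- seq(100, by = 10, length.out = 22)
  bt <- mk_count_table(counts, chroms = paste0("chr", 1:22))
  adj <- adjust_counts(bt)
  at <- adj[adj$retained]
  byc <- stats::setNames(at$adj_count, at$chrom)
  expect_equal(ncv_ratio(adj, "chr21"), byc[["chr21"]] / byc[["chr9"]])
  expect_equal(ncv_ratio(adj, "chr18"), byc[["chr18"]] / byc[["chr8"]])
  expect_equal(ncv_ratio(adj, "chr13"),
               byc[["chr13"]] / sum(byc[paste0("chr", 2:6)]))
  ref <- structure(list(method = "ncv",
                        mean = c(chr21 = ncv_ratio(adj, "chr21")),
                        sd = c(chr21 = 0.01), n = 994),
                   class = "ReferenceStats")
  expect_equal(ncv_score(adj, ref, "chr21")$score, 0)
  expect_false(ncv_score(adj, ref, "chr21")$call)
})

test_that("z-score grows monotonically with fetal fraction", {
  g <- small_genome()
  bins <- make_bins(g)
  frac_at <- function(f, seed) {
    cfg <- sim_config(g, n_fragments = 150000L, fetal_fraction = f,
                      trisomy = "chr21", seed = seed)
    ft <- fd_features(simulate_sample(cfg, bins)$fragments, bins)
    chrom_fraction(adjust_counts(ft$bin_table))
  }
  eup <- t(vapply(1:25, function(i) frac_at(0, 600L + i),
                  numeric(22)))
  ref <- build_reference(eup, "z")
  ff <- c(0.04, 0.10, 0.16)
  z <- vapply(seq_along(ff), function(i) {
    mean(vapply(1:4, function(r)
      z_score(frac_at(ff[i], 700L + 10L * i + r), ref, "chr21")$score,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(z) > 0))
})

test_that("reference stats survive a JSON round-trip", {
  ref <- build_reference(cbind(chr21 = rnorm(10, 0.013, 1e-4),
                               chr18 = rnorm(10, 0.025, 1e-4),
                               chr13 = rnorm(10, 0.031, 1e-4)), "ncv")
  f <- withr::local_tempfile(fileext = ".json")
  write_reference(ref, f)
  back <- read_reference(f)
  expect_equal(back$mean, ref$mean)
  expect_equal(back$sd, ref$sd)
  expect_equal(back$method, "ncv")
})
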