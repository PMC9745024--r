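# independent OLS + MSE oracle used against select_icc
ols_mse <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  b <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  a <- ym - b * xm
  mean((y - (a + b * x))^2)
}

test_that("a perfectly predictive candidate ranks first with infinite score", {
  set.seed(1)
  chroms <- c("chr21", "chr1", "chr2", "chr3", "chr4")
  m <- matrix(runif(20 * 5, 2000, 3000), 20, 5,
              dimnames = list(NULL, chroms))
  m[, "chr1"] <- m[, "chr21"]  # reciprocal values equal in every sample
  sel <- select_icc(m, "chr21")
  expect_equal(sel$icc[1], "chr1")
  expect_equal(sel$score[["chr1"]], Inf)
})

test_that("ICC selection orders candidates by regression MSE (oracle check)", {
  set.seed(2)
  chroms <- c("chr21", "chr1", "chr2", "chr3", "chr4")
  base <- runif(20, 1 / 3000, 1 / 2000)  # reciprocal median FD of the target
  m <- matrix(0, 20, 5, dimnames = list(NULL, chroms))
  m[, "chr21"] <- 1 / base
  noise <- c(chr1 = 1e-6, chr2 = 1e-5, chr3 = 1e-4, chr4 = 1e-3)
  for (cn in names(noise))
    m[, cn] <- 1 / (2 * base + rnorm(20, 0, noise[cn]))
  sel <- select_icc(m, "chr21")
  expect_equal(sel$icc, c("chr1", "chr2", "chr3"))
  # scores agree with a hand-rolled OLS + MSE
  for (cn in names(noise)) {
    mse <- ols_mse(1 / m[, cn], 1 / m[, "chr21"])
    expect_equal(sel$score[[cn]], -log10(mse), tolerance = 1e-8)
  }
})

test_that("ICC selection needs a real cohort and enough candidates", {
  m1 <- matrix(runif(5, 2000, 3000), 1, 5,
               dimnames = list(NULL, c("chr21", "chr1", "chr2", "chr3",
                                       "chr4")))
  expect_error(select_icc(m1, "chr21"), "at least 2")
  m2 <- matrix(runif(20 * 3, 2000, 3000), 20, 3,
               dimnames = list(NULL, c("chr21", "chr1", "chr2")))
  expect_error(select_icc(m2, "chr21"), "fewer than 3")
})

test_that("selected controls are genuine autosomal controls on simulated data", {
  fe <- small_cohort_features()
  sel <- select_icc(fe$chrom_med, "chr21")
  expect_length(sel$icc, 3)
  expect_false("chr21" %in% sel$icc)
  expect_false(any(c("chr13", "chr18") %in% sel$icc))
})

test_that("median normalization is exact on constant input and scale-invariant", {
  g <- flat_genome(n_chrom = 4, len = 31e6)
  b <- make_bins(g)
  bt <- data.table::as.data.table(b)
  bt[, `:=`(fc = 100L, n_fd = 100L, fd_mean = 2500, fd_median = 2000,
            fd_iqr = 1800, usable = TRUE)]
  data.table::setattr(bt, "width", 1e6)
  nt <- normalize_and_trim(bt, c("chr1", "chr2"))
  expect_equal(nt$global_median, 2000)
  expect_true(all(unlist(nt$values$chr1$median) == 1))
  expect_true(all(unlist(nt$values$chr1$mean) == 2500 / 2000))

  # doubling every FD leaves normalized values unchanged
  bt2 <- data.table::copy(bt)
  bt2[, `:=`(fd_mean = fd_mean * 2, fd_median = fd_median * 2,
             fd_iqr = fd_iqr * 2)]
  nt2 <- normalize_and_trim(bt2, c("chr1", "chr2"))
  expect_equal(nt2$values, nt$values)
})

test_that("trimming removes floor(0.1 n) bins per tail and preserves order", {
  g <- flat_genome(n_chrom = 1, len = 30e6)
  b <- make_bins(g)
  bt <- data.table::as.data.table(b)
  set.seed(3)
  vals <- sample(seq(1000, 3900, by = 100))  # 30 distinct values
  bt[, `:=`(fc = 100L, n_fd = 100L, fd_mean = vals, fd_median = vals,
            fd_iqr = vals, usable = TRUE)]
  data.table::setattr(bt, "width", 1e6)
  nt <- normalize_and_trim(bt, "chr1")
  out <- nt$values$chr1$median
  expect_length(out, 24)  # 30 - 3 - 3
  # survivors keep genomic order: they appear as a subsequence of the input
  norm_in <- vals / nt$global_median
  expect_equal(out, norm_in[norm_in %in% out])
  # never more than 20% of a chromosome's bins are removed
  expect_gte(length(out), ceiling(0.8 * length(vals)))
})

test_that("a constant sequence renders as one horizontal line of full width", {
  img <- render_trs(rep(1, 10), list(rep(1, 12), rep(1, 8), rep(1, 15)))
  expect_s3_class(img, "TRSImage")
  expect_equal(dim(img), c(200, 400))
  lit_rows <- which(rowSums(unclass(img)) > 0)
  expect_length(lit_rows, 1)
  # y = 1.0 in [0.5, 1.5] maps to the middle row band
  expect_equal(lit_rows, 100)
  expect_equal(sum(unclass(img)[lit_rows, ] > 0), 400)
})

test_that("rendering is deterministic and bounded for arbitrary inputs", {
  set.seed(4)
  tv <- runif(9, 0.4, 1.6)  # includes values outside the clip range
  icc <- lapply(c(20, 25, 30), function(n) runif(n, 0.8, 1.2))
  i1 <- render_trs(tv, icc)
  i2 <- render_trs(tv, icc)
  expect_identical(i1, i2)
  expect_true(all(unclass(i1) %in% c(0, 1)))
  expect_error(render_trs(numeric(0), icc), "empty")
})

test_that("a trisomic level shift appears in the TC segments at positions 2, 4, 6", {
  set.seed(5)
  tc <- rnorm(10, 0.90, 0.01)   # trisomy: more fragments, smaller distances
  icc <- lapply(c(20, 25, 30), function(n) rnorm(n, 1, 0.01))
  img <- render_trs(tc, icc)
  seg <- attr(img, "segments")
  mean_row <- function(from, to) {
    sub <- unclass(img)[, from:to, drop = FALSE]
    mean(apply(sub, 2, function(col) mean(which(col > 0))))
  }
  rows <- vapply(seq_len(6), function(i)
    mean_row(seg$col_from[i], seg$col_to[i]), numeric(1))
  # lower normalized FD -> line lower in the image -> larger row index
  expect_true(all(rows[c(2, 4, 6)] > rows[c(1, 3, 5)] + 10))
  expect_equal(seg$role, rep(c("ICC", "TC"), 3))
})

test_that("euploid TC segments sit at the same level as ICC segments", {
  fe <- small_cohort_features()
  sel <- select_icc(fe$chrom_med, "chr21")
  seg_rows <- matrix(NA_real_, length(fe$bin_tables), 2)
  for (i in seq_along(fe$bin_tables)) {
    img <- trs_image(fe$bin_tables[[i]], sel, representative = "median")
    seg <- attr(img, "segments")
    row_of <- function(j) {
      sub <- unclass(img)[, seg$col_from[j]:seg$col_to[j], drop = FALSE]
      mean(apply(sub, 2, function(col) mean(which(col > 0))))
    }
    rows <- vapply(seq_len(6), row_of, numeric(1))
    seg_rows[i, ] <- c(mean(rows[c(1, 3, 5)]), mean(rows[c(2, 4, 6)]))
  }
  tst <- stats::t.test(seg_rows[, 1], seg_rows[, 2], paired = TRUE)
  expect_gt(tst$p.value, 0.01)
})

test_that("PNG export writes an 8-bit grayscale image of the right size", {
  img <- render_trs(rep(1, 10), list(rep(1, 12), rep(1, 8), rep(1, 15)))
  f <- withr::local_tempfile(fileext = ".png")
  write_trs_png(img, f)
  back <- png::readPNG(f)
  expect_equal(dim(back), c(200, 400))
  expect_equal(as.vector(back), as.vector(unclass(img)))
  # lossless TSV matrix round-trip
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_trs_matrix(img, f2)
  m2 <- read_trs_matrix(f2)
  expect_equal(dim(m2), dim(img))
  expect_equal(as.vector(unclass(m2)), as.vector(unclass(img)))
})
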