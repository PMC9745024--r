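#' GC and mappability adjustment of bin counts
#'
#' Count-based callers need depth corrected for GC amplification bias and
#' alignability. The GC bias curve is estimated by loess of count on GC
#' percent over the retained bins, normalized to mean 1; counts are divided
#' by the fitted bias and by `mappability/100`.
#'
#' @param bin_table `data.table` with `fc` (or `count`), `gc`,
#'   `mappability` and `retained` columns (a `BinFDTable` works).
#' @param span loess span of the GC fit.
#' @return the table with an `adj_count` column on retained bins.
#' @export
adjust_counts <- function(bin_table, span = 0.75) {
  bt <- copy(as.data.table(bin_table))
  cnt_col <- if ("fc" %in% names(bt)) "fc" else "count"
  r <- bt$retained
  cnt <- as.numeric(bt[[cnt_col]])
  if (all(cnt[r] == 0)) stop("all-zero counts: nothing to adjust")
  bias <- rep(NA_real_, nrow(bt))
  gcr <- bt$gc[r]
  if (length(unique(gcr)) > 3) {
    fit <- stats::loess(cnt[r] ~ gcr, span = span, degree = 2,
                        family = "symmetric")
    b <- stats::predict(fit, gcr)
    b[!is.finite(b) | b <= 0] <- mean(cnt[r])
  } else {
    b <- rep(mean(cnt[r]), sum(r))
  }
  bias[r] <- b / mean(b)
  bt[, adj_count := NA_real_]
  bt[r, adj_count := cnt[r] / bias[r] / (mappability / 100)]
  bt[]
}

#' Per-chromosome normalized fraction
#'
#' The conventional count statistic: each chromosome's share of the
#' genome-wide adjusted count.
#'
#' @param adj_table output of [adjust_counts()].
#' @return named numeric vector summing to 1 over chromosomes.
#' @export
chrom_fraction <- function(adj_table) {
  at <- as.data.table(adj_table)[retained & !is.na(adj_count)]
  tot <- sum(at$adj_count)
  if (tot <= 0) stop("zero genome-wide adjusted count")
  s <- at[, .(v = sum(adj_count)), by = chrom]
  stats::setNames(s$v / tot, s$chrom)
}

# NCV denominator sets
.ncv_denominator <- function(target) {
  switch(target,
         chr21 = "chr9",
         chr18 = "chr8",
         chr13 = paste0("chr", 2:6),
         stop("no NCV denominator defined for ", target))
}

#' Per-chromosome NCV ratio
#'
#' The normalized chromosomal value uses a designated denominator set for
#' each target: chr9 for chr21, chr8 for chr18 and the sum of chr2-chr6
#' for chr13.
#'
#' @param adj_table output of [adjust_counts()].
#' @param target target chromosome.
#' @return scalar ratio target count / denominator count.
#' @export
ncv_ratio <- function(adj_table, target) {
  at <- as.data.table(adj_table)[retained & !is.na(adj_count)]
  den_chr <- .ncv_denominator(target)
  num <- sum(at[chrom == target, adj_count])
  den <- sum(at[chrom %in% den_chr, adj_count])
  if (den <= 0) stop("zero NCV denominator for ", target)
  num / den
}

#' Build euploid reference statistics
#'
#' Mean and SD per target chromosome of the normalized value across the
#' euploid reference cohort: chromosome fractions for the Z method, NCV
#' ratios for the NCV method.
#'
#' @param cohort_values for `method = "z"`, a matrix/data.frame of
#'   chromosome fractions (samples x chromosomes); for `"ncv"`, a
#'   samples x targets matrix of NCV ratios.
#' @param method `"z"` or `"ncv"`.
#' @param targets target chromosomes.
#' @return list of class `ReferenceStats`: `method`, `mean`, `sd` (named by
#'   target), `n`.
#' @export
build_reference <- function(cohort_values, method = c("z", "ncv"),
                            targets = c("chr21", "chr18", "chr13")) {
  method <- match.arg(method)
  m <- as.matrix(cohort_values)
  if (nrow(m) < 2) stop("reference cohort must have at least 2 samples")
  targets <- intersect(targets, colnames(m))
  mu <- colMeans(m[, targets, drop = FALSE])
  sdv <- apply(m[, targets, drop = FALSE], 2, stats::sd)
  if (any(sdv == 0))
    stop("degenerate reference: zero SD for ",
         paste(targets[sdv == 0], collapse = ", "))
  structure(list(method = method, mean = mu, sd = sdv, n = nrow(m)),
            class = "ReferenceStats")
}

#' Z-score call for one target chromosome
#'
#' @param fractions named chromosome-fraction vector of the sample.
#' @param ref `ReferenceStats` with `method = "z"`.
#' @param target target chromosome.
#' @param cutoff positive-call threshold (>= comparison; default 3).
#' @return list with `score` and logical `call`.
#' @export
z_score <- function(fractions, ref, target, cutoff = 3) {
  stopifnot(inherits(ref, "ReferenceStats"), ref$method == "z")
  s <- (fractions[[target]] - ref$mean[[target]]) / ref$sd[[target]]
  list(score = s, call = s >= cutoff)
}

#' NCV-score call for one target chromosome
#'
#' @param adj_table adjusted bin counts of the sample
#'   ([adjust_counts()] output), or a precomputed named ratio vector.
#' @param ref `ReferenceStats` with `method = "ncv"`.
#' @inheritParams z_score
#' @return list with `score` and logical `call`.
#' @export
ncv_score <- function(adj_table, ref, target, cutoff = 3) {
  stopifnot(inherits(ref, "ReferenceStats"), ref$method == "ncv")
  ratio <- if (is.numeric(adj_table)) adj_table[[target]]
           else ncv_ratio(adj_table, target)
  s <- (ratio - ref$mean[[target]]) / ref$sd[[target]]
  list(score = s, call = s >= cutoff)
}

#' Write reference statistics as JSON
#' @param ref a `ReferenceStats`.
#' @param path output path.
#' @export
write_reference <- function(ref, path) {
  jsonlite::write_json(list(method = ref$method, mean = as.list(ref$mean),
                            sd = as.list(ref$sd), n = ref$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read reference statistics from JSON
#' @param path JSON path written by [write_reference()].
#' @return a `ReferenceStats`.
#' @export
read_reference <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(method = j$method, mean = unlist(j$mean),
                 sd = unlist(j$sd), n = j$n),
            class = "ReferenceStats")
}
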