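#' Select internal control chromosomes (ICC) for a target
#'
#' For each candidate autosome (all autosomes except the target and the
#' clinically tested chromosomes 13/18/21), an ordinary least-squares
#' regression of the target's reciprocal median FD on the candidate's is
#' fitted across the euploid reference samples; candidates are ranked by
#' `-log10(MSE)` of the fit and the top three become the ICC set. A perfect
#' fit (MSE 0) scores `+Inf` and ranks first; ties break by genome
#' chromosome order.
#'
#' @param ref_chrom_med matrix or data.frame of chromosome-level median FD,
#'   samples in rows, chromosomes in columns (as from [fd_features()]'s
#'   `chrom_med_fd` stacked across the reference cohort).
#' @param target target chromosome name (`"chr21"`, `"chr18"`, `"chr13"`).
#' @param exclude chromosomes never eligible as controls (default the three
#'   clinical targets); sex chromosomes are always ineligible.
#' @return list of class `ICCSelection`: `target`, `icc` (three chromosome
#'   names, best first), `score` (named `-log10(MSE)` for all candidates).
#' @export
select_icc <- function(ref_chrom_med, target,
                       exclude = c("chr13", "chr18", "chr21")) {
  m <- as.matrix(ref_chrom_med)
  if (nrow(m) < 2) stop("ICC regression needs at least 2 reference samples")
  if (!target %in% colnames(m)) stop("target ", target, " not in cohort table")
  cand <- setdiff(colnames(m), unique(c(target, exclude)))
  cand <- cand[!sub("^chr", "", cand) %in% c("X", "Y", "M", "MT")]
  if (length(cand) < 3) stop("fewer than 3 eligible control candidates")
  y <- 1 / m[, target]
  score <- vapply(cand, function(cn) {
    x <- 1 / m[, cn]
    fit <- stats::lm.fit(cbind(1, x), y)
    mse <- mean(fit$residuals^2)
    # a fit exact to machine precision counts as MSE 0
    if (mse <= mean(y^2) * .Machine$double.eps) Inf else -log10(mse)
  }, numeric(1))
  ord <- order(-score, match(cand, colnames(m)))
  structure(list(target = target, icc = cand[ord][1:3], score = score),
            class = "ICCSelection")
}

#' Median-normalize FD representatives and trim extreme bins
#'
#' The sample's `global_median` is the median over all retained, usable
#' bins genome-wide of the per-bin FD median. Every representative value
#' (per-bin mean, median and IQR) is divided by it, which removes
#' between-sample depth differences (halving the depth doubles every FD).
#' Then, separately for the target and each ICC chromosome and separately
#' per representative, the `floor(0.10 * n)` lowest and highest bins by
#' normalized value are dropped; survivors keep their genomic order.
#'
#' @param fd_table a `BinFDTable`.
#' @param chroms chromosomes to produce sequences for (target + ICC set).
#' @param trim fraction trimmed from each tail (default 0.10).
#' @return list with `global_median` and `values`: per chromosome, a list
#'   of numeric vectors `mean`, `median`, `iqr` in genomic order.
#' @export
normalize_and_trim <- function(fd_table, chroms, trim = 0.10) {
  ft <- as.data.table(fd_table)[retained & usable]
  if (!nrow(ft)) stop("no retained, usable bins in sample")
  gm <- stats::median(ft$fd_median)
  if (!is.finite(gm) || gm == 0) stop("degenerate sample: global median FD is 0")
  reps <- c(mean = "fd_mean", median = "fd_median", iqr = "fd_iqr")
  values <- list()
  for (cn in chroms) {
    cb <- ft[chrom == cn][order(start)]
    if (!nrow(cb)) stop("no usable bins on chromosome ", cn)
    values[[cn]] <- lapply(reps, function(col) {
      v <- cb[[col]] / gm
      k <- floor(trim * length(v))
      if (k > 0) {
        ord <- order(v)
        drop <- c(ord[seq_len(k)], ord[seq.int(length(v) - k + 1, length(v))])
        v <- v[-drop]
      }
      v
    })
  }
  list(global_median = gm, values = values)
}

#' Render a target-repeat-stacking (TRS) image
#'
#' Concatenates six segments — ICC1, TC, ICC2, TC, ICC3, TC — of one
#' representative's trimmed normalized values and draws them as a single
#' polyline on a 200 x 400 grayscale raster (rows x columns). The x axis is
#' the index within the concatenation rescaled to the 400 columns; the y
#' axis maps `y_range` (default \[0.5, 1.5\], values clipped) linearly to
#' rows bottom-to-top. The line is 1 px, intensity 1 on background 0, drawn
#' with an integer Bresenham walk so rendering is bit-exact across
#' platforms.
#'
#' @param target_values numeric vector: trimmed normalized values of the
#'   target chromosome (one representative).
#' @param icc_values list of three numeric vectors, best ICC first.
#' @param y_range fixed y limits; a fixed range (not per-image min-max)
#'   preserves level shifts between TC and ICC across samples.
#' @param width,height raster size in px.
#' @return `height x width` numeric matrix in \[0, 1\], class `TRSImage`,
#'   with attribute `segments` describing the layout.
#' @export
render_trs <- function(target_values, icc_values, y_range = c(0.5, 1.5),
                       width = 400L, height = 200L) {
  if (!length(target_values)) stop("empty target segment")
  if (length(icc_values) != 3 || any(!vapply(icc_values, length, 1L)))
    stop("need three non-empty ICC segments")
  segs <- list(icc_values[[1]], target_values, icc_values[[2]],
               target_values, icc_values[[3]], target_values)
  seg_role <- rep(c("ICC", "TC"), 3)
  v <- unlist(segs, use.names = FALSE)
  n <- length(v)
  # x: index 1..n mapped across the full width; y: clip then affine to rows
  xs <- if (n == 1) rep(1L, 2) else
    as.integer(round(1 + (seq_len(n) - 1) * (width - 1) / (n - 1)))
  vc <- pmin(pmax(v, y_range[1]), y_range[2])
  ys <- as.integer(round(height - (vc - y_range[1]) /
                           (y_range[2] - y_range[1]) * (height - 1)))
  img <- matrix(0, nrow = height, ncol = width)
  if (n == 1) {
    img[ys[1], ] <- 1
  } else {
    for (i in seq_len(n - 1)) {
      img <- .draw_segment(img, xs[i], ys[i], xs[i + 1], ys[i + 1])
    }
  }
  lens <- vapply(segs, length, 1L)
  bounds <- cumsum(c(0, lens))
  seg_cols <- lapply(seq_along(segs), function(i) {
    idx <- seq.int(bounds[i] + 1, bounds[i + 1])
    range(xs[idx])
  })
  structure(img, class = "TRSImage",
            segments = data.table(position = seq_along(segs), role = seg_role,
                                  n_bins = lens,
                                  col_from = vapply(seg_cols, `[`, 1, i = 1),
                                  col_to = vapply(seg_cols, `[`, 1, i = 2)))
}

# integer Bresenham line; endpoints inclusive
.draw_segment <- function(img, x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  x <- x0; y <- y0
  repeat {
    img[y, x] <- 1
    if (x == x1 && y == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  img
}

#' Build the TRS image of one sample for one target and representative
#'
#' @param fd_table the sample's `BinFDTable`.
#' @param icc an `ICCSelection` for the target.
#' @param representative `"mean"`, `"median"` or `"iqr"`.
#' @param ... passed to [render_trs()].
#' @return a `TRSImage`.
#' @export
trs_image <- function(fd_table, icc,
                      representative = c("median", "mean", "iqr"), ...) {
  representative <- match.arg(representative)
  nt <- normalize_and_trim(fd_table, c(icc$target, icc$icc))
  render_trs(nt$values[[icc$target]][[representative]],
             lapply(icc$icc, function(cn) nt$values[[cn]][[representative]]),
             ...)
}

#' Write a TRS image as an 8-bit grayscale PNG
#'
#' The PNG is a faithful export of the data matrix (no axes or decoration);
#' for lossless numeric storage use [write_fd_table()]-style TSV of the
#' matrix instead.
#'
#' @param img a `TRSImage`.
#' @param path output path.
#' @export
write_trs_png <- function(img, path) {
  png::writePNG(unclass(img), path)
  invisible(path)
}

#' Write a TRS image as a lossless numeric TSV matrix
#'
#' 200 rows x 400 tab-separated columns, no header — the exact training
#' tensor.
#'
#' @param img a `TRSImage`.
#' @param path output path.
#' @export
write_trs_matrix <- function(img, path) {
  utils::write.table(unclass(img), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TRS matrix written by [write_trs_matrix()]
#' @param path TSV path.
#' @return numeric matrix of class `TRSImage`.
#' @export
read_trs_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  structure(m, class = "TRSImage")
}
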