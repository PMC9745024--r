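#' Positional shifting of single-end fragments
#'
#' Single-end reads define a fragment position differently on the two
#' strands, so positions are harmonized before distances are computed: a
#' forward read's leftmost coordinate is shifted right by `shift` bp, a
#' reverse read's rightmost coordinate (`pos + read_len - 1`) is shifted
#' left by `shift` bp. Shifted positions may legally fall just outside the
#' chromosome ends; binning drops them later.
#'
#' @param fragments `data.table` of filtered fragments (see
#'   [load_fragments()]); must have `chrom`, `pos`, `strand` and either a
#'   `read_len` column or the `read_len` argument.
#' @param shift shift in bp (default 80).
#' @param read_len fallback read length if the table has no column.
#' @return named list, one sorted numeric vector of shifted positions per
#'   chromosome (class `ShiftedPositions`).
#' @export
shift_positions <- function(fragments, shift = 80, read_len = 75L) {
  fr <- as.data.table(fragments)
  rl <- if ("read_len" %in% names(fr)) fr$read_len else
    rep_len(read_len, nrow(fr))
  fwd <- fr$strand == "+"
  sp <- numeric(nrow(fr))
  sp[fwd] <- fr$pos[fwd] + shift
  sp[!fwd] <- (fr$pos[!fwd] + rl[!fwd] - 1) - shift
  grp <- data.table(chrom = fr$chrom, sp = sp)
  agg <- grp[, .(p = list(sort(sp, method = "radix"))), by = chrom]
  out <- stats::setNames(agg$p, agg$chrom)
  structure(out, class = "ShiftedPositions")
}

#' Fragment distances (FD)
#'
#' FD is the difference in shifted positions between adjacent fragments:
#' the successive differences of each chromosome's sorted position vector.
#' A chromosome with fewer than two positions yields an empty distance
#' vector.
#'
#' @param shifted a `ShiftedPositions` object.
#' @return named list of non-negative numeric distance vectors, one per
#'   chromosome, each of length `n_positions - 1`.
#' @export
compute_fd <- function(shifted) {
  lapply(shifted, function(p) if (length(p) < 2) numeric(0) else diff(p))
}

#' Per-bin fragment-distance summaries
#'
#' Assigns each distance to the bin containing the left member of its
#' adjacent pair (so every distance lands in exactly one bin), counts the
#' shifted positions per bin (FC), and summarizes each bin's distance
#' sample by mean, median and IQR. Quartiles use linear interpolation
#' between order statistics (R's default quantile type 7). Bins with fewer
#' than `min_fd_n` distances are flagged unusable: their statistics would
#' be dominated by sampling noise.
#'
#' @param shifted a `ShiftedPositions` object.
#' @param distances output of [compute_fd()] on the same object.
#' @param bins a `BinSet`.
#' @param min_fd_n minimum number of distances for a usable bin.
#' @return `data.table`: the bin grid joined with `fc`, `n_fd`, `fd_mean`,
#'   `fd_median`, `fd_iqr`, `usable` (class `BinFDTable`).
#' @export
bin_fd_stats <- function(shifted, distances, bins, min_fd_n = 10L) {
  bins <- as.data.table(bins)
  width <- attr(bins, "width")
  if (is.null(width)) width <- bins$end[1] - bins$start[1]
  pieces_fc <- list(); pieces_fd <- list()
  for (cn in names(shifted)) {
    p <- shifted[[cn]]
    if (!length(p)) next
    pieces_fc[[cn]] <- data.table(chrom = cn, bin = floor((p - 1) / width))
    d <- distances[[cn]]
    if (length(d)) {
      left <- p[seq_along(d)]
      pieces_fd[[cn]] <- data.table(chrom = cn,
                                    bin = floor((left - 1) / width),
                                    d = as.numeric(d))
    }
  }
  out <- copy(bins)
  out[, bin := floor(start / width)]
  if (length(pieces_fc)) {
    fc_dt <- rbindlist(pieces_fc)[, .(fc = .N), by = .(chrom, bin)]
    out <- merge(out, fc_dt, by = c("chrom", "bin"), all.x = TRUE)
  } else out[, fc := NA_integer_]
  if (length(pieces_fd)) {
    fd_dt <- rbindlist(pieces_fd)[, .(
      n_fd = .N, fd_mean = mean(d),
      fd_median = as.numeric(stats::median(d)),
      fd_iqr = as.numeric(diff(stats::quantile(d, c(0.25, 0.75))))),
      by = .(chrom, bin)]
    out <- merge(out, fd_dt, by = c("chrom", "bin"), all.x = TRUE)
  } else out[, `:=`(n_fd = NA_integer_, fd_mean = NA_real_,
                    fd_median = NA_real_, fd_iqr = NA_real_)]
  out[is.na(fc), fc := 0L]
  out[is.na(n_fd), n_fd := 0L]
  out[, usable := n_fd >= min_fd_n]
  setorderv(out, c("chrom", "start"))
  out[, bin := NULL]
  setcolorder(out, c("bin_id", "chrom", "start", "end"))
  setattr(out, "width", width)
  setattr(out, "class", c("BinFDTable", class(out)))
  out[]
}

#' Chromosome-level median fragment distance
#'
#' Pools the distances whose left position lies in a retained, usable bin
#' of each chromosome and takes the median. The reciprocal of this value is
#' the quantity used for internal-control-chromosome selection.
#'
#' @inheritParams bin_fd_stats
#' @param fd_table the `BinFDTable` for the sample (for the usable flags).
#' @return named numeric vector, median FD per chromosome (NA where no
#'   usable distances exist).
#' @export
chrom_fd_median <- function(shifted, distances, fd_table) {
  ft <- as.data.table(fd_table)
  width <- attr(fd_table, "width")
  if (is.null(width)) width <- ft$end[1] - ft$start[1]
  ok <- ft[retained & usable, .(chrom, bin = floor(start / width))]
  chroms <- unique(ft$chrom)
  out <- stats::setNames(rep(NA_real_, length(chroms)), chroms)
  for (cn in chroms) {
    d <- distances[[cn]]
    if (!length(d)) next
    left <- shifted[[cn]][seq_along(d)]
    keep <- floor((left - 1) / width) %in% ok[chrom == cn, bin]
    if (any(keep)) out[cn] <- stats::median(d[keep])
  }
  out
}

#' Full fragment-distance feature extraction for one sample
#'
#' Convenience wrapper: shift, distance, per-bin summaries and
#' chromosome-level medians in one call.
#'
#' @param fragments filtered fragment table.
#' @param bins a `BinSet`.
#' @param shift positional shift in bp.
#' @param min_fd_n usability floor for per-bin statistics.
#' @return list with `bin_table` (`BinFDTable`) and `chrom_med_fd`
#'   (named vector).
#' @export
fd_features <- function(fragments, bins, shift = 80, min_fd_n = 10L) {
  sh <- shift_positions(fragments, shift = shift)
  fd <- compute_fd(sh)
  bt <- bin_fd_stats(sh, fd, bins, min_fd_n = min_fd_n)
  list(bin_table = bt, chrom_med_fd = chrom_fd_median(sh, fd, bt))
}

#' Write a per-bin FD table as TSV
#' @param fd_table a `BinFDTable`.
#' @param path output path.
#' @export
write_fd_table <- function(fd_table, path) {
  fwrite(as.data.table(fd_table), path, sep = "\t")
  invisible(path)
}
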