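#' @useDynLib aidnipt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "chrom", "pos", "strand", "mapq", "dup", "start", "end", "bin_id",
  "gc", "mappability", "masked", "low_mapp", "gc_excluded", "retained",
  "usable", "fc", "fd_mean", "fd_median", "fd_iqr", "bin", "d", "value",
  "intensity", "n_fd", "read_len", "adj_count", "sample_id", ".", "N", "J"
))

#' Genome build definition
#'
#' Bundles everything the binning and simulation code needs to know about a
#' genome: ordered chromosome names and lengths, excluded (masked) intervals
#' such as centromeres and telomeres, and per-1-Mb-bin GC and mappability
#' tracks.
#'
#' @param chrom_lengths named numeric vector, base pairs per chromosome, in
#'   the desired chromosome order.
#' @param masks `data.frame`/`data.table` with columns `chrom`, `start`,
#'   `end` (0-based half-open, BED convention) of regions to exclude.
#' @param gc named list (or `data.table` with `chrom`, `start`, `gc`):
#'   GC percent per bin, one value per full bin of each chromosome.
#' @param mappability same layout as `gc`, mappability percent per bin.
#' @param bin_width bin width in bp the tracks are defined on (default 1e6).
#'
#' @return an object of class `GenomeBuild`.
#' @export
genome_build <- function(chrom_lengths, masks = NULL, gc = NULL,
                         mappability = NULL, bin_width = 1e6L) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0))
  chroms <- names(chrom_lengths)
  if (anyDuplicated(chroms)) stop("duplicated chromosome names")
  if (is.null(masks)) {
    masks <- data.table(chrom = character(), start = numeric(), end = numeric())
  } else {
    masks <- as.data.table(masks)[, .(chrom, start, end)]
    bad <- masks[!chrom %in% chroms]
    if (nrow(bad)) stop("mask interval on unknown chromosome: ", bad$chrom[1])
    for (i in seq_len(nrow(masks))) {
      L <- chrom_lengths[[masks$chrom[i]]]
      if (masks$start[i] < 0 || masks$end[i] > L || masks$start[i] >= masks$end[i])
        stop("mask interval outside chromosome ", masks$chrom[i])
    }
  }
  norm_track <- function(tr, what) {
    if (is.null(tr)) return(NULL)
    if (is.data.frame(tr)) {
      tr <- as.data.table(tr)
      setnames(tr, c("chrom", "start", what)[seq_len(ncol(tr))])
      split(tr[[what]], factor(tr$chrom, levels = chroms))
    } else {
      tr
    }
  }
  gc <- norm_track(gc, "gc")
  mappability <- norm_track(mappability, "mappability")
  for (tr in list(gc, mappability)) {
    if (!is.null(tr)) {
      v <- unlist(tr, use.names = FALSE)
      if (any(v < 0 | v > 100)) stop("track values must lie in [0, 100]")
    }
  }
  structure(list(chrom_lengths = chrom_lengths, masks = masks, gc = gc,
                 mappability = mappability, bin_width = as.integer(bin_width)),
            class = "GenomeBuild")
}

#' @export
print.GenomeBuild <- function(x, ...) {
  cat(sprintf("GenomeBuild: %d chromosomes, %.1f Mb, %d mask intervals\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              nrow(x$masks)))
  invisible(x)
}

#' Autosome names of a genome build
#'
#' Chromosomes named `chrX`, `chrY`, `X`, `Y`, `chrM`/`MT` are treated as
#' non-autosomal; everything else counts as an autosome.
#'
#' @param genome a `GenomeBuild`.
#' @return character vector of autosome names, in genome order.
#' @export
autosomes <- function(genome) {
  nm <- names(genome$chrom_lengths)
  nm[!sub("^chr", "", nm) %in% c("X", "Y", "M", "MT")]
}

#' Scaled hg19-like toy genome
#'
#' A deterministic small genome for testing and simulation: the 22 human
#' autosome lengths (hg19) multiplied by `scale`, a centromere mask of
#' `centromere_mb` Mb in the middle of each chromosome, and smoothly varying
#' GC / mappability tracks that deliberately place a few bins outside the
#' GC (30, 50] and mappability > 80 acceptance windows so the bin filters
#' are exercised.
#'
#' @param scale length multiplier applied to the hg19 autosome lengths.
#' @param centromere_mb width of the central masked region, Mb.
#' @param seed integer seed for the (deterministic) track jitter.
#' @return a `GenomeBuild`.
#' @export
toy_genome <- function(scale = 0.25, centromere_mb = 2, seed = 99L) {
  hg19 <- c(
    chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566)
  lens <- round(hg19 * scale)
  w <- 1e6
  masks <- data.table(
    chrom = names(lens),
    start = floor(lens / 2 / w) * w,
    end   = floor(lens / 2 / w) * w + centromere_mb * w)
  masks[end > lens[chrom], end := lens[chrom]]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gc <- list(); mp <- list()
  for (i in seq_along(lens)) {
    nb <- floor(lens[i] / w)
    x <- seq_len(nb)
    gcv <- 41 + 9 * sin(2 * pi * x / 37 + i) + stats::rnorm(nb, 0, 1.5)
    gcv <- pmin(70, pmax(20, gcv))
    mpv <- 96 + 3 * sin(2 * pi * x / 23 + 2 * i) + stats::rnorm(nb, 0, 1)
    # a sprinkling of hard-to-map bins
    low <- which(x %% 29 == 7)
    mpv[low] <- 70 + stats::runif(length(low), 0, 9)
    mpv <- pmin(100, pmax(0, mpv))
    gc[[names(lens)[i]]] <- gcv
    mp[[names(lens)[i]]] <- mpv
  }
  genome_build(lens, masks, gc, mp, bin_width = as.integer(w))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Read a genome build from a YAML bundle
#'
#' The bundle is a YAML file with a `chromosomes` map (name -> length in bp)
#' and optional `masks` (BED path), `gc` and `mappability` (4-column bedGraph
#' paths at bin resolution) and `bin_width`. Relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a `GenomeBuild`.
#' @export
read_genome <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$chromosomes)) stop("genome YAML lacks a 'chromosomes' map")
  lens <- unlist(cfg$chromosomes)
  dir <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else file.path(dir, p)
  masks <- NULL
  if (!is.null(cfg$masks)) masks <- read_bed(resolve(cfg$masks))
  rd_track <- function(p) {
    if (is.null(p)) return(NULL)
    bg <- fread(resolve(p), header = FALSE,
                col.names = c("chrom", "start", "end", "value"))
    bg[, .(chrom, start, value)]
  }
  genome_build(lens, masks, rd_track(cfg$gc), rd_track(cfg$mappability),
               bin_width = if (is.null(cfg$bin_width)) 1e6L else cfg$bin_width)
}

#' Read a BED file of intervals
#'
#' @param path BED path (first three columns used; 0-based half-open).
#' @return `data.table` with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  b <- fread(path, header = FALSE)
  if (ncol(b) < 3) stop("BED file needs at least 3 columns: ", path)
  setnames(b, 1:3, c("chrom", "start", "end"))
  b[, .(chrom, start, end)]
}

#' Construct the 1-Mb bin grid for a genome
#'
#' Tiles every chromosome with non-overlapping bins of `width` bp. A short
#' terminal remainder (< `width`) is never emitted: partial bins would bias
#' fragment-distance statistics. Each bin is flagged:
#' * `masked` — overlaps a mask interval by at least 1 bp;
#' * `low_mapp` — mappability <= 80;
#' * `gc_excluded` — GC <= 30 or GC > 50.
#' A bin is `retained` iff no flag is set.
#'
#' @param genome a `GenomeBuild` with GC and mappability tracks.
#' @param width bin width in bp (default 1 Mb).
#' @return `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `bin_id`, `gc`, `mappability`, `masked`, `low_mapp`,
#'   `gc_excluded`, `retained`; class `BinSet`.
#' @export
make_bins <- function(genome, width = 1e6L) {
  stopifnot(inherits(genome, "GenomeBuild"), width > 0)
  chroms <- names(genome$chrom_lengths)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    cn <- chroms[ci]
    nb <- floor(genome$chrom_lengths[[cn]] / width)
    if (nb == 0) next
    gc <- genome$gc[[cn]]
    mp <- genome$mappability[[cn]]
    if (is.null(gc) || is.null(mp))
      stop("missing GC or mappability track for chromosome ", cn)
    if (length(gc) < nb || length(mp) < nb)
      stop("track for ", cn, " shorter than its bin grid")
    dt <- data.table(chrom = cn,
                     start = as.numeric(seq_len(nb) - 1) * width,
                     end = as.numeric(seq_len(nb)) * width,
                     gc = gc[seq_len(nb)], mappability = mp[seq_len(nb)])
    msk <- genome$masks[chrom == cn]
    dt[, masked := FALSE]
    for (i in seq_len(nrow(msk)))
      dt[start < msk$end[i] & end > msk$start[i], masked := TRUE]
    out[[ci]] <- dt
  }
  bins <- rbindlist(out)
  bins[, low_mapp := mappability <= 80]
  bins[, gc_excluded := gc <= 30 | gc > 50]
  bins[, retained := !masked & !low_mapp & !gc_excluded]
  bins[, bin_id := paste0(chrom, ":", format(start, scientific = FALSE,
                                             trim = TRUE))]
  setattr(bins, "width", as.numeric(width))
  setattr(bins, "class", c("BinSet", class(bins)))
  bins[]
}

#' Load aligned cfDNA fragments
#'
#' Reads single-end aligned fragments from a SAM/BAM file (via Rsamtools) or
#' from the package's tab-separated fragment dialect: a header line then
#' columns `chrom`, `pos` (1-based leftmost), `strand` (`+`/`-`), `mapq`,
#' `dup` (0/1). Records are filtered to primary alignments with
#' `mapq >= min_mapq` that are not flagged as duplicates; input order is
#' preserved.
#'
#' @param path input file; `.sam`/`.bam` are parsed as alignments, anything
#'   else as the TSV dialect.
#' @param min_mapq minimum mapping quality kept (default 60).
#' @param chroms optional character vector of known chromosome names; a
#'   record on any other chromosome raises an error naming it.
#' @param read_len read length in bp attached to each record (default 75).
#' @return `data.table` with `chrom`, `pos`, `strand`, `mapq`, `dup`,
#'   `read_len`.
#' @export
load_fragments <- function(path, min_mapq = 60L, chroms = NULL,
                           read_len = 75L) {
  if (!file.exists(path)) stop("no such file: ", path)
  rl <- as.integer(read_len)
  empty <- data.table(chrom = character(), pos = numeric(),
                      strand = character(), mapq = integer(),
                      dup = integer(), read_len = integer())
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    fr <- .read_alignments(path)
  } else if (file.size(path) == 0) {
    return(empty)
  } else {
    fr <- fread(path, header = TRUE, colClasses = list(character = "chrom"))
    need <- c("chrom", "pos", "strand", "mapq", "dup")
    if (!all(need %in% names(fr)))
      stop("fragment TSV must have header columns: ",
           paste(need, collapse = ", "))
    if (nrow(fr) && !all(fr$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
  }
  if (!nrow(fr)) return(empty)
  if (!is.null(chroms)) {
    bad <- which(!fr$chrom %in% chroms)
    if (length(bad))
      stop(sprintf("record %d on unknown chromosome '%s'",
                   bad[1], fr$chrom[bad[1]]))
  }
  fr <- fr[mapq >= min_mapq & dup == 0]
  fr[, read_len := rl]
  fr[]
}

.read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read SAM/BAM input")
  if (tolower(tools::file_ext(path)) == "sam")
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "mapq", "flag"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos) &
    bitwAnd(b$flag, 0x4) == 0 &     # mapped
    bitwAnd(b$flag, 0x100) == 0 &   # not secondary
    bitwAnd(b$flag, 0x800) == 0     # not supplementary
  data.table(chrom = as.character(b$rname)[keep],
             pos = as.numeric(b$pos)[keep],
             strand = as.character(b$strand)[keep],
             mapq = as.integer(b$mapq)[keep],
             dup = as.integer(bitwAnd(b$flag[keep], 0x400) != 0))
}

#' Write fragments in the package TSV dialect
#'
#' @param fragments `data.table` as returned by [load_fragments()] or
#'   [simulate_sample()].
#' @param path output path.
#' @export
write_fragments <- function(fragments, path) {
  fwrite(fragments[, .(chrom, pos, strand, mapq, dup)], path, sep = "\t")
  invisible(path)
}

#' Write the bin grid as TSV
#' @param bins a `BinSet`.
#' @param path output path.
#' @export
write_bins <- function(bins, path) {
  fwrite(as.data.table(bins), path, sep = "\t")
  invisible(path)
}
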