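#' Simulation configuration
#'
#' Describes one simulated cfDNA sample: sequencing depth, fetal fraction,
#' trisomy status, GC bias, maternal CNV spike-ins and reproducibility seed.
#' A trisomic fetus at fetal fraction `f` raises the affected chromosome's
#' expected dosage by the factor `1 + f/2` (two maternal copies plus three
#' fetal copies in the fetal compartment instead of two).
#'
#' @param genome a `GenomeBuild`.
#' @param n_fragments total fragments drawn for the sample. The clinical
#'   regime is ~12e6 reads on the full genome; the toy default 2e5 keeps the
#'   same order of per-bin density on the quarter-scale [toy_genome()].
#' @param fetal_fraction proportion of cfDNA of fetal origin, in \[0, 1\].
#' @param trisomy one of `"none"`, `"chr21"`, `"chr18"`, `"chr13"`.
#' @param gc_bias numeric length-3: coefficients `(b0, b1, b2)` of a
#'   quadratic bias curve `b0 + b1*u + b2*u^2` in `u = (GC - 40)/10`,
#'   floored at 0.05 and normalized to mean 1 over the simulated bins.
#' @param cnv_specs list of maternal CNV events, each a list with `chrom`,
#'   `start`, `end` (0-based half-open, bp) and `copy_ratio` (> 0; 1.5 is a
#'   heterozygous duplication, 0.5 a heterozygous deletion).
#' @param strand_prob probability a fragment is on the forward strand.
#' @param read_len read length, bp.
#' @param seed integer seed; the sample is fully reproducible from it.
#' @param prop_dup,prop_low_mapq proportions of additional junk records
#'   (duplicate-flagged, MAPQ 30) injected to exercise the input filters;
#'   both default 0.
#' @return a `SimConfig` (list).
#' @export
sim_config <- function(genome, n_fragments = 200000L, fetal_fraction = 0,
                       trisomy = c("none", "chr21", "chr18", "chr13"),
                       gc_bias = c(1, -0.08, -0.06), cnv_specs = list(),
                       strand_prob = 0.5, read_len = 75L, seed = 1L,
                       prop_dup = 0, prop_low_mapq = 0) {
  trisomy <- match.arg(trisomy)
  stopifnot(inherits(genome, "GenomeBuild"),
            n_fragments > 0,
            fetal_fraction >= 0, fetal_fraction <= 1,
            length(gc_bias) == 3,
            strand_prob >= 0, strand_prob <= 1)
  if (trisomy != "none" && !trisomy %in% names(genome$chrom_lengths))
    stop("trisomy chromosome ", trisomy, " absent from genome")
  for (cs in cnv_specs) {
    stopifnot(all(c("chrom", "start", "end", "copy_ratio") %in% names(cs)))
    if (cs$copy_ratio <= 0) stop("copy_ratio must be > 0")
    if (!cs$chrom %in% names(genome$chrom_lengths))
      stop("CNV chromosome ", cs$chrom, " absent from genome")
  }
  structure(list(genome = genome, n_fragments = as.integer(n_fragments),
                 fetal_fraction = fetal_fraction, trisomy = trisomy,
                 gc_bias = gc_bias, cnv_specs = cnv_specs,
                 strand_prob = strand_prob, read_len = as.integer(read_len),
                 seed = as.integer(seed), prop_dup = prop_dup,
                 prop_low_mapq = prop_low_mapq),
            class = "SimConfig")
}

#' Per-bin expected intensity of a simulated sample
#'
#' Intensity is proportional to
#' `bin_width * dosage(bin) * gc_bias(GC) * mappability/100`, with
#' `dosage = 1 + fetal_fraction/2` on the trisomic chromosome, multiplied by
#' `1 + (copy_ratio - 1) * overlap_fraction` on bins overlapping a maternal
#' CNV, and exactly 0 on masked bins (so no fragment ever falls in a masked
#' region).
#'
#' @param config a `SimConfig`.
#' @param bins optionally a precomputed `BinSet` for `config$genome`.
#' @return the `BinSet` with an `intensity` column (summing to 1 over bins).
#' @export
sim_bin_intensity <- function(config, bins = NULL) {
  if (is.null(bins)) bins <- make_bins(config$genome)
  bins <- copy(as.data.table(bins))
  w <- attr(bins, "width")
  if (is.null(w)) w <- bins[1, end - start]
  u <- (bins$gc - 40) / 10
  bias <- config$gc_bias[1] + config$gc_bias[2] * u + config$gc_bias[3] * u^2
  bias <- pmax(bias, 0.05)
  inten <- (bins$end - bins$start) * bias * bins$mappability / 100
  inten[bins$masked] <- 0
  if (config$trisomy != "none") {
    on_t <- bins$chrom == config$trisomy
    inten[on_t] <- inten[on_t] * (1 + config$fetal_fraction / 2)
  }
  for (cs in config$cnv_specs) {
    ov <- pmax(0, pmin(bins$end, cs$end) - pmax(bins$start, cs$start))
    hit <- bins$chrom == cs$chrom & ov > 0
    frac <- ov[hit] / (bins$end[hit] - bins$start[hit])
    inten[hit] <- inten[hit] * (1 + (cs$copy_ratio - 1) * frac)
  }
  if (all(inten == 0)) stop("degenerate simulation: all-zero intensity")
  bins[, intensity := inten / sum(inten)]
  bins[]
}

#' Simulate one cfDNA sample
#'
#' Draws the per-bin fragment count vector from a multinomial with total
#' `n_fragments` (fixed per-sample yield, mirroring a fixed sequencing
#' depth), places fragments uniformly within their bin, and assigns strands
#' Bernoulli(`strand_prob`). Clean records carry MAPQ 60 and no duplicate
#' flag; optional junk records (see [sim_config()]) are appended to exercise
#' the [load_fragments()] filters.
#'
#' @param config a `SimConfig`.
#' @param bins optionally a precomputed `BinSet` (with or without the
#'   intensity column) to avoid recomputation across samples.
#' @return list with `fragments` (`data.table`: chrom, pos, strand, mapq,
#'   dup, read_len) and `truth` (`SimTruth`: trisomy, fetal_fraction,
#'   cnv_specs, seed).
#' @export
simulate_sample <- function(config, bins = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  ib <- sim_bin_intensity(config, bins)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  counts <- as.vector(stats::rmultinom(1, config$n_fragments, ib$intensity))
  idx <- rep.int(seq_len(nrow(ib)), counts)
  width <- ib$end[idx] - ib$start[idx]
  pos <- ib$start[idx] + floor(stats::runif(length(idx)) * width) + 1
  fr <- data.table(
    chrom = ib$chrom[idx],
    pos = pos,
    strand = c("-", "+")[1L + (stats::runif(length(idx)) <
                                 config$strand_prob)],
    mapq = 60L, dup = 0L, read_len = config$read_len)
  n_junk_dup <- round(config$prop_dup * nrow(fr))
  n_junk_lq <- round(config$prop_low_mapq * nrow(fr))
  if (n_junk_dup + n_junk_lq > 0 && nrow(fr) > 0) {
    pick <- function(n) fr[sample.int(nrow(fr), n, replace = TRUE)]
    jd <- pick(n_junk_dup); if (nrow(jd)) jd[, dup := 1L]
    jl <- pick(n_junk_lq); if (nrow(jl)) jl[, mapq := 30L]
    fr <- rbindlist(list(fr, jd, jl))
  }
  truth <- structure(list(trisomy = config$trisomy,
                          fetal_fraction = config$fetal_fraction,
                          cnv_specs = config$cnv_specs,
                          seed = config$seed),
                     class = "SimTruth")
  list(fragments = fr, truth = truth)
}

#' Derive the per-sample seed of a cohort member
#'
#' Counter scheme: `(base_seed + 7919 * index) mod (2^31 - 1)`, so cohorts
#' are reproducible under parallel generation and all seeds stay within
#' R's integer range.
#'
#' @param base_seed integer master seed.
#' @param index 1-based sample index.
#' @return integer seed.
#' @export
cohort_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) + 7919 * as.numeric(index)) %%
               (2^31 - 1))
}

#' Draw the design (labels, fetal fractions, seeds) of a simulated cohort
#'
#' @param n number of samples.
#' @param prevalence named numeric, e.g. `c(chr21 = 0.073, chr18 = 0.025,
#'   chr13 = 0.007)`; proportions must sum to at most 1, the remainder is
#'   euploid.
#' @param base_seed master seed.
#' @param ff_range range of the uniform per-sample fetal-fraction draw.
#' @return `data.table` with `sample_id`, `trisomy`, `fetal_fraction`,
#'   `seed`.
#' @export
cohort_design <- function(n, prevalence = c(chr21 = 0, chr18 = 0, chr13 = 0),
                          base_seed = 1L, ff_range = c(0.04, 0.20)) {
  if (n <= 0) stop("n must be positive")
  if (sum(prevalence) > 1) stop("prevalence proportions sum to more than 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(base_seed))
  labs <- sample(c(names(prevalence), "none"), n, replace = TRUE,
                 prob = c(prevalence, 1 - sum(prevalence)))
  ff <- stats::runif(n, ff_range[1], ff_range[2])
  data.table(sample_id = sprintf("sim%04d", seq_len(n)),
             trisomy = labs, fetal_fraction = ff,
             seed = vapply(seq_len(n), cohort_seed,
                           integer(1), base_seed = base_seed))
}

#' Simulate a cohort of cfDNA samples
#'
#' Labels are drawn per `prevalence`, per-sample fetal fractions uniform on
#' `ff_range`, per-sample seeds by the [cohort_seed()] counter scheme, so
#' the whole dataset is reproducible from `base_config$seed`.
#'
#' @param n number of samples.
#' @param prevalence named proportions of each trisomy (see
#'   [cohort_design()]).
#' @param base_config a `SimConfig` used as the template (its seed is the
#'   cohort master seed).
#' @param ff_range uniform range for per-sample fetal fraction.
#' @return list with `design` (the truth table) and `samples` (list of
#'   [simulate_sample()] results, in design order).
#' @export
simulate_cohort <- function(n, prevalence, base_config,
                            ff_range = c(0.04, 0.20)) {
  design <- cohort_design(n, prevalence, base_config$seed, ff_range)
  bins <- make_bins(base_config$genome)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- base_config
    cfg$trisomy <- design$trisomy[i]
    cfg$fetal_fraction <- design$fetal_fraction[i]
    cfg$seed <- design$seed[i]
    samples[[i]] <- simulate_sample(cfg, bins)
  }
  list(design = design, samples = samples)
}

#' Write a cohort truth table as TSV
#' @param design the `design` table of [simulate_cohort()].
#' @param path output path.
#' @export
write_truth <- function(design, path) {
  fwrite(design, path, sep = "\t")
  invisible(path)
}
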