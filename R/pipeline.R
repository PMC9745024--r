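#' Fragment-distance features for a whole simulated cohort
#'
#' Streams the cohort: each sample is simulated, reduced to its per-bin FD
#' table, chromosome-level median FDs, GC/mappability-adjusted chromosome
#' fractions and NCV ratios, and its fragments are discarded, so memory
#' stays flat in cohort size.
#'
#' @param design a [cohort_design()] table.
#' @param base_config `SimConfig` template (depth, GC bias, genome...).
#' @param targets chromosomes for which NCV ratios are computed.
#' @param verbose print progress every 50 samples.
#' @return list: `bin_tables` (per sample `BinFDTable`), `chrom_med`
#'   (samples x chromosomes matrix of median FD), `fractions` (samples x
#'   chromosomes), `ncv` (samples x targets), `design`.
#' @export
cohort_fd_features <- function(design, base_config,
                               targets = c("chr21", "chr18", "chr13"),
                               verbose = FALSE) {
  bins <- make_bins(base_config$genome)
  n <- nrow(design)
  chroms <- names(base_config$genome$chrom_lengths)
  bin_tables <- vector("list", n)
  chrom_med <- matrix(NA_real_, n, length(chroms),
                      dimnames = list(design$sample_id, chroms))
  fractions <- matrix(0, n, length(chroms),
                      dimnames = list(design$sample_id, chroms))
  ncv <- matrix(NA_real_, n, length(targets),
                dimnames = list(design$sample_id, targets))
  for (i in seq_len(n)) {
    cfg <- base_config
    cfg$trisomy <- design$trisomy[i]
    cfg$fetal_fraction <- design$fetal_fraction[i]
    cfg$seed <- design$seed[i]
    sm <- simulate_sample(cfg, bins)
    ft <- fd_features(sm$fragments, bins)
    bin_tables[[i]] <- ft$bin_table
    chrom_med[i, names(ft$chrom_med_fd)] <- ft$chrom_med_fd
    adj <- adjust_counts(ft$bin_table)
    fr <- chrom_fraction(adj)
    fractions[i, names(fr)] <- fr
    for (tg in targets) ncv[i, tg] <- ncv_ratio(adj, tg)
    if (verbose && i %% 50 == 0)
      message("  features: ", i, "/", n, " samples")
  }
  list(bin_tables = bin_tables, chrom_med = chrom_med,
       fractions = fractions, ncv = ncv, design = design)
}

#' TRS images for a cohort, one target chromosome
#'
#' @param bin_tables list of per-sample `BinFDTable`s.
#' @param icc an `ICCSelection` for the target.
#' @return named list (`mean`, `median`, `iqr`), each a list of 200 x 400
#'   image matrices in cohort order.
#' @export
cohort_images <- function(bin_tables, icc) {
  out <- list(mean = vector("list", length(bin_tables)),
              median = vector("list", length(bin_tables)),
              iqr = vector("list", length(bin_tables)))
  for (i in seq_along(bin_tables)) {
    nt <- normalize_and_trim(bin_tables[[i]], c(icc$target, icc$icc))
    for (rp in c("mean", "median", "iqr")) {
      out[[rp]][[i]] <- render_trs(
        nt$values[[icc$target]][[rp]],
        lapply(icc$icc, function(cn) nt$values[[cn]][[rp]]))
    }
  }
  out
}

#' End-to-end simulated study: simulate, featurize, train, score
#'
#' Runs the whole method on a simulated cohort: the euploid members serve
#' as the reference cohort (for Z/NCV statistics and ICC selection), TRS
#' images are built for each requested target, per-target CNN sets are
#' trained with cross-validation, and held-out probabilities plus Z/NCV
#' scores are returned per sample.
#'
#' @param genome a `GenomeBuild` (default quarter-scale [toy_genome()]).
#' @param n cohort size.
#' @param prevalence named trisomy proportions for the cohort.
#' @param n_fragments per-sample depth.
#' @param ff_range fetal-fraction range of the cohort.
#' @param targets target chromosomes to train models for.
#' @param seed master seed.
#' @param config `TrainConfig` template (its seed is overridden per target).
#' @param verbose progress messages.
#' @return list: `design`, `features` (without bin tables), `icc`,
#'   `reference` (`z` and `ncv` `ReferenceStats`), `models` per target,
#'   `calls` (`data.table` per sample: z/ncv scores and held-out aiD
#'   probabilities per target), `auc` per target (held-out ensemble AUC).
#' @export
run_study <- function(genome = toy_genome(), n = 300,
                      prevalence = c(chr21 = 0.25, chr18 = 0.25),
                      n_fragments = 400000L, ff_range = c(0.08, 0.15),
                      targets = names(prevalence), seed = 1L,
                      config = train_config(), verbose = FALSE) {
  base <- sim_config(genome, n_fragments = n_fragments, seed = seed)
  design <- cohort_design(n, prevalence, seed, ff_range)
  if (verbose) message("simulating + featurizing ", n, " samples")
  feats <- cohort_fd_features(design, base, verbose = verbose)
  eup <- design$trisomy == "none"
  if (sum(eup) < 2) stop("cohort has fewer than 2 euploid reference samples")
  ref_z <- build_reference(feats$fractions[eup, , drop = FALSE], "z")
  ref_ncv <- build_reference(feats$ncv[eup, , drop = FALSE], "ncv",
                             targets = colnames(feats$ncv))
  calls <- data.table(sample_id = design$sample_id,
                      trisomy = design$trisomy,
                      fetal_fraction = design$fetal_fraction)
  icc_sets <- list(); models <- list(); auc <- list()
  for (tg in targets) {
    if (verbose) message("target ", tg, ": ICC, images, training")
    icc_sets[[tg]] <- select_icc(feats$chrom_med[eup, , drop = FALSE], tg)
    imgs <- cohort_images(feats$bin_tables, icc_sets[[tg]])
    labels <- as.integer(design$trisomy == tg)
    cfg <- config
    cfg$seed <- config$seed + match(tg, targets)
    models[[tg]] <- train_models(imgs, labels, cfg)
    rm(imgs)
    oof <- models[[tg]]$oof
    calls[, paste0("z_", tg) := vapply(seq_len(n), function(i)
      z_score(feats$fractions[i, ], ref_z, tg)$score, numeric(1))]
    calls[, paste0("ncv_", tg) := (feats$ncv[, tg] - ref_ncv$mean[[tg]]) /
                                   ref_ncv$sd[[tg]]]
    for (cl in c("p_mean", "p_median", "p_iqr", "p_ensemble"))
      calls[, paste0(cl, "_", tg) := oof[[cl]]]
    auc[[tg]] <- roc_auc(oof$p_ensemble, labels)
  }
  feats$bin_tables <- NULL
  list(design = design, features = feats, icc = icc_sets,
       reference = list(z = ref_z, ncv = ref_ncv),
       models = models, calls = calls, auc = auc)
}

#' Maternal-CNV false-positive scenario
#'
#' Simulates euploid samples carrying a maternal duplication on chromosome
#' 18 large enough to push the count-based Z-score over its cutoff, and
#' scores each replicate with both the Z-score and the trained trisomy-18
#' ensemble. Because extreme bins are trimmed before rasterization and the
#' classifier reads the whole-chromosome pattern, the ensemble is expected
#' to stay below its cutoff while Z fires.
#'
#' @param study a [run_study()] result containing a `chr18` model.
#' @param genome the same `GenomeBuild` used in the study.
#' @param n_reps number of replicates.
#' @param cnv maternal CNV spec. The default is a duplication of the
#'   17-18 Mb bin of the quarter-scale chr18 at copy ratio 2: like the
#'   clinical multi-Mb events that fool count-based callers, it spans
#'   fewer of the chromosome's usable bins than the 10% trim removes
#'   (one bin here, against a trim depth of one), so the rasterized
#'   pattern stays clean while the chromosome-wide count shifts by
#'   several SD.
#' @param n_fragments per-sample depth (defaults to the study's).
#' @param seed seed for the replicate series.
#' @return `data.table` per replicate: `z_chr18`, `z_call`, `p_ensemble`,
#'   `aid_call`.
#' @export
cnv_scenario <- function(study, genome = toy_genome(), n_reps = 12,
                         cnv = list(chrom = "chr18", start = 17e6,
                                    end = 18e6, copy_ratio = 2),
                         n_fragments = 400000L, seed = 777L) {
  stopifnot("chr18" %in% names(study$models))
  bins <- make_bins(genome)
  icc <- study$icc$chr18
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(genome, n_fragments = n_fragments,
                      trisomy = "none", cnv_specs = list(cnv),
                      seed = cohort_seed(seed, r))
    sm <- simulate_sample(cfg, bins)
    ft <- fd_features(sm$fragments, bins)
    adj <- adjust_counts(ft$bin_table)
    z <- z_score(chrom_fraction(adj), study$reference$z, "chr18")
    nt <- normalize_and_trim(ft$bin_table, c(icc$target, icc$icc))
    imgs <- lapply(c(mean = "mean", median = "median", iqr = "iqr"),
                   function(rp) list(render_trs(
                     nt$values[[icc$target]][[rp]],
                     lapply(icc$icc, function(cn) nt$values[[cn]][[rp]]))))
    pp <- predict_proba(study$models$chr18, imgs)
    out[[r]] <- data.table(z_chr18 = z$score, z_call = z$call,
                           p_ensemble = pp$p_ensemble,
                           aid_call = call_sample(pp$p_ensemble))
  }
  rbindlist(out)
}
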