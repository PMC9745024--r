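---
title: "Fragment-distance NIPT: models, parameters and design choices"
author: "aidnipt package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-distance NIPT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the feature

Non-invasive prenatal testing (NIPT) screens for fetal trisomy 21, 18 and
13 from low-coverage sequencing of cell-free DNA (cfDNA) in maternal
plasma. The plasma is a mixture: a fraction *f* (the fetal fraction,
typically 4–20%) of the fragments derive from the placenta. A trisomic
fetus contributes three copies of the affected chromosome instead of two,
so the expected dosage of that chromosome in the mixture is multiplied by
*1 + f/2* — a shift of a few percent that must be detected against
counting noise.

Conventional callers count fragments (FC) per region and standardize the
affected chromosome's share against a euploid reference cohort (the
Z-score), possibly using a designated denominator chromosome set (the
NCV: chr9 for chr21, chr8 for chr18, the sum of chr2–chr6 for chr13),
calling a trisomy when the score reaches 3.

This package implements a *fragment distance* (FD) representation
instead. After positional shifting — +80 bp onto the leftmost coordinate
of a forward read, −80 bp off the rightmost coordinate
(`pos + read_len − 1`) of a reverse read, harmonizing the
strand-dependent definition of a single-end fragment's position — the FD
is the difference between adjacent shifted positions on a chromosome.
Where a count collapses a 1-Mb bin to one number, the distance sample in
the bin has a distribution, summarized here by its mean, median and IQR.
At fixed chromosome length, more fragments means smaller gaps, so trisomy
*lowers* FD on the affected chromosome; but FD is not a deterministic
function of FC (bins with equal median FD and different counts are
common), which is what makes the representation complementary rather than
redundant.

## From fragments to TRS images

The per-sample pipeline is:

1. 1-Mb non-overlapping binning of each chromosome (a terminal remainder
   shorter than 1 Mb is never used — a partial bin would bias distance
   statistics);
2. removal of bins overlapping masked regions (centromeres, telomeres) by
   at least 1 bp — conservative whole-bin exclusion;
3. removal of bins with mappability ≤ 80;
4. removal of bins with GC ≤ 30 or GC > 50 (both boundaries as written:
   GC = 50 is retained, GC = 30 is removed);
5. per-bin FD summaries (mean, median, IQR), each distance assigned to the
   bin containing the left member of its pair so it lands in exactly one
   bin; bins with fewer than `min_fd_n = 10` distances are flagged
   unusable, a floor that guards against degenerate statistics at toy
   depth;
6. `global_median` = the median over all retained, usable bins genome-wide
   of the per-bin FD median;
7. division of every representative value by `global_median` (median
   normalization; this removes sequencing-depth differences, because every
   distance scales inversely with depth);
8. per chromosome and per representative, removal of the `floor(0.10 n)`
   lowest and highest bins, survivors keeping genomic order;
9. rasterization: the trimmed sequences of three internal control
   chromosomes (ICC) and the target chromosome (TC) are concatenated as
   ICC1, TC, ICC2, TC, ICC3, TC and drawn as one polyline on a 200 × 400
   grayscale raster.

Step 6 is read literally: one genome-wide median of the per-bin *median*
normalizes all three representatives. The alternative (a per-representative
global median) was considered and rejected in favour of the literal
reading; since all three representatives of the same bin scale together
with depth, the choice affects only the vertical placement of the mean
and IQR curves, not their shape.

Trimming is per chromosome, not pooled: the trimming step exists to
protect the image from focal artifacts (e.g. an unmasked CNV) on *either*
the target or a control chromosome, and pooling would let a whole
chromosome's level shift survive at the expense of the other segments.

### ICC selection

Controls are chosen per target from the euploid reference cohort: for
each candidate autosome (never chr13/18/21, never a sex chromosome), an
ordinary least-squares regression of the target's reciprocal median FD on
the candidate's across reference samples; candidates are ranked by
−log10(MSE) and the top three are kept, in score order. A fit exact to
machine precision counts as MSE 0 and ranks first; ties break by genome
order. The reciprocal is used because 1/median-FD is proportional to
fragment density, the scale on which chromosomes co-vary with depth.

### Rasterization choices

The y axis maps a *fixed* range [0.5, 1.5] (values clipped) to the image
rows, bottom to top. Per-image min–max scaling would erase exactly the
level shift between TC and ICC segments that carries the trisomy signal;
a fixed window keeps images comparable across samples. The polyline is
drawn with an integer Bresenham walk, one pixel wide, intensity 1 on
background 0 — no anti-aliasing, no plotting canvas — so identical inputs
give byte-identical images on any platform. The x axis is the index
within the six-segment concatenation rescaled to the 400 columns.

## The classifier

One binary model set per target trisomy. Samples are dealt into five
stratified cross-validation folds; within each fold the held-out fold is
the test split and the remainder is split 5:3 into training and
validation (5:3:2 overall). Each fold × representative sub-model is a
small CNN selected at its minimum validation loss (early stopping,
patience 5). A sample's per-representative probability is the mean of the
five fold models; the ensemble is the *median* of the three
representative probabilities taken per fold, then averaged across folds.
(Taking the median of the three final fold-averaged values is almost the
same number; the per-fold reading is implemented because the two orders
provably differ and only the per-fold order makes the ensemble a proper
per-fold statistic.) Calls use probability ≥ 0.5.

The network is deliberately small, and is the package's own CPU
implementation (compiled convolution/pooling kernels, Adam, weighted
binary cross-entropy): a fixed 4 × 8 average pooling (200 × 400 → 50 ×
50), two 3 × 3 convolution blocks of 8 and 16 filters with ReLU and 2 × 2
max pooling, one 32-unit dense layer with dropout 0.3, and a sigmoid
output. A TRS image is a sparse polyline whose informative feature is the
vertical level of the TC segments; capacity beyond this adds variance,
not signal. All randomness (fold assignment, initialization, shuffling,
dropout) derives from the configured seed, so training is exactly
reproducible run to run on CPU. Class weighting (positives weighted by
the negative:positive ratio) substitutes for the rebalancing a clinical
cohort would need, where a trisomy-13 model may see only a dozen
positives. A small random hyperparameter search (`tune_models()`) is
provided in place of large-scale Bayesian optimization, which is not a
desk-scale exercise and is orthogonal to what the FD/TRS representation
itself is for.

## Count-based baselines

`adjust_counts()` divides bin counts by a loess fit of count on GC
(normalized to mean 1 over retained bins; span 0.75, symmetric family)
and by mappability/100 — a standard in-house correction in the role a
dedicated read-depth package would play in a clinical pipeline. Z uses
the chromosome's share of the genome-wide adjusted count; NCV the
designated denominator ratios; both standardize against the euploid
reference cohort's mean and SD and call at score ≥ 3 (the boundary is
inclusive by documented convention). Whether published pipelines compute
Z on adjusted or raw fractions is usually implicit; here adjustment comes
first, and the scores are invariant to any global rescaling of counts
either way.

## The simulator

The simulator is the package's study design, not a tuning knob. Per-bin
expected intensity is
`bin_width × dosage × gc_bias(GC) × mappability/100`, zero on masked
bins; dosage is `1 + f/2` on the trisomic chromosome and
`1 + (copy_ratio − 1) × overlap` on bins overlapping a maternal CNV. The
count vector is one multinomial draw with the sample's total fragment
count — fixed per-sample yield, mirroring fixed sequencing depth, rather
than independent Poisson bins. Positions are uniform within bins; strands
Bernoulli(0.5); every record carries MAPQ 60 and no duplicate flag, with
optional junk records (MAPQ 30 / duplicate-flagged) injected solely to
exercise the input filters. The GC bias default is a mild quadratic in
(GC − 40)/10 normalized to mean 1 — the simplest smooth confounder that
exercises both the GC bin filter and the loess correction.

Per-sample seeds follow a stated counter scheme
(`(base + 7919 i) mod 2^31 − 1`), so cohorts are reproducible even under
parallel generation. Cohort fetal fractions default to uniform 0.04–0.20,
a range consistent with clinical fetal-fraction strata; the clinical
literature gives no per-sample joint distribution of fetal fraction and
trisomy, so the default is stated rather than inferred.

What the simulator does *not* emulate: fragment-length distributions
(single-end 75-bp data), sequence content, alignment artifacts beyond the
MAPQ/duplicate flags, sex-chromosome aneuploidy, twin pregnancies, and
placental mosaicism. Passing the end-to-end tests therefore shows the
pipeline recovers the dosage signal it models — not clinical performance,
which requires clinical cohorts orders of magnitude larger.

## Problem sizes and numerical choices

The built-in toy genome is the 22 human autosome lengths scaled by 0.25
(~720 Mb, 707 bins), with a 2-Mb central mask per chromosome and smooth
GC/mappability tracks that deliberately place some bins outside the
filter windows. Default per-sample depth is 200,000 fragments (~280 per
bin); the end-to-end study uses 300 samples at 400,000 fragments with
fetal fractions 0.08–0.15, sizes at which the per-bin median FD has ~4%
sampling noise against a 4–7% trisomy shift — chosen a priori by that
power reasoning, and small enough that the whole study (simulation,
features, 30 CNN sub-models across two targets) runs in minutes on one
CPU. The depth used in the Z-score power checks (600,000) likewise comes
from the closed-form approximation z ≈ (f/2)·√(n·p₂₁).

Quartiles use linear interpolation between order statistics (R's default
type 7) throughout, fixed so golden values are stable. Zero distances
(two fragments shifted to the same coordinate) are kept — deduplication
happened upstream, and re-deduplicating shifted positions would distort
the distance distribution. Confidence intervals are Wald
(normal-approximation) on the proportion scale with the metric's
denominator, capped to [0, 100] and rounded half-up to two decimals;
Wilson or Clopper–Pearson intervals would not produce the collapsed
(100–100) upper bounds that exact proportions report here.

## Known limitations

* The FD definition takes each fragment's distance to its *following*
  neighbour (successive differences of sorted positions). The
  alternative reading — min(previous, next) — is not implemented; the
  brute-force oracle in the test suite covers the implemented reading
  only.
* The ensemble's per-fold-median-then-mean order is one of two defensible
  readings (see above); both are exposed through `ensemble_median()`.
* Training determinism assumes a fixed BLAS thread count; the package
  uses plain loops in its compiled kernels precisely to avoid
  thread-order-dependent reductions.
* The simulator's uniform-within-bin placement makes within-bin FD
  exponential-like; real cfDNA has nucleosome-phased positioning that
  modulates distances at ~180-bp scale. Bin-level summaries are robust to
  this, but sub-bin features should not be read into simulated data.

## A worked session

```{r example}
library(aidnipt)

genome <- toy_genome()
bins <- make_bins(genome)

# one trisomy-21 sample at 10% fetal fraction
cfg <- sim_config(genome, n_fragments = 200000L, fetal_fraction = 0.10,
                  trisomy = "chr21", seed = 11L)
sample <- simulate_sample(cfg, bins)
feats <- fd_features(sample$fragments, bins)

# a small euploid reference cohort
base <- sim_config(genome, n_fragments = 200000L, seed = 1L)
ref_design <- cohort_design(40, c(chr21 = 0), base_seed = 1L)
ref <- cohort_fd_features(ref_design, base)

# count-based calls
ref_z <- build_reference(ref$fractions, "z")
z_score(chrom_fraction(adjust_counts(feats$bin_table)), ref_z, "chr21")

# FD-based image
icc <- select_icc(ref$chrom_med, "chr21")
img <- trs_image(feats$bin_table, icc, representative = "median")
write_trs_png(img, "chr21.median.png")

# full study incl. CNN training (several minutes)
study <- run_study(genome = genome, n = 300, seed = 1L, verbose = TRUE)
study$auc
```
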