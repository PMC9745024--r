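# Shared fixtures, built in code at test time.

# uniform "flat" genome: constant GC 40, mappability 100, no masks -- for
# tests that need exact arithmetic with no filtering side effects
flat_genome <- function(n_chrom = 4, len = 10e6,
                        names_ = paste0("chr", seq_len(n_chrom))) {
  lens <- stats::setNames(rep(len, n_chrom), names_)
  nb <- floor(len / 1e6)
  genome_build(lens,
               gc = stats::setNames(rep(list(rep(40, nb)), n_chrom), names_),
               mappability = stats::setNames(rep(list(rep(100, nb)), n_chrom),
                                             names_))
}

# small quarter->tenth scale hg19-like genome; shared across tests (built
# once per test run)
small_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- toy_genome(scale = 0.1, centromere_mb = 1)
    g
  }
})

small_bins <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- make_bins(small_genome())
    b
  }
})

# a fragment table written directly (no simulator), for filter tests
toy_fragment_tsv <- function(path) {
  writeLines(c(
    "chrom\tpos\tstrand\tmapq\tdup",
    "chr1\t1001\t+\t60\t0",     # clean
    "chr1\t2001\t-\t60\t1",     # duplicate
    "chr1\t3001\t+\t59\t0",     # low MAPQ
    "chr2\t4001\t-\t60\t1",     # duplicate
    "chr2\t5001\t+\t60\t0"),    # clean
    path)
  path
}

# features for a small euploid cohort, cached (used by ICC / TRS tests)
small_cohort_features <- local({
  fe <- NULL
  function() {
    if (is.null(fe)) {
      base <- sim_config(small_genome(), n_fragments = 100000L, seed = 42L)
      des <- cohort_design(12, c(chr21 = 0), base_seed = 42L)
      fe <<- cohort_fd_features(des, base)
    }
    fe
  }
})
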