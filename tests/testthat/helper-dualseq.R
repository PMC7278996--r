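# Shared fixtures: built in code, small enough for fast property loops.

# A down-scaled experiment configuration (20 kb panel, ~100-200 errors
# per library) that keeps the structure of the full design.
small_config <- function(...) {
  args <- list(
    n_regions = 20, region_length = 1000,
    fp_pool_range = c(100, 200),
    fp_count_ranges = list(
      strelka2 = list(c(100, 200), c(100, 200)),
      mutect2 = list(c(20, 50), c(70, 100)),
      lofreq = list(c(15, 40), c(5, 12))))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Random call tibble over a small key universe, one row per (key, run).
random_calls <- function(n, design, n_keys = 30, seed = 1) {
  withr::with_seed(seed, {
    pool <- tidyr::expand_grid(
      k = seq_len(n_keys),
      run = seq_len(nrow(design)))
    pick <- pool[sample.int(nrow(pool), n), ]
    tibble::tibble(
      chrom = "chr1",
      pos = pick$k * 10L,
      ref = "C", alt = "T",
      caller = design$caller[pick$run],
      polymerase = design$polymerase[pick$run],
      replicate = design$replicate[pick$run],
      vaf = round(stats::runif(n), 4),
      depth = 100, alt_count = NA_real_,
      passed = stats::runif(n) < 0.5)
  })
}

# Random single-nucleotide calls with count-consistent VAFs, for VCF
# round-trip checks.
random_snv_calls <- function(n, seed = 1) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    depth <- sample(50:500, n, replace = TRUE)
    alt_count <- rbinom(n, depth, runif(n, 0.01, 0.4))
    tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      pos = sample.int(1e6, n),
      ref = ref, alt = alt,
      vaf = alt_count / depth,
      depth = depth, alt_count = alt_count,
      passed = runif(n) < 0.7)
  }) |>
    dplyr::distinct(chrom, pos, .keep_all = TRUE)
}

default_design <- function() {
  detection_design(c("strelka2", "mutect2", "lofreq"),
                   c("Agilent", "KAPA", "NEB"), 2)
}
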