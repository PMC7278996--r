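#' Configuration for a simulated dual-sequencing experiment
#'
#' Defines the generative model for a full cancer-gene-panel experiment:
#' a handful of true somatic mosaic variants shared by every library,
#' plus thousands of library-specific false positives that emulate
#' polymerase errors arising in the first cycles of pre-capture PCR.
#' Each library (polymerase x replicate) gets its own error set, placed
#' uniformly over the panel, so recurrence of an error across libraries
#' happens only by positional collision; callers observe a shared error
#' pool per library but report different subsets of it, with
#' caller-specific call loads and filter pass rates.
#'
#' Defaults encode the study conditions the model is calibrated to:
#' 3 polymerases x 2 replicates over a ~1 Mb panel; 6 true variants at
#' VAF 0.15-0.3 and mean depth 300; per-run VAF fluctuation with SD
#' ~0.08 (multiplicative lognormal amplification bias); per-caller
#' per-replicate false-positive loads of 2000-4000 (strelka2-like, of
#' which ~15% pass filters), 200-1000 then 1700-3000 (mutect2-like,
#' ~35% passing), and 150-600 then 50-120 (lofreq-like, which emits
#' passing calls only).
#'
#' @param n_regions,region_length Panel geometry: number of target
#'   regions and bases per region (defaults 500 x 2000 bp = 1 Mb).
#' @param polymerases,replicates,callers Experiment design labels.
#' @param n_true Number of planted mosaic variants.
#' @param true_vaf_range True VAF range (uniform draw).
#' @param run_bias_sd Target SD of per-library realized VAF around the
#'   true VAF (on the VAF scale, at the mid-range true VAF).
#' @param mean_depth,depth_dispersion Negative-binomial per-call depth.
#' @param fp_pool_range Range of the per-library polymerase-error pool
#'   size (the superset of what any caller reports).
#' @param fp_count_ranges Named list (per caller) of per-replicate
#'   `c(lo, hi)` ranges for the number of errors that caller reports.
#' @param pass_rates Named per-caller probability that a false-positive
#'   call is marked filter-passing.
#' @param true_pass_prob Probability a true-variant call passes filters.
#' @param fp_vaf_shape,fp_vaf_max Beta shape parameters and truncation
#'   for false-positive VAFs (low, sub-clonal).
#' @param alt_min Minimum alternate reads for a true variant to be
#'   callable in a library.
#' @param caller_vaf_noise_sd SD (VAF scale) of caller-specific
#'   re-estimation noise, applied as a perturbation of the alternate
#'   read count so reported VAFs stay count-consistent.
#' @param region_depth_cv Lognormal CV of per-region mean depth in the
#'   emitted depth tracks.
#' @param reads_total Nominal total mapped reads a full library
#'   corresponds to (used by [saturation_curve()] thinning).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_regions = 500,
                       region_length = 2000,
                       polymerases = c("Agilent", "KAPA", "NEB"),
                       replicates = 2,
                       callers = c("strelka2", "mutect2", "lofreq"),
                       n_true = 6,
                       true_vaf_range = c(0.15, 0.3),
                       run_bias_sd = 0.08,
                       mean_depth = 300,
                       depth_dispersion = 10,
                       fp_pool_range = c(2000, 4000),
                       fp_count_ranges = list(
                         strelka2 = list(c(2000, 4000), c(2000, 4000)),
                         mutect2 = list(c(200, 1000), c(1700, 3000)),
                         lofreq = list(c(150, 600), c(50, 120))),
                       pass_rates = c(strelka2 = 0.15, mutect2 = 0.35,
                                      lofreq = 1),
                       true_pass_prob = 0.9,
                       fp_vaf_shape = c(1, 15),
                       fp_vaf_max = 0.1,
                       alt_min = 3,
                       caller_vaf_noise_sd = 0.005,
                       region_depth_cv = 0.3,
                       reads_total = 600000) {
  replicates <- as.integer(replicates)
  stopifnot(n_regions >= 1, region_length >= 1,
            length(polymerases) >= 1, replicates >= 1,
            length(callers) >= 1,
            n_true >= 0,
            length(true_vaf_range) == 2,
            true_vaf_range[1] > 0, true_vaf_range[2] < 1,
            true_vaf_range[1] <= true_vaf_range[2],
            run_bias_sd >= 0, mean_depth > 0, depth_dispersion > 0,
            length(fp_pool_range) == 2,
            fp_pool_range[1] >= 0, fp_pool_range[1] <= fp_pool_range[2],
            fp_vaf_max > 0, fp_vaf_max <= 1,
            alt_min >= 0, caller_vaf_noise_sd >= 0, reads_total > 0)
  if (!all(callers %in% names(fp_count_ranges))) {
    abort("`fp_count_ranges` must name every caller")
  }
  if (!all(callers %in% names(pass_rates))) {
    abort("`pass_rates` must name every caller")
  }
  if (any(pass_rates < 0 | pass_rates > 1) ||
      true_pass_prob < 0 || true_pass_prob > 1) {
    abort("pass probabilities must lie in [0, 1]")
  }
  fp_count_ranges <- lapply(fp_count_ranges, function(rg) {
    if (!is.list(rg)) rg <- list(rg)
    if (length(rg) == 1) rg <- rep(rg, replicates)
    if (length(rg) != replicates) {
      abort("each caller's fp_count_ranges must have one range per replicate")
    }
    rg
  })
  if (fp_pool_range[2] >= n_regions * region_length) {
    abort("false-positive pool exceeds panel size")
  }
  structure(list(
    n_regions = n_regions, region_length = region_length,
    polymerases = polymerases, replicates = replicates,
    callers = callers, n_true = n_true,
    true_vaf_range = true_vaf_range, run_bias_sd = run_bias_sd,
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    fp_pool_range = fp_pool_range, fp_count_ranges = fp_count_ranges,
    pass_rates = pass_rates, true_pass_prob = true_pass_prob,
    fp_vaf_shape = fp_vaf_shape, fp_vaf_max = fp_vaf_max,
    alt_min = alt_min, caller_vaf_noise_sd = caller_vaf_noise_sd,
    region_depth_cv = region_depth_cv, reads_total = reads_total),
    class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# Deterministic synthetic reference: every position has a fixed reference
# base and a fixed characteristic error substitution (polymerase errors
# are modeled as context-determined), so the same site hit in two
# libraries yields the same variant and cross-library recurrence is a
# pure positional-collision process.
sim_ref_base <- function(pos) BASES[(pos %% 4L) + 1L]
sim_err_alt <- function(pos) {
  BASES[((pos %% 4L) + (pos %% 3L) + 1L) %% 4L + 1L]
}

trunc_beta <- function(n, shape, max) {
  qbeta(runif(n) * pbeta(max, shape[1], shape[2]), shape[1], shape[2])
}

#' Simulate a dual deep-sequencing experiment
#'
#' Generates a complete synthetic experiment under the model described
#' in [sim_config()]: a tiled target panel on a synthetic genome,
#' planted mosaic variants with library-specific lognormal amplification
#' bias and binomial read sampling, per-library polymerase-error pools
#' reported caller-specifically, and (optionally) per-base depth
#' tracks. The result is fully deterministic for a given
#' `(config, seed)` pair.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param with_depth Also generate per-library per-base depth tracks
#'   (skipped by default: they dominate memory for megabase panels).
#' @param dir Optional directory: when given, per-run VCFs (each in its
#'   caller's dialect), the panel BED, depth TSVs and truth TSVs are
#'   written there.
#' @return A `sim_experiment` list: `calls` (tibble of every emitted
#'   call, with `origin` "true"/"error"), `truth` (planted variants with
#'   per-library realizations; library error pools), `panel`, `design`,
#'   `depth_tracks` (named list or `NULL`), `config`, `seed`, and
#'   `files` when `dir` was given.
#' @export
simulate_experiment <- function(config, seed, with_depth = FALSE,
                                dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(seed), {
    sim_experiment_impl(config, seed, with_depth, dir)
  })
}

sim_experiment_impl <- function(config, seed, with_depth, dir) {
  len <- config$region_length
  gap <- 1000L
  starts0 <- as.integer((seq_len(config$n_regions) - 1L) * (len + gap))
  panel <- tibble(chrom = "chr1", start = starts0, end = starts0 + len,
                  name = sprintf("region_%04d", seq_len(config$n_regions)))
  pos_all <- rep(starts0, each = len) + sequence(rep(len, config$n_regions))
  L <- length(pos_all)

  libraries <- expand_grid(polymerase = config$polymerases,
                           replicate = seq_len(config$replicates))
  n_lib <- nrow(libraries)
  reps <- seq_len(config$replicates)

  # --- planted true variants -------------------------------------------
  idx_true <- if (config$n_true > 0) sort(sample.int(L, config$n_true))
              else integer(0)
  pos_true <- pos_all[idx_true]
  ref_true <- sim_ref_base(pos_true)
  alt_true <- vapply(ref_true,
                     function(b) sample(setdiff(BASES, b), 1), "")
  true_vaf <- runif(config$n_true, config$true_vaf_range[1],
                    config$true_vaf_range[2])
  key_true <- variant_id("chr1", pos_true, ref_true, alt_true)

  cv_bias <- config$run_bias_sd / base::mean(config$true_vaf_range)
  sigma2 <- log(1 + cv_bias^2)

  planted <- NULL
  if (config$n_true > 0) {
    planted <- expand_grid(v = seq_len(config$n_true),
                           lib = seq_len(n_lib)) |>
      mutate(key = key_true[.data$v],
             chrom = "chr1", pos = pos_true[.data$v],
             ref = ref_true[.data$v], alt = alt_true[.data$v],
             polymerase = libraries$polymerase[.data$lib],
             replicate = libraries$replicate[.data$lib],
             true_vaf = true_vaf[.data$v])
    bias <- exp(rnorm(nrow(planted), -sigma2 / 2, sqrt(sigma2)))
    planted$realized_vaf <- pmin(pmax(planted$true_vaf * bias, 1e-4), 0.999)
    planted$depth <- pmax(1L, rnbinom(nrow(planted),
                                      mu = config$mean_depth,
                                      size = config$depth_dispersion))
    planted$alt_count <- rbinom(nrow(planted), planted$depth,
                                planted$realized_vaf)
    planted$detected <- planted$alt_count >= config$alt_min
  } else {
    planted <- tibble(v = integer(), lib = integer(), key = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      polymerase = character(), replicate = integer(),
                      true_vaf = double(), realized_vaf = double(),
                      depth = integer(), alt_count = integer(),
                      detected = logical())
  }

  # --- per-library polymerase-error pools ------------------------------
  free_idx <- if (config$n_true > 0) seq_len(L)[-idx_true] else seq_len(L)
  pools <- vector("list", n_lib)
  for (l in seq_len(n_lib)) {
    pool_n <- as.integer(round(runif(1, config$fp_pool_range[1],
                                     config$fp_pool_range[2])))
    p_idx <- sample(free_idx, pool_n)
    p_pos <- pos_all[p_idx]
    depth <- pmax(1L, rnbinom(pool_n, mu = config$mean_depth,
                              size = config$depth_dispersion))
    vaf <- trunc_beta(pool_n, config$fp_vaf_shape, config$fp_vaf_max)
    alt_reads <- pmax(1L, rbinom(pool_n, depth, vaf))
    pools[[l]] <- tibble(
      chrom = "chr1", pos = p_pos,
      ref = sim_ref_base(p_pos), alt = sim_err_alt(p_pos),
      polymerase = libraries$polymerase[l],
      replicate = libraries$replicate[l],
      depth = depth, alt_count = alt_reads) |>
      mutate(key = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt))
  }

  # --- caller-reported calls -------------------------------------------
  jitter_alt <- function(alt, depth) {
    if (config$caller_vaf_noise_sd == 0) return(as.integer(alt))
    as.integer(pmin(pmax(
      alt + round(rnorm(length(alt), 0, config$caller_vaf_noise_sd * depth)),
      0L), depth))
  }
  call_rows <- list()
  for (cl in config$callers) {
    det_true <- planted[planted$detected, , drop = FALSE]
    if (nrow(det_true) > 0) {
      alt_c <- jitter_alt(det_true$alt_count, det_true$depth)
      call_rows[[length(call_rows) + 1]] <- tibble(
        chrom = det_true$chrom, pos = det_true$pos,
        ref = det_true$ref, alt = det_true$alt, key = det_true$key,
        caller = cl,
        polymerase = det_true$polymerase, replicate = det_true$replicate,
        vaf = alt_c / det_true$depth,
        depth = as.double(det_true$depth), alt_count = as.double(alt_c),
        passed = runif(nrow(det_true)) < config$true_pass_prob,
        origin = "true")
    }
    for (l in seq_len(n_lib)) {
      pool <- pools[[l]]
      r <- libraries$replicate[l]
      rg <- config$fp_count_ranges[[cl]][[r]]
      n_call <- min(nrow(pool),
                    as.integer(round(runif(1, rg[1], rg[2]))))
      sel <- pool[sample.int(nrow(pool), n_call), , drop = FALSE]
      alt_c <- jitter_alt(sel$alt_count, sel$depth)
      alt_c <- pmax(alt_c, 1L) # a caller never reports zero supporting reads
      call_rows[[length(call_rows) + 1]] <- tibble(
        chrom = sel$chrom, pos = sel$pos, ref = sel$ref, alt = sel$alt,
        key = sel$key, caller = cl,
        polymerase = sel$polymerase, replicate = sel$replicate,
        vaf = alt_c / sel$depth,
        depth = as.double(sel$depth), alt_count = as.double(alt_c),
        passed = runif(n_call) < config$pass_rates[[cl]],
        origin = "error")
    }
  }
  calls <- bind_rows(call_rows)
  if (nrow(calls) == 0) {
    calls <- tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), key = character(), caller = character(),
                    polymerase = character(), replicate = integer(),
                    vaf = double(), depth = double(), alt_count = double(),
                    passed = logical(), origin = character())
  }

  # --- depth tracks ----------------------------------------------------
  depth_tracks <- NULL
  if (with_depth) {
    s2 <- log(1 + config$region_depth_cv^2)
    depth_tracks <- list()
    for (l in seq_len(n_lib)) {
      region_mu <- config$mean_depth *
        exp(rnorm(config$n_regions, -s2 / 2, sqrt(s2)))
      d <- rpois(L, rep(region_mu, each = len))
      keep <- d > 0
      depth_tracks[[paste0(libraries$polymerase[l], "_rep",
                           libraries$replicate[l])]] <-
        tibble(chrom = "chr1", pos = pos_all[keep], depth = d[keep])
    }
  }

  out <- structure(list(
    calls = calls,
    truth = list(
      planted = planted[, setdiff(names(planted), c("v", "lib"))],
      planted_keys = key_true,
      errors = bind_rows(pools)),
    panel = panel,
    design = detection_design(config$callers, config$polymerases,
                              config$replicates),
    depth_tracks = depth_tracks,
    config = config, seed = seed),
    class = "sim_experiment")

  if (!is.null(dir)) out$files <- write_experiment(out, dir)
  out
}

write_experiment <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  files$panel <- file.path(dir, "panel.bed")
  write_bed(x$panel, files$panel)
  files$vcf <- character(0)
  for (i in seq_len(nrow(x$design))) {
    cl <- x$design$caller[i]; p <- x$design$polymerase[i]
    r <- x$design$replicate[i]
    path <- file.path(dir, sprintf("%s_%s_rep%d.vcf", cl, p, r))
    run_calls <- filter(x$calls, .data$caller == cl,
                        .data$polymerase == p, .data$replicate == r)
    write_vcf(run_calls, dialect = if (cl %in% c("strelka2", "mutect2",
                                                 "lofreq")) cl
              else "generic",
              path = path)
    files$vcf <- c(files$vcf, setNames(path, paste(cl, p, r, sep = "_")))
  }
  if (!is.null(x$depth_tracks)) {
    files$depth <- character(0)
    for (nm in names(x$depth_tracks)) {
      path <- file.path(dir, paste0("depth_", nm, ".tsv"))
      readr::write_tsv(x$depth_tracks[[nm]], path, col_names = FALSE)
      files$depth <- c(files$depth, setNames(path, nm))
    }
  }
  files$truth_planted <- file.path(dir, "truth_planted.tsv")
  readr::write_tsv(x$truth$planted, files$truth_planted)
  files$truth_errors <- file.path(dir, "truth_errors.tsv")
  readr::write_tsv(x$truth$errors, files$truth_errors)
  files
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("<sim_experiment> seed", x$seed, "\n")
  cat("  panel:", nrow(x$panel), "regions,",
      sum(x$panel$end - x$panel$start), "bases\n")
  cat("  planted variants:", length(x$truth$planted_keys),
      "| calls:", nrow(x$calls), "\n")
  invisible(x)
}

#' @export
tidy.sim_experiment <- function(x, ...) x$calls

#' @export
glance.sim_experiment <- function(x, ...) {
  x$calls |>
    group_by(.data$caller, .data$replicate) |>
    summarise(n_calls = dplyr::n(), n_passed = sum(.data$passed),
              n_true = sum(.data$origin == "true"), .groups = "drop")
}

#' Precision and recall of the pipeline against the planted truth
#'
#' Runs the consensus machinery on a simulated experiment and scores
#' each per-caller category set, and the cross-caller consensus, against
#' the planted variants: the synthetic analogue of orthogonal wet-lab
#' validation of candidate variants.
#'
#' @param experiment A [simulate_experiment()] result.
#' @param mode Filter mode passed to [categorize_all()].
#' @param categories Categories whose union forms the candidate set.
#' @return A list with `per_category` (per caller x category: size,
#'   true/false-positive composition, precision, recall) and `consensus`
#'   (one row: cross-caller consensus size, precision, recall).
#' @export
evaluate_recovery <- function(experiment, mode = "all",
                              categories = c(1L, 2L)) {
  stopifnot(inherits(experiment, "sim_experiment"))
  truth_keys <- experiment$truth$planted_keys
  m <- build_detection_matrix(
    select(experiment$calls, -"origin"), experiment$design)
  callers <- unique(experiment$design$caller)
  asg <- lapply(setNames(callers, callers),
                function(cl) categorize_all(m, cl, mode = mode))
  score <- function(keys) {
    tp <- sum(keys %in% truth_keys)
    tibble(n = length(keys), n_true = tp, n_false = length(keys) - tp,
           precision = if (length(keys) > 0) tp / length(keys) else NA_real_,
           recall = if (length(truth_keys) > 0) tp / length(truth_keys)
                    else NA_real_)
  }
  per_category <- expand_grid(caller = callers, category = 1:4) |>
    pmap(function(caller, category) {
      keys <- asg[[caller]]$key[asg[[caller]]$category == category]
      bind_cols(tibble(caller = caller, category = category), score(keys))
    }) |>
    list_rbind()
  cons <- cross_caller_consensus(asg, categories = categories)
  list(per_category = per_category,
       consensus = bind_cols(
         tibble(categories = paste(categories, collapse = "+")),
         score(cons$consensus)),
       assignments = asg,
       cross_caller = cons)
}

#' @rdname saturation_curve
#' @export
saturation_curve.sim_experiment <- function(x, n_list, seed, ...) {
  check_n_list(n_list, x$config$reads_total)
  calls <- x$calls
  rows <- withr::with_seed(as.integer(seed), {
    lapply(n_list, function(n) {
      f <- n / x$config$reads_total
      alt_n <- rbinom(nrow(calls), calls$alt_count, f)
      # true variants stay callable while they retain alt_min supporting
      # reads; error calls persist while any supporting read remains
      thr <- ifelse(calls$origin == "true", x$config$alt_min, 1L)
      kept <- calls[alt_n >= thr, , drop = FALSE]
      m <- build_detection_matrix(select(kept, -"origin"), x$design)
      per_caller <- lapply(unique(x$design$caller), function(cl) {
        a <- categorize_all(m, cl, mode = "all")
        tibble(n_reads = n, caller = cl, n_detected = nrow(a),
               n_category_12 = sum(a$category %in% 1:2))
      })
      out <- bind_rows(per_caller)
      if (!is.null(x$depth_tracks)) {
        cov <- lapply(x$depth_tracks, function(tr) {
          thinned <- tr
          thinned$depth <- rbinom(nrow(tr), tr$depth, f)
          coverage_metrics(thinned[thinned$depth > 0, ], x$panel)
        })
        cov <- bind_rows(cov) |>
          summarise(across(c("average_depth", "coverage_rate",
                             "pct_regions_full", "pct_regions_zero"),
                           base::mean))
        out <- bind_cols(out, cov[rep(1, nrow(out)), ])
      }
      out
    })
  })
  out <- bind_rows(rows)
  structure(out, class = c("saturation_curve", class(out)))
}
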