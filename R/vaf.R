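#' Per-variant VAF summaries
#'
#' Summarises the variant allele frequencies observed for each variant
#' across runs, either overall, per caller, or per (polymerase,
#' replicate) library. Sample standard deviation (n - 1 denominator) is
#' reported; `sd` is `NA` for fewer than two observations. Missing VAFs
#' are excluded and counted in `n_missing`.
#'
#' @param calls Call tibble with `key`, `vaf` and the grouping columns
#'   (`caller`, `polymerase`, `replicate` as needed).
#' @param grouping `"overall"`, `"by_caller"`, or `"by_run"`.
#' @param variants Optional vector of keys to restrict to.
#' @return A tibble with one row per variant (x group), columns `n`,
#'   `n_missing`, `mean`, `sd`, `min`, `max` (fractions in `[0, 1]`).
#' @export
vaf_summary <- function(calls,
                        grouping = c("overall", "by_caller", "by_run"),
                        variants = NULL) {
  grouping <- match.arg(grouping)
  calls <- as_tibble(calls)
  if (!is.null(variants)) calls <- filter(calls, .data$key %in% variants)
  group_cols <- switch(grouping,
                       overall = "key",
                       by_caller = c("key", "caller"),
                       by_run = c("key", "polymerase", "replicate"))
  calls |>
    group_by(across(all_of(group_cols))) |>
    summarise(
      n = sum(!is.na(.data$vaf)),
      n_missing = sum(is.na(.data$vaf)),
      mean = if (sum(!is.na(.data$vaf)) > 0)
        base::mean(.data$vaf, na.rm = TRUE) else NA_real_,
      sd = if (sum(!is.na(.data$vaf)) >= 2)
        stats::sd(.data$vaf, na.rm = TRUE) else NA_real_,
      min = if (sum(!is.na(.data$vaf)) > 0)
        base::min(.data$vaf, na.rm = TRUE) else NA_real_,
      max = if (sum(!is.na(.data$vaf)) > 0)
        base::max(.data$vaf, na.rm = TRUE) else NA_real_,
      .groups = "drop")
}

#' Between-run versus between-caller VAF variability
#'
#' For each consensus variant, contrasts two standard deviations: the SD
#' of VAF across callers within each (polymerase, replicate) library
#' (how much the callers disagree on the same data) and the SD across
#' libraries within each caller (how much the PCR/library step
#' fluctuates). The ratio of their means quantifies whether run-to-run
#' variation exceeds caller-to-caller variation.
#'
#' @param x A [build_detection_matrix()] result (or a plain call tibble).
#' @param variants Character vector of consensus variant keys; each must
#'   be observed with non-missing VAF in at least 2 callers and at least
#'   2 libraries, otherwise it is skipped with a message.
#' @return A `vaf_decomposition` tibble: per variant, `mean_caller_sd`,
#'   `mean_run_sd`, `run_to_caller_ratio`, plus observation counts.
#' @export
vaf_variance_decomposition <- function(x, variants) {
  calls <- if (inherits(x, "detection_matrix")) x$calls else as_tibble(x)
  rows <- lapply(variants, function(k) {
    v <- filter(calls, .data$key == k, !is.na(.data$vaf))
    if (dplyr::n_distinct(v$caller) < 2 ||
        dplyr::n_distinct(paste(v$polymerase, v$replicate)) < 2) {
      inform(paste0("vaf_variance_decomposition: skipping ", k,
                    " (needs >= 2 callers and >= 2 libraries)"))
      return(NULL)
    }
    caller_sd <- v |>
      group_by(.data$polymerase, .data$replicate) |>
      summarise(s = if (dplyr::n() >= 2) stats::sd(.data$vaf) else NA_real_,
                .groups = "drop") |>
      pull(.data$s)
    run_sd <- v |>
      group_by(.data$caller) |>
      summarise(s = if (dplyr::n() >= 2) stats::sd(.data$vaf) else NA_real_,
                .groups = "drop") |>
      pull(.data$s)
    mean_caller_sd <- base::mean(caller_sd, na.rm = TRUE)
    mean_run_sd <- base::mean(run_sd, na.rm = TRUE)
    tibble(key = k,
           n_obs = nrow(v),
           n_callers = dplyr::n_distinct(v$caller),
           n_libraries = dplyr::n_distinct(paste(v$polymerase, v$replicate)),
           mean_caller_sd = mean_caller_sd,
           mean_run_sd = mean_run_sd,
           run_to_caller_ratio =
             if (is.finite(mean_caller_sd) && mean_caller_sd > 0)
               mean_run_sd / mean_caller_sd else NA_real_)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(key = character(), n_obs = integer(),
                  n_callers = integer(), n_libraries = integer(),
                  mean_caller_sd = double(), mean_run_sd = double(),
                  run_to_caller_ratio = double())
  }
  structure(out, class = c("vaf_decomposition", class(out)))
}
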