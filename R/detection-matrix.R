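#' Build the experiment design grid
#'
#' The design of a dual-sequencing experiment is the full grid of
#' caller x polymerase x replicate coordinates ("runs"); one VCF call set
#' is expected per run.
#'
#' @param callers Character vector of variant-caller labels.
#' @param polymerases Character vector of DNA-polymerase labels.
#' @param replicates Number of replicate sequencing experiments (or an
#'   integer vector of replicate indices).
#' @return A tibble with columns `caller`, `polymerase`, `replicate`.
#' @examples
#' detection_design(c("strelka2", "mutect2"), c("KAPA", "NEB"), 2)
#' @export
detection_design <- function(callers, polymerases, replicates) {
  if (length(replicates) == 1) replicates <- seq_len(replicates)
  stopifnot(length(callers) >= 1, length(polymerases) >= 1,
            !anyDuplicated(callers), !anyDuplicated(polymerases))
  expand_grid(caller = as.character(callers),
              polymerase = as.character(polymerases),
              replicate = as.integer(replicates))
}

#' Assemble variant calls into a detection matrix
#'
#' Groups normalized calls by caller and variant identity, recording for
#' each (caller, variant) the set of (polymerase, replicate) libraries
#' that detected it. This is the central data structure from which Venn
#' groups, reproducibility categories and the cross-caller consensus are
#' derived.
#'
#' @param calls A data frame of calls with columns `chrom`, `pos`, `ref`,
#'   `alt` (or a precomputed `key`), `caller`, `polymerase`, `replicate`,
#'   `passed`, and optionally `vaf`, `depth`, `alt_count`.
#' @param design The expected run grid, from [detection_design()]. Every
#'   call must belong to a declared run; runs without calls contribute
#'   empty sets.
#' @return A `detection_matrix` object: a list with the validated `calls`
#'   tibble and the `design` tibble.
#' @examples
#' design <- detection_design("strelka2", c("KAPA", "NEB"), 2)
#' calls <- tibble::tibble(
#'   chrom = "chr1", pos = 100, ref = "C", alt = "T",
#'   caller = "strelka2", polymerase = "KAPA", replicate = 1L,
#'   passed = TRUE, vaf = 0.2, depth = 300L, alt_count = 60L)
#' build_detection_matrix(calls, design)
#' @export
build_detection_matrix <- function(calls, design) {
  stopifnot(is.data.frame(design),
            all(c("caller", "polymerase", "replicate") %in% names(design)))
  calls <- as_tibble(calls)
  for (col in c("vaf", "depth", "alt_count")) {
    if (!col %in% names(calls)) calls[[col]] <- NA_real_
  }
  need <- c("caller", "polymerase", "replicate", "passed")
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols) > 0) {
    abort(paste0("`calls` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"key" %in% names(calls)) calls <- normalize_variants(calls)
  calls$replicate <- as.integer(calls$replicate)

  stray <- anti_join(distinct(calls, .data$caller, .data$polymerase, .data$replicate),
                     design, by = c("caller", "polymerase", "replicate"))
  if (nrow(stray) > 0) {
    abort(paste0("calls from run(s) outside the design, e.g. ",
                 stray$caller[1], "/", stray$polymerase[1],
                 "/rep", stray$replicate[1]))
  }
  dup <- calls |>
    count(.data$key, .data$caller, .data$polymerase, .data$replicate) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate call for variant ", dup$key[1], " in run ",
                 dup$caller[1], "/", dup$polymerase[1], "/rep",
                 dup$replicate[1], " (", nrow(dup), " duplicated pair(s))"))
  }
  structure(list(calls = calls, design = as_tibble(design)),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("<detection_matrix>\n")
  cat("  runs in design:", nrow(x$design),
      "| calls:", nrow(x$calls),
      "| distinct variants:", dplyr::n_distinct(x$calls$key), "\n")
  invisible(x)
}

#' @export
tidy.detection_matrix <- function(x, ...) x$calls

#' @export
glance.detection_matrix <- function(x, ...) {
  tibble(n_runs = nrow(x$design),
         n_calls = nrow(x$calls),
         n_variants = dplyr::n_distinct(x$calls$key),
         n_callers = dplyr::n_distinct(x$design$caller),
         n_polymerases = dplyr::n_distinct(x$design$polymerase),
         n_replicates = dplyr::n_distinct(x$design$replicate))
}

#' Per-replicate polymerase support for variants of one caller
#'
#' For each variant in one caller's call sets, counts how many distinct
#' polymerase libraries detected it in each replicate experiment. These
#' support tuples drive the category 1-4 classification.
#'
#' @param x A [build_detection_matrix()] result.
#' @param caller Caller label to tabulate.
#' @param variants Optional character vector of variant keys to restrict
#'   to; requesting a variant absent from the caller's calls is an error.
#' @param passed_only If `TRUE`, only calls that passed the caller's own
#'   filters count as detections.
#' @return A tibble with `key` and one integer column `rep_<r>` per
#'   replicate in the design (0 when no library detected the variant in
#'   that replicate).
#' @export
replicate_support <- function(x, caller, variants = NULL, passed_only = FALSE) {
  stopifnot(inherits(x, "detection_matrix"))
  if (!caller %in% x$design$caller) {
    abort(paste0("unknown caller: ", caller))
  }
  reps <- sort(unique(x$design$replicate))
  calls <- filter(x$calls, .data$caller == !!caller)
  if (passed_only) calls <- filter(calls, .data$passed)
  sup <- calls |>
    distinct(.data$key, .data$replicate, .data$polymerase) |>
    count(.data$key, .data$replicate) |>
    pivot_wider(names_from = "replicate", values_from = "n",
                names_prefix = "rep_", values_fill = 0L)
  for (r in reps) {
    col <- paste0("rep_", r)
    if (!col %in% names(sup)) sup[[col]] <- 0L
  }
  sup <- sup[, c("key", paste0("rep_", reps))]
  if (!is.null(variants)) {
    miss <- setdiff(variants, sup$key)
    if (length(miss) > 0) {
      abort(paste0("variant not detected by ", caller, ": ", miss[1]))
    }
    sup <- sup[match(variants, sup$key), ]
  }
  sup
}
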