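#' Three-set Venn partition of variant sets
#'
#' Partitions the union of three variant-key sets into the seven classic
#' Venn regions. Regions 1-3 are the parts exclusive to the first, second
#' and third set, regions 4-6 the pairwise-only intersections (1&2, 1&3,
#' 2&3), and region 7 the triple intersection. Region numbering follows
#' the order the sets are supplied in.
#'
#' @param set_a,set_b,set_c Character vectors of variant keys.
#' @param labels Length-3 character vector of distinct set labels.
#' @return A `venn_partition`: a tibble with one row per distinct key and
#'   columns `key`, `region` (1-7) and `region_label`.
#' @examples
#' venn_groups(c("a", "b"), c("a"), c("a", "c"),
#'             labels = c("KAPA", "NEB", "Agilent"))
#' @export
venn_groups <- function(set_a, set_b, set_c, labels = c("A", "B", "C")) {
  if (length(labels) != 3 || anyDuplicated(labels)) {
    abort("`labels` must be 3 distinct set labels")
  }
  keys <- unique(c(set_a, set_b, set_c))
  code <- (keys %in% set_a) + 2L * (keys %in% set_b) + 4L * (keys %in% set_c)
  # membership code (a + 2b + 4c) -> region 1..7
  region_of_code <- c(`1` = 1L, `2` = 2L, `4` = 3L,
                      `3` = 4L, `5` = 5L, `6` = 6L, `7` = 7L)
  region <- unname(region_of_code[as.character(code)])
  region_labels <- c(
    paste0(labels[1], " only"), paste0(labels[2], " only"),
    paste0(labels[3], " only"),
    paste0(labels[1], "&", labels[2]), paste0(labels[1], "&", labels[3]),
    paste0(labels[2], "&", labels[3]),
    paste(labels, collapse = "&"))
  out <- tibble(key = keys, region = region,
                region_label = region_labels[region]) |>
    arrange(.data$region, .data$key)
  structure(out, labels = labels, region_labels = region_labels,
            class = c("venn_partition", class(out)))
}

#' @export
glance.venn_partition <- function(x, ...) {
  n <- vapply(1:7, function(r) sum(x$region == r), integer(1))
  out <- as_tibble(as.list(setNames(n, paste0("region_", 1:7))))
  out$n_total <- nrow(x)
  out
}

#' Classify replicate-support tuples into reproducibility categories
#'
#' Implements the four-way classification of somatic variants by
#' cross-polymerase, cross-replicate reproducibility:
#' \describe{
#'   \item{category 1}{detected by all polymerases in every replicate
#'     experiment;}
#'   \item{category 2}{detected by at least two polymerases in every
#'     replicate (but not all in all);}
#'   \item{category 3}{detected by at least two polymerases in exactly
#'     one replicate;}
#'   \item{category 4}{never reaches two polymerases in any replicate
#'     (single-polymerase detections only).}
#' }
#' "Two of three polymerases" is read as a threshold (>= 2), which makes
#' the four categories a total partition of all nonzero support tuples.
#'
#' @param support A data frame of per-replicate polymerase counts (the
#'   `rep_*` columns of [replicate_support()]; a `key` column is carried
#'   through), a numeric matrix with one column per replicate, or a
#'   single tuple as a numeric vector.
#' @param n_polymerases Number of polymerases in the design (the count
#'   required for category 1).
#' @return An integer vector of categories (1-4), or, for data-frame
#'   input, the input tibble with a `category` column appended.
#' @examples
#' classify_category(c(3, 3), n_polymerases = 3) # category 1
#' classify_category(c(2, 0), n_polymerases = 3) # category 3
#' @export
classify_category <- function(support, n_polymerases) {
  df_in <- is.data.frame(support)
  if (df_in) {
    rep_cols <- grep("^rep_", names(support), value = TRUE)
    if (length(rep_cols) == 0) abort("no rep_* columns in `support`")
    m <- as.matrix(support[, rep_cols])
  } else if (is.matrix(support)) {
    m <- support
  } else {
    m <- matrix(support, nrow = 1)
  }
  storage.mode(m) <- "integer"
  if (any(m < 0) || any(m > n_polymerases)) {
    abort("support counts must lie in [0, n_polymerases]")
  }
  if (any(rowSums(m) == 0)) {
    abort("all-zero support tuple: not a detected variant")
  }
  min_sup <- apply(m, 1, min)
  n_multi <- rowSums(m >= 2L) # replicates reaching 2 polymerases
  category <- rep.int(4L, nrow(m))
  category[n_multi == 1L] <- 3L
  category[min_sup >= 2L] <- 2L
  category[min_sup == n_polymerases] <- 1L
  if (df_in) {
    support$category <- category
    support
  } else category
}

#' Categorize every variant detected by one caller
#'
#' Computes replicate-support tuples for all of a caller's variants and
#' assigns each to reproducibility category 1-4. With `mode = "passed"`,
#' only calls that passed the caller's internal filters count as
#' detections (support is recomputed, so a variant's category can change
#' in either direction relative to `mode = "all"`).
#'
#' @param x A [build_detection_matrix()] result.
#' @param caller Caller label.
#' @param mode `"all"` (every call) or `"passed"` (filter-passing calls
#'   only).
#' @return A `category_assignment`: tibble with `key`, one `rep_*` support
#'   column per replicate, and `category`; attributes record the caller,
#'   mode and design dimensions. [glance()] gives per-category counts and
#'   percentages.
#' @export
categorize_all <- function(x, caller, mode = c("all", "passed")) {
  mode <- match.arg(mode)
  n_pol <- dplyr::n_distinct(x$design$polymerase)
  sup <- replicate_support(x, caller, passed_only = (mode == "passed"))
  out <- if (nrow(sup) == 0) {
    sup$category <- integer(0)
    sup
  } else {
    classify_category(sup, n_polymerases = n_pol)
  }
  structure(out, caller = caller, mode = mode,
            n_polymerases = n_pol,
            n_replicates = dplyr::n_distinct(x$design$replicate),
            class = c("category_assignment", class(out)))
}

#' @export
glance.category_assignment <- function(x, ...) {
  n <- vapply(1:4, function(k) sum(x$category == k), integer(1))
  total <- nrow(x)
  pct <- if (total > 0) 100 * n / total else rep(0, 4)
  tibble(caller = attr(x, "caller"), mode = attr(x, "mode"),
         n_variants = total,
         n_category_1 = n[1], n_category_2 = n[2],
         n_category_3 = n[3], n_category_4 = n[4],
         pct_category_1 = pct[1], pct_category_2 = pct[2],
         pct_category_3 = pct[3], pct_category_4 = pct[4],
         pct_category_12 = pct[1] + pct[2])
}

#' Cross-caller consensus of reproducible variants
#'
#' Intersects the per-caller sets of category-1/2 variants (the variants
#' reproducibly detected across polymerase libraries in every replicate).
#' The variants found by every caller are the pipeline's headline
#' consensus output. With exactly three callers the full 7-region Venn
#' partition of the sets is also returned.
#'
#' @param assignments Named list of [categorize_all()] results, one per
#'   caller, computed from the same detection matrix.
#' @param categories Categories counted as reproducible (default 1 and 2).
#' @return A `cross_caller_consensus` list with `sets` (per-caller key
#'   sets), `venn` (a [venn_groups()] partition, or `NULL` unless three
#'   callers), and `consensus` (keys present in every caller's set).
#' @export
cross_caller_consensus <- function(assignments, categories = c(1L, 2L)) {
  stopifnot(is.list(assignments), length(assignments) >= 1)
  if (is.null(names(assignments)) || any(names(assignments) == "")) {
    names(assignments) <- vapply(assignments, attr, "", which = "caller")
  }
  if (length(assignments) == 1) {
    warn("single caller: consensus degenerates to its own category set")
  }
  sets <- lapply(assignments,
                 function(a) a$key[a$category %in% categories])
  venn <- if (length(sets) == 3) {
    venn_groups(sets[[1]], sets[[2]], sets[[3]], labels = names(sets))
  } else NULL
  structure(list(sets = sets, venn = venn,
                 consensus = Reduce(intersect, sets),
                 categories = categories),
            class = "cross_caller_consensus")
}

#' @export
print.cross_caller_consensus <- function(x, ...) {
  cat("<cross_caller_consensus> categories",
      paste(x$categories, collapse = "+"), "\n")
  for (nm in names(x$sets)) {
    cat("  ", nm, ":", length(x$sets[[nm]]), "variants\n")
  }
  cat("  consensus (all callers):", length(x$consensus), "variants\n")
  invisible(x)
}

#' Full count report for a dual-sequencing experiment
#'
#' The machine-readable summary of an experiment: per-run call counts,
#' per-caller Venn groups across polymerases (per replicate), per-caller
#' category counts/percentages, and cross-caller consensus sizes --
#' everything computed in both filter modes.
#'
#' @param x A [build_detection_matrix()] result whose design has exactly
#'   three polymerases (the Venn grouping is three-way).
#' @return A `consensus_report` list of tibbles: `run_counts`,
#'   `polymerase_venn`, `category_counts`, `consensus_counts`; plus the
#'   underlying `assignments` and `consensus` objects per mode.
#' @export
count_report <- function(x) {
  stopifnot(inherits(x, "detection_matrix"))
  callers <- unique(x$design$caller)
  pols <- unique(x$design$polymerase)
  reps <- sort(unique(x$design$replicate))

  run_counts <- x$design |>
    left_join(
      x$calls |>
        group_by(.data$caller, .data$polymerase, .data$replicate) |>
        summarise(n_total = dplyr::n(), n_passed = sum(.data$passed),
                  .groups = "drop"),
      by = c("caller", "polymerase", "replicate")) |>
    mutate(n_total = as.integer(replace_na(.data$n_total, 0L)),
           n_passed = as.integer(replace_na(.data$n_passed, 0L)))

  modes <- c("all", "passed")
  polymerase_venn <- NULL
  category_counts <- NULL
  consensus_counts <- NULL
  assignments <- list()
  consensus <- list()

  for (mode in modes) {
    calls <- if (mode == "passed") filter(x$calls, .data$passed) else x$calls
    if (length(pols) == 3) {
      pv <- expand_grid(caller = callers, replicate = reps) |>
        pmap(function(caller, replicate) {
          sets <- lapply(pols, function(p) {
            calls$key[calls$caller == caller &
                        calls$polymerase == p &
                        calls$replicate == replicate]
          })
          glance(venn_groups(sets[[1]], sets[[2]], sets[[3]],
                             labels = pols)) |>
            mutate(caller = caller, replicate = replicate,
                   mode = mode, .before = 1)
        }) |>
        list_rbind()
      polymerase_venn <- bind_rows(polymerase_venn, pv)
    }
    asg <- lapply(setNames(callers, callers),
                  function(cl) categorize_all(x, cl, mode = mode))
    assignments[[mode]] <- asg
    category_counts <- bind_rows(
      category_counts,
      list_rbind(lapply(asg, glance)))
    cons <- cross_caller_consensus(asg)
    consensus[[mode]] <- cons
    cc <- tibble(mode = mode,
                 n_consensus = length(cons$consensus))
    if (!is.null(cons$venn)) cc <- bind_cols(cc, glance(cons$venn))
    consensus_counts <- bind_rows(consensus_counts, cc)
  }

  structure(list(run_counts = run_counts,
                 polymerase_venn = polymerase_venn,
                 category_counts = category_counts,
                 consensus_counts = consensus_counts,
                 assignments = assignments,
                 consensus = consensus),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report>\n")
  cat("  run_counts:", nrow(x$run_counts), "runs\n")
  print(x$category_counts[, c("caller", "mode", "n_variants",
                              "n_category_1", "n_category_2",
                              "pct_category_12")])
  invisible(x)
}
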