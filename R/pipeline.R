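#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors the arguments of [run_pipeline()]: a `design`
#' list of runs (each with `caller`, `polymerase`, `replicate`, `vcf`
#' and optionally `dialect`), plus optional `panel`, `depth_tracks`
#' (name: path), `min_depth`, `out_dir` and `seed` entries. Relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A config list suitable for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^/", p), p, file.path(base_dir, p))
  }
  cfg$design <- bind_rows(lapply(cfg$design, as_tibble))
  cfg$design$vcf <- resolve(cfg$design$vcf)
  if (!is.null(cfg$panel)) cfg$panel <- resolve(cfg$panel)
  if (!is.null(cfg$depth_tracks)) {
    cfg$depth_tracks <- lapply(cfg$depth_tracks, resolve)
  }
  cfg
}

#' Run the full consensus pipeline
#'
#' Executes the whole workflow on a set of per-run somatic VCFs: read
#' and normalize each call set, assemble the detection matrix, compute
#' Venn groups, category assignments (in both filter modes), the
#' cross-caller consensus, VAF summaries for consensus variants, and
#' panel coverage metrics when depth tracks are supplied. All report
#' tables are written as TSV (plus a generic-dialect consensus VCF) into
#' `out_dir`; outputs are staged in a temporary directory and moved into
#' place only after every table has been written, so a failing run never
#' leaves partial output. Reruns with identical inputs produce
#' byte-identical files.
#'
#' @param config A list (or [read_pipeline_config()] result) with:
#'   `design` -- tibble with `caller`, `polymerase`, `replicate`, `vcf`
#'   (path) and optional `dialect`; optional `panel` (BED path),
#'   `depth_tracks` (named list of TSV paths), `min_depth` (default 1),
#'   `out_dir` (default `"dualseq_out"`).
#' @return Invisibly, a list with the detection matrix, the
#'   [count_report()], consensus variant table, VAF summaries, coverage
#'   table and output paths.
#' @export
run_pipeline <- function(config) {
  design <- as_tibble(config$design)
  need <- c("caller", "polymerase", "replicate", "vcf")
  if (!all(need %in% names(design))) {
    abort(paste0("config design needs columns: ",
                 paste(need, collapse = ", ")))
  }
  min_depth <- config$min_depth %||% 1
  out_dir <- config$out_dir %||% "dualseq_out"

  # enumerate every missing input before doing any work
  paths <- c(design$vcf, config$panel,
             unlist(config$depth_tracks, use.names = FALSE))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("missing input file(s):\n  ",
                 paste(missing, collapse = "\n  ")))
  }

  calls <- pmap(design, function(caller, polymerase, replicate, vcf, ...) {
    args <- list(...)
    read_vcf(vcf, dialect = args$dialect) |>
      mutate(caller = caller, polymerase = polymerase,
             replicate = as.integer(replicate))
  }) |> list_rbind()

  matrix <- build_detection_matrix(
    calls, design[, c("caller", "polymerase", "replicate")])
  report <- count_report(matrix)

  consensus_all <- report$consensus[["all"]]
  consensus_keys <- consensus_all$consensus
  consensus_tbl <- NULL
  if (length(consensus_keys) > 0) {
    per_caller_cat <- lapply(report$assignments[["all"]], function(a) {
      tibble(key = a$key, category = a$category)
    }) |>
      imap(function(d, nm) rename(d, !!paste0("category_", nm) := "category")) |>
      purrr::reduce(function(x, y) full_join(x, y, by = "key"))
    consensus_tbl <- matrix$calls |>
      filter(.data$key %in% consensus_keys) |>
      distinct(.data$key, .data$chrom, .data$pos, .data$ref, .data$alt) |>
      left_join(vaf_summary(matrix$calls, "overall",
                            variants = consensus_keys), by = "key") |>
      left_join(per_caller_cat, by = "key") |>
      arrange(.data$chrom, .data$pos)
  } else {
    consensus_tbl <- tibble(key = character(), chrom = character(),
                            pos = integer(), ref = character(),
                            alt = character())
  }

  vaf_tbl <- if (length(consensus_keys) > 0) {
    vaf_summary(matrix$calls, "by_caller", variants = consensus_keys)
  } else tibble()

  coverage_tbl <- NULL
  if (!is.null(config$panel) && !is.null(config$depth_tracks)) {
    panel <- read_bed(config$panel)
    coverage_tbl <- imap(config$depth_tracks, function(p, nm) {
      bind_cols(tibble(library = nm),
                coverage_metrics(read_depth_track(p), panel,
                                 min_depth = min_depth))
    }) |> list_rbind()
  }

  # stage outputs, then move into place
  stage <- tempfile("dualseq_stage_")
  dir.create(stage)
  write_out <- function(x, name) {
    readr::write_tsv(x, file.path(stage, name))
  }
  write_out(report$run_counts, "run_counts.tsv")
  write_out(report$category_counts, "category_counts.tsv")
  if (!is.null(report$polymerase_venn)) {
    write_out(report$polymerase_venn, "polymerase_venn.tsv")
  }
  write_out(report$consensus_counts, "consensus_counts.tsv")
  write_out(consensus_tbl, "consensus_variants.tsv")
  {
    cons_calls <- matrix$calls |>
      filter(.data$key %in% consensus_keys) |>
      group_by(.data$chrom, .data$pos, .data$ref, .data$alt, .data$key) |>
      summarise(vaf = base::mean(.data$vaf, na.rm = TRUE),
                depth = round(base::mean(.data$depth, na.rm = TRUE)),
                alt_count = round(base::mean(.data$alt_count, na.rm = TRUE)),
                passed = TRUE, .groups = "drop")
    write_vcf(cons_calls, "generic", file.path(stage, "consensus.vcf"))
  }
  if (nrow(vaf_tbl) > 0) write_out(vaf_tbl, "vaf_by_caller.tsv")
  if (!is.null(coverage_tbl)) write_out(coverage_tbl, "coverage.tsv")
  log_lines <- c(
    paste0("dualseq version: ",
           as.character(utils::packageVersion("dualseq"))),
    paste0("runs: ", nrow(design)),
    paste0("min_depth: ", min_depth),
    "category reading: 'two of three polymerases' treated as >= 2; both filter modes computed")
  writeLines(log_lines, file.path(stage, "run_log.txt"))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage, full.names = TRUE)) {
    file.copy(f, file.path(out_dir, basename(f)), overwrite = TRUE)
  }
  unlink(stage, recursive = TRUE)

  invisible(list(matrix = matrix, report = report,
                 consensus_variants = consensus_tbl,
                 vaf_by_caller = vaf_tbl,
                 coverage = coverage_tbl,
                 out_dir = out_dir,
                 files = list.files(out_dir)))
}
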