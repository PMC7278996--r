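#' VCF dialect descriptors
#'
#' The three somatic callers whose output the pipeline consumes encode
#' allele support differently, so VAF extraction is dialect-specific:
#' \describe{
#'   \item{strelka2}{tumor/normal sample columns; SNV VAF from tier-1
#'     base counts (`AU/CU/GU/TU`), indels from an allele-depth field;}
#'   \item{mutect2}{tumor sample column; VAF from the allele-depth
#'     (`AD`) field;}
#'   \item{lofreq}{no sample columns; VAF from `INFO/AF` with depth from
#'     `INFO/DP` (alternate read count is not recoverable);}
#'   \item{generic}{no sample columns; `INFO` `AF`/`DP`/`AC`.}
#' }
#'
#' @param name One of `"strelka2"`, `"mutect2"`, `"lofreq"`, `"generic"`.
#' @return A `vcf_dialect` object.
#' @export
vcf_dialect <- function(name = c("strelka2", "mutect2", "lofreq", "generic")) {
  name <- match.arg(name)
  structure(list(
    name = name,
    has_sample_columns = name %in% c("strelka2", "mutect2"),
    vaf_source = switch(name,
                        strelka2 = "tier-counts",
                        mutect2 = "allele-depths",
                        lofreq = "info-af",
                        generic = "info-af"),
    fail_label = switch(name,
                        strelka2 = "LowEVS",
                        mutect2 = "weak_evidence",
                        lofreq = "min_af",
                        generic = "FAIL")),
    class = "vcf_dialect")
}

as_dialect <- function(dialect) {
  if (inherits(dialect, "vcf_dialect")) dialect else vcf_dialect(dialect)
}

info_field <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))
  m[, 2]
}

#' Read a somatic VCF into a call table
#'
#' Parses a VCF v4.x file (plain or gzip) in one of the supported caller
#' dialects, splits multi-allelic records into one call per alternate
#' allele, normalizes variant identities, and extracts per-call VAF,
#' depth and alternate read count with the dialect's rule. Records whose
#' support fields cannot be parsed keep `vaf = NA` rather than being
#' dropped; only records with non-nucleotide alleles (symbolic or `N`)
#' are skipped, and their count is recorded in the `n_skipped` attribute.
#'
#' @param path VCF file path.
#' @param dialect A [vcf_dialect()] (or its name). `NULL` auto-detects
#'   from the header `##source=` line.
#' @return A tibble of calls: `chrom`, `pos`, `ref`, `alt`, `key`,
#'   `vaf`, `depth`, `alt_count`, `passed`, `filter`.
#' @export
read_vcf <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  first <- readLines(con, n = 200)
  if (is.null(dialect)) {
    src <- grep("^##source=", first, value = TRUE)
    hit <- c("strelka2", "mutect2", "lofreq", "generic")[
      c(any(grepl("strelka2", src, ignore.case = TRUE)),
        any(grepl("mutect2", src, ignore.case = TRUE)),
        any(grepl("lofreq", src, ignore.case = TRUE)),
        any(grepl("generic", src, ignore.case = TRUE)))]
    if (length(hit) == 0) {
      abort(paste0("cannot auto-detect dialect from header of ", path))
    }
    dialect <- hit[1]
  }
  dialect <- as_dialect(dialect)

  empty <- tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character(),
                  key = character(), vaf = double(), depth = double(),
                  alt_count = double(), passed = logical(),
                  filter = character())
  v <- suppressWarnings(
    try(vcfR::read.vcfR(path, verbose = FALSE), silent = TRUE))
  if (inherits(v, "try-error") || nrow(v@fix) == 0) {
    # header-only file
    return(structure(empty, n_skipped = 0L))
  }
  fix <- as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  names(fix) <- tolower(names(fix))
  required <- c("chrom", "pos", "ref", "alt", "filter")
  miss <- setdiff(required, names(fix))
  if (length(miss) > 0) {
    abort(paste0("malformed VCF ", path, ": missing column(s) ",
                 paste(toupper(miss), collapse = ", ")))
  }
  gt <- if (ncol(v@gt) > 0) as.data.frame(v@gt, stringsAsFactors = FALSE)
        else NULL
  if (dialect$has_sample_columns) {
    if (is.null(gt) || ncol(gt) < 2) {
      abort(paste0("dialect ", dialect$name,
                   " expects sample columns, none in ", path))
    }
    tumor_col <- if ("TUMOR" %in% names(gt)) "TUMOR" else names(gt)[ncol(gt)]
    fix$format <- gt[["FORMAT"]]
    fix$tumor <- gt[[tumor_col]]
  } else {
    fix$format <- NA_character_
    fix$tumor <- NA_character_
  }
  fix$pos <- as.integer(fix$pos)
  fix$row_id <- seq_len(nrow(fix))

  # split multi-allelic records, remembering each allele's index
  calls <- fix |>
    mutate(alt = str_split(.data$alt, fixed(","))) |>
    unnest("alt") |>
    group_by(.data$row_id) |>
    mutate(alt_index = dplyr::row_number()) |>
    ungroup()

  valid <- grepl("^[ACGTacgt]+$", calls$ref) & grepl("^[ACGTacgt]+$", calls$alt)
  n_skipped <- sum(!valid)
  if (n_skipped > 0) {
    inform(paste0("read_vcf: skipped ", n_skipped,
                  " allele(s) with non-ACGT sequence in ", basename(path)))
    calls <- calls[valid, ]
  }
  if (nrow(calls) == 0) return(structure(empty, n_skipped = n_skipped))

  support <- extract_vaf(calls, dialect)
  out <- calls |>
    transmute(chrom = .data$chrom, pos = .data$pos,
              ref = toupper(.data$ref), alt = toupper(.data$alt),
              filter = .data$filter,
              passed = .data$filter %in% c("PASS", ".")) |>
    bind_cols(support) |>
    normalize_variants() |>
    select("chrom", "pos", "ref", "alt", "key", "vaf", "depth",
           "alt_count", "passed", "filter")
  structure(out, n_skipped = n_skipped)
}

#' Extract VAF, depth and alternate read count from VCF record fields
#'
#' Applies the dialect's allele-support rule to one or more records (one
#' alternate allele each). Zero total depth yields a missing VAF, never
#' zero.
#'
#' @param fields A data frame (or list coercible to one) with columns
#'   `ref`, `alt`, `info`, and, for sample-column dialects, `format` and
#'   `tumor` (the colon-separated FORMAT and tumor-sample strings);
#'   optionally `alt_index` (position of this allele in the original ALT
#'   list, default 1).
#' @param dialect A [vcf_dialect()] or its name.
#' @return A tibble with columns `vaf`, `depth`, `alt_count` (NA where
#'   not recoverable).
#' @examples
#' extract_vaf(
#'   data.frame(ref = "C", alt = "T", info = ".",
#'              format = "DP:AU:CU:GU:TU",
#'              tumor = "100:0,0:90,90:0,0:10,10"),
#'   "strelka2")
#' @export
extract_vaf <- function(fields, dialect) {
  dialect <- as_dialect(dialect)
  fields <- as_tibble(as.data.frame(fields, stringsAsFactors = FALSE))
  n <- nrow(fields)
  if (!"alt_index" %in% names(fields)) fields$alt_index <- 1L
  if (!"info" %in% names(fields)) fields$info <- NA_character_
  vaf <- rep(NA_real_, n); depth <- rep(NA_real_, n)
  alt_count <- rep(NA_real_, n)

  if (dialect$vaf_source == "info-af") {
    af <- suppressWarnings(
      vapply(seq_len(n), function(i) {
        vals <- str_split(info_field(fields$info[i], "AF"), fixed(","))[[1]]
        as.numeric(vals[min(fields$alt_index[i], length(vals))])
      }, double(1)))
    dp <- suppressWarnings(as.numeric(info_field(fields$info, "DP")))
    ac <- suppressWarnings(
      vapply(seq_len(n), function(i) {
        vals <- str_split(info_field(fields$info[i], "AC"), fixed(","))[[1]]
        as.numeric(vals[min(fields$alt_index[i], length(vals))])
      }, double(1)))
    vaf <- af; depth <- dp; alt_count <- ac
  } else {
    fmt <- str_split(fields$format, fixed(":"))
    val <- str_split(fields$tumor, fixed(":"))
    get_field <- function(i, key) {
      j <- match(key, fmt[[i]])
      if (is.na(j) || j > length(val[[i]])) NA_character_ else val[[i]][j]
    }
    for (i in seq_len(n)) {
      ref_i <- toupper(fields$ref[i]); alt_i <- toupper(fields$alt[i])
      is_snv <- nchar(ref_i) == 1 && nchar(alt_i) == 1
      if (dialect$name == "strelka2" && is_snv &&
          !is.na(get_field(i, paste0(alt_i, "U")))) {
        tier1 <- vapply(c("A", "C", "G", "T"), function(b) {
          suppressWarnings(as.numeric(
            str_split(get_field(i, paste0(b, "U")), fixed(","))[[1]][1]))
        }, double(1))
        if (!anyNA(tier1)) {
          depth[i] <- sum(tier1)
          alt_count[i] <- tier1[[alt_i]]
          vaf[i] <- if (depth[i] > 0) alt_count[i] / depth[i] else NA_real_
        }
      } else {
        # allele depths (mutect2; strelka2 indel fallback)
        ad <- suppressWarnings(as.numeric(
          str_split(get_field(i, "AD"), fixed(","))[[1]]))
        if (!anyNA(ad) && length(ad) >= fields$alt_index[i] + 1) {
          depth[i] <- sum(ad)
          alt_count[i] <- ad[fields$alt_index[i] + 1]
          vaf[i] <- if (depth[i] > 0) alt_count[i] / depth[i] else NA_real_
        }
      }
    }
  }
  bad_depth <- !is.na(depth) & depth == 0
  vaf[bad_depth] <- NA_real_
  tibble(vaf = vaf, depth = depth, alt_count = alt_count)
}

#' Write calls as a VCF file in a caller dialect
#'
#' Emits a valid VCF v4.2 file whose characteristic per-dialect fields
#' are populated so that [read_vcf()] round-trips keys, pass flags and
#' VAFs. Records are sorted by chromosome then position; chromosome
#' order is taken from `chrom_order` when given, otherwise lexicographic
#' (with a warning when several chromosomes are present).
#'
#' @param calls Call tibble (as from [read_vcf()] or the simulator) with
#'   columns `chrom`, `pos`, `ref`, `alt`, `passed`, and `vaf`, `depth`,
#'   `alt_count` where available. Calls must come from a single caller.
#' @param dialect A [vcf_dialect()] or its name.
#' @param path Output file path.
#' @param chrom_order Optional character vector fixing chromosome order.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, dialect, path, chrom_order = NULL) {
  dialect <- as_dialect(dialect)
  calls <- as_tibble(calls)
  if ("caller" %in% names(calls) &&
      dplyr::n_distinct(calls$caller) > 1) {
    abort("write_vcf: calls must come from a single caller")
  }
  for (col in c("vaf", "depth", "alt_count")) {
    if (!col %in% names(calls)) calls[[col]] <- NA_real_
  }
  chroms <- unique(calls$chrom)
  if (is.null(chrom_order)) {
    if (length(chroms) > 1) {
      warn("write_vcf: no chrom_order given; sorting chromosomes lexicographically")
    }
    chrom_order <- sort(chroms)
  }
  calls <- calls |>
    mutate(.chrom_rank = match(.data$chrom, chrom_order)) |>
    arrange(.data$.chrom_rank, .data$pos, .data$ref, .data$alt)

  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", dialect$name, "-like"),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    paste0("##FILTER=<ID=", dialect$fail_label,
           ",Description=\"Failed caller filter\">"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">")
  if (dialect$name == "generic") {
    header <- c(header,
      "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate read count\">")
  }
  if (dialect$name == "strelka2") {
    header <- c(header,
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=AU,Number=2,Type=Integer,Description=\"A tier1,tier2 counts\">",
      "##FORMAT=<ID=CU,Number=2,Type=Integer,Description=\"C tier1,tier2 counts\">",
      "##FORMAT=<ID=GU,Number=2,Type=Integer,Description=\"G tier1,tier2 counts\">",
      "##FORMAT=<ID=TU,Number=2,Type=Integer,Description=\"T tier1,tier2 counts\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">")
  }
  if (dialect$name == "mutect2") {
    header <- c(header,
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
      "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  }
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (dialect$has_sample_columns) cols <- c(cols, "FORMAT", "NORMAL", "TUMOR")
  header <- c(header, paste(cols, collapse = "\t"))

  n <- nrow(calls)
  body <- character(0)
  if (n > 0) {
    filt <- ifelse(calls$passed, "PASS", dialect$fail_label)
    dp <- ifelse(is.na(calls$depth), ".",
                 format(calls$depth, scientific = FALSE, trim = TRUE))
    ac <- calls$alt_count
    af_str <- ifelse(is.na(calls$vaf), ".", sprintf("%.6f", calls$vaf))
    fixed8 <- function(info) {
      paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
            filt, info, sep = "\t")
    }
    if (dialect$name %in% c("lofreq", "generic")) {
      info <- paste0("DP=", dp, ";AF=", af_str)
      if (dialect$name == "generic") {
        info <- paste0(info, ";AC=", ifelse(is.na(ac), ".",
                       format(ac, scientific = FALSE, trim = TRUE)))
      } else {
        info <- paste0(info, ";SB=0")
      }
      body <- fixed8(info)
    } else {
      info <- "SOMATIC"
      ref_n <- ifelse(is.na(calls$depth) | is.na(ac), NA,
                      pmax(calls$depth - ac, 0))
      ad_str <- ifelse(is.na(ref_n), ".:.",
                       paste0(ref_n, ",", ac))
      if (dialect$name == "strelka2") {
        is_snv <- nchar(calls$ref) == 1 & nchar(calls$alt) == 1
        fmt <- ifelse(is_snv, "DP:AU:CU:GU:TU", "DP:AD")
        tier <- function(base) {
          cnt <- ifelse(is.na(ref_n), NA,
                        ifelse(calls$alt == base, ac,
                               ifelse(calls$ref == base, ref_n, 0)))
          ifelse(is.na(cnt), ".,.", paste0(cnt, ",", cnt))
        }
        tumor <- ifelse(is_snv,
                        paste(dp, tier("A"), tier("C"), tier("G"), tier("T"),
                              sep = ":"),
                        paste(dp, paste0(ifelse(is.na(ref_n), ".",
                                                paste0(ref_n, ",", ac))),
                              sep = ":"))
        norm_tier <- function(base) {
          cnt <- ifelse(is.na(calls$depth), NA,
                        ifelse(calls$ref == base, calls$depth, 0))
          ifelse(is.na(cnt), ".,.", paste0(cnt, ",", cnt))
        }
        normal <- ifelse(is_snv,
                         paste(dp, norm_tier("A"), norm_tier("C"),
                               norm_tier("G"), norm_tier("T"), sep = ":"),
                         paste(dp, ifelse(is.na(calls$depth), ".",
                                          paste0(dp, ",0")), sep = ":"))
        body <- paste(fixed8(info), fmt, normal, tumor, sep = "\t")
      } else { # mutect2
        fmt <- "GT:AD:AF:DP"
        tumor <- paste0("0/1:", ad_str, ":", af_str, ":", dp)
        normal <- paste0("0/0:", ifelse(is.na(calls$depth), ".:.",
                                        paste0(dp, ",0")), ":0.000000:", dp)
        body <- paste(fixed8(info), fmt, normal, tumor, sep = "\t")
      }
    }
  }
  writeLines(c(header, body), path)
  invisible(path)
}
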