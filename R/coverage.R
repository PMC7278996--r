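#' Read a BED file of target regions or read intervals
#'
#' BED input is 0-based half-open; coordinates are kept that way in the
#' returned tibble (`start` 0-based inclusive, `end` exclusive), matching
#' the convention used by [coverage_metrics()] and [on_target_rate()].
#'
#' @param path BED file path (3+ columns, tab-separated, no header).
#' @return A tibble with `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE)
  std <- c("chrom", "start", "end", "name", "score", "strand")
  names(bed)[seq_len(min(ncol(bed), 6))] <- std[seq_len(min(ncol(bed), 6))]
  out <- as_tibble(bed[, intersect(c("chrom", "start", "end", "name"),
                                   names(bed))])
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if (any(out$start >= out$end)) abort("BED intervals must have start < end")
  out
}

#' Write target regions to BED
#'
#' @param regions Tibble with `chrom`, `start` (0-based), `end`, and
#'   optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(regions))
  readr::write_tsv(regions[, cols], path, col_names = FALSE)
  invisible(path)
}

#' Read a per-base depth track
#'
#' Consumes `samtools depth`-style TSV (chrom, 1-based position, depth).
#' Positions absent from the file are taken to have depth 0.
#'
#' @param path TSV path (no header).
#' @return A tibble with `chrom`, `pos`, `depth`.
#' @export
read_depth_track <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "pos", "depth"),
                  col_types = "cii", progress = FALSE)
}

panel_granges <- function(panel, merge = TRUE) {
  gr <- GenomicRanges::GRanges(
    panel$chrom,
    IRanges::IRanges(start = panel$start + 1L, end = panel$end))
  if (merge) GenomicRanges::reduce(gr) else gr
}

#' Capture-panel coverage metrics
#'
#' Computes the panel QC metrics used to compare libraries: mean depth
#' over all target bases (zeros included), the coverage rate (percentage
#' of target bases at or above `min_depth`), and the percentage of
#' target regions that are fully covered and completely uncovered at
#' `min_depth`. Overlapping panel regions are merged before computation.
#'
#' @param track Depth track tibble (`chrom`, `pos` 1-based, `depth`);
#'   positions not listed count as depth 0.
#' @param panel Target regions tibble (`chrom`, `start` 0-based, `end`).
#' @param min_depth Depth threshold defining "covered" (default 1).
#' @return A one-row tibble: `average_depth`, `coverage_rate`,
#'   `pct_regions_full`, `pct_regions_zero`, `n_regions`,
#'   `panel_bases`.
#' @export
coverage_metrics <- function(track, panel, min_depth = 1) {
  if (nrow(panel) == 0) abort("empty panel")
  if (min_depth < 1) abort("`min_depth` must be >= 1")
  dup <- duplicated(track[, c("chrom", "pos")])
  if (any(dup)) abort("duplicate (chrom, pos) rows in depth track")
  gr <- panel_granges(panel)
  widths <- GenomicRanges::width(gr)
  panel_bases <- sum(widths)

  region_depth_sum <- numeric(length(gr))
  region_covered <- numeric(length(gr))
  if (nrow(track) > 0) {
    pos_gr <- GenomicRanges::GRanges(
      track$chrom, IRanges::IRanges(track$pos, track$pos))
    ov <- GenomicRanges::findOverlaps(pos_gr, gr)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    if (length(q) > 0) {
      d <- track$depth[q]
      sums <- tapply(d, s, sum)
      region_depth_sum[as.integer(names(sums))] <- as.numeric(sums)
      cov <- tapply(d >= min_depth, s, sum)
      region_covered[as.integer(names(cov))] <- as.numeric(cov)
    }
  }
  tibble(
    average_depth = sum(region_depth_sum) / panel_bases,
    coverage_rate = 100 * sum(region_covered) / panel_bases,
    pct_regions_full = 100 * mean(region_covered == widths),
    pct_regions_zero = 100 * mean(region_covered == 0),
    n_regions = length(gr),
    panel_bases = panel_bases,
    min_depth = min_depth)
}

#' On-target rate of mapped reads
#'
#' Percentage of mapped reads overlapping at least one panel base.
#'
#' @param reads Read intervals tibble (`chrom`, `start` 0-based
#'   half-open, `end`).
#' @param panel Target regions tibble (same convention).
#' @return Percentage in `[0, 100]`, or `NA` for zero reads.
#' @export
on_target_rate <- function(reads, panel) {
  if (nrow(reads) == 0) {
    inform("on_target_rate: no reads; rate undefined")
    return(NA_real_)
  }
  reads_gr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(start = reads$start + 1L, end = reads$end))
  hits <- GenomicRanges::countOverlaps(reads_gr, panel_granges(panel)) > 0
  100 * sum(hits) / nrow(reads)
}

#' Subsample mapped reads
#'
#' Uniform sample of `n` read intervals without replacement,
#' reproducible for a given `seed` (the emulation, at the aligned-read
#' level, of FASTQ downsampling with tools like Seqtk).
#'
#' @param reads Read intervals tibble.
#' @param n Number of reads to keep (`0 <= n <= nrow(reads)`).
#' @param seed Integer seed.
#' @return A tibble of `n` rows (original order preserved).
#' @export
subsample_reads <- function(reads, n, seed) {
  total <- nrow(reads)
  if (n > total) {
    abort(paste0("cannot sample ", n, " reads from ", total))
  }
  if (n < 0) abort("`n` must be >= 0")
  idx <- withr::with_seed(seed, sample.int(total, n))
  reads[sort(idx), ]
}

#' Depth track implied by a set of read intervals
#'
#' Per-base depth over the panel from read alignments (0-based
#' half-open); bases with zero depth are omitted, consistent with
#' [read_depth_track()]'s convention.
#'
#' @param reads Read intervals tibble.
#' @param panel Target regions tibble.
#' @return A depth-track tibble (`chrom`, `pos`, `depth`).
#' @export
depth_from_reads <- function(reads, panel) {
  gr <- panel_granges(panel)
  if (nrow(reads) == 0) {
    return(tibble(chrom = character(), pos = integer(), depth = integer()))
  }
  reads_gr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(start = reads$start + 1L, end = reads$end))
  cvg <- GenomicRanges::coverage(reads_gr)
  out <- vector("list", length(gr))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr); ends <- GenomicRanges::end(gr)
  for (i in seq_along(gr)) {
    ch <- chroms[i]
    pos <- starts[i]:ends[i]
    if (!ch %in% names(cvg)) next
    rle <- cvg[[ch]]
    d <- integer(length(pos))
    in_range <- pos <= length(rle)
    if (any(in_range)) {
      d[in_range] <- as.integer(rle[pos[in_range]])
    }
    keep <- d > 0
    if (any(keep)) {
      out[[i]] <- tibble(chrom = ch, pos = pos[keep], depth = d[keep])
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(chrom = character(), pos = integer(), depth = integer())
  }
  res
}

#' Saturation of coverage and detection metrics under downsampling
#'
#' Recomputes metrics at a ladder of read counts. For read intervals
#' (data-frame method) the reads are permuted once under `seed` and each
#' `n` takes the first `n` of the permutation, so samples are nested and
#' metrics vary monotonically along the ladder. For a simulated
#' experiment the per-call read support is thinned binomially by
#' `n / reads_total` and detection plus category classification is
#' re-evaluated, giving the detected-variant saturation curve.
#'
#' @param x Read intervals tibble, or a [simulate_experiment()] result.
#' @param n_list Strictly increasing integer vector of read counts.
#' @param seed Integer seed.
#' @param min_depth Coverage threshold (read-interval method).
#' @param panel Target regions (read-interval method).
#' @param ... Passed between methods.
#' @return A `saturation_curve` tibble, one row per `n` (per caller for
#'   the experiment method).
#' @export
saturation_curve <- function(x, n_list, seed, ...) {
  UseMethod("saturation_curve")
}

#' @rdname saturation_curve
#' @export
saturation_curve.data.frame <- function(x, n_list, seed, panel,
                                        min_depth = 1, ...) {
  check_n_list(n_list, nrow(x))
  perm <- withr::with_seed(seed, sample.int(nrow(x)))
  rows <- lapply(n_list, function(n) {
    sub <- x[sort(perm[seq_len(n)]), , drop = FALSE]
    track <- depth_from_reads(sub, panel)
    bind_cols(tibble(n_reads = n),
              coverage_metrics(track, panel, min_depth = min_depth),
              tibble(on_target_rate = on_target_rate(sub, panel)))
  })
  out <- bind_rows(rows)
  structure(out, class = c("saturation_curve", class(out)))
}

check_n_list <- function(n_list, total = Inf) {
  if (length(n_list) == 0 || any(diff(n_list) <= 0)) {
    abort("`n_list` must be strictly increasing")
  }
  if (max(n_list) > total) {
    abort(paste0("largest n (", max(n_list), ") exceeds total reads (",
                 total, ")"))
  }
  invisible(n_list)
}
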