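# per-base brute-force recomputation of every coverage metric
brute_coverage <- function(track, panel, min_depth = 1) {
  depth_at <- function(ch, p) {
    hit <- track$depth[track$chrom == ch & track$pos == p]
    if (length(hit) == 0) 0L else hit[1]
  }
  per_region <- lapply(seq_len(nrow(panel)), function(i) {
    pos <- (panel$start[i] + 1):panel$end[i]
    d <- vapply(pos, function(p) depth_at(panel$chrom[i], p), integer(1))
    list(sum = sum(d), covered = sum(d >= min_depth), width = length(pos))
  })
  sums <- vapply(per_region, `[[`, numeric(1), "sum")
  cov <- vapply(per_region, `[[`, numeric(1), "covered")
  w <- vapply(per_region, `[[`, numeric(1), "width")
  list(average_depth = sum(sums) / sum(w),
       coverage_rate = 100 * sum(cov) / sum(w),
       pct_regions_full = 100 * mean(cov == w),
       pct_regions_zero = 100 * mean(cov == 0))
}

random_panel <- function(n_regions, chrom = "chr1", width_range = c(5, 30)) {
  width <- sample(width_range[1]:width_range[2], n_regions, replace = TRUE)
  gap <- sample(5:20, n_regions, replace = TRUE)
  start <- cumsum(gap) + cumsum(dplyr::lag(width, default = 0))
  tibble::tibble(chrom = chrom, start = start, end = start + width)
}

test_that("coverage metrics on simple panels are exact", {
  panel <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
  track <- tibble::tibble(chrom = "chr1", pos = 1:10, depth = 5L)
  m <- coverage_metrics(track, panel)
  expect_equal(m$average_depth, 5)
  expect_equal(m$coverage_rate, 100)
  expect_equal(m$pct_regions_full, 100)
  expect_equal(m$pct_regions_zero, 0)

  # one full region at depth 10, one empty region
  panel2 <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                           end = c(10L, 110L))
  track2 <- tibble::tibble(chrom = "chr1", pos = 1:10, depth = 10L)
  m2 <- coverage_metrics(track2, panel2)
  expect_equal(m2$average_depth, 5)
  expect_equal(m2$coverage_rate, 50)
  expect_equal(m2$pct_regions_full, 50)
  expect_equal(m2$pct_regions_zero, 50)

  expect_error(coverage_metrics(track, panel[0, ]), "empty panel")
})

test_that("coverage metrics equal a per-base brute-force recomputation", {
  withr::with_seed(17, {
    for (i in 1:20) {
      panel <- random_panel(sample(3:8, 1))
      all_pos <- unlist(lapply(seq_len(nrow(panel)), function(j)
        (panel$start[j] + 1):panel$end[j]))
      keep <- sample(all_pos, round(length(all_pos) * runif(1, 0.2, 0.9)))
      track <- tibble::tibble(chrom = "chr1", pos = sort(keep),
                              depth = sample(0:50, length(keep),
                                             replace = TRUE))
      md <- sample(1:10, 1)
      got <- coverage_metrics(track, panel, min_depth = md)
      exp <- brute_coverage(track, panel, min_depth = md)
      expect_equal(got$average_depth, exp$average_depth)
      expect_equal(got$coverage_rate, exp$coverage_rate)
      expect_equal(got$pct_regions_full, exp$pct_regions_full)
      expect_equal(got$pct_regions_zero, exp$pct_regions_zero)
    }
  })
})

test_that("coverage rate is non-increasing in min_depth and merge-invariant", {
  withr::with_seed(29, {
    panel <- random_panel(6)
    all_pos <- unlist(lapply(seq_len(nrow(panel)), function(j)
      (panel$start[j] + 1):panel$end[j]))
    track <- tibble::tibble(chrom = "chr1", pos = all_pos,
                            depth = sample(0:20, length(all_pos),
                                           replace = TRUE))
    rates <- vapply(1:15, function(md)
      coverage_metrics(track, panel, min_depth = md)$coverage_rate,
      numeric(1))
    expect_true(all(diff(rates) <= 0))
    # splitting a region in two then relying on internal merge only
    # changes region counts, not base-level metrics
    split_panel <- panel
    split_panel$end[1] <- panel$start[1] + 2
    extra <- tibble::tibble(chrom = "chr1", start = panel$start[1] + 2,
                            end = panel$end[1])
    merged <- coverage_metrics(track, rbind(split_panel, extra))
    expect_equal(merged$average_depth,
                 coverage_metrics(track, panel)$average_depth)
    expect_equal(merged$coverage_rate,
                 coverage_metrics(track, panel)$coverage_rate)
  })
})

test_that("on-target rate matches a quadratic brute-force overlap check", {
  panel <- tibble::tibble(chrom = "chr1", start = c(0L, 50L),
                          end = c(10L, 60L))
  reads <- tibble::tibble(chrom = "chr1",
                          start = c(2L, 20L, 30L, 55L),
                          end = c(8L, 25L, 40L, 65L))
  expect_equal(on_target_rate(reads, panel), 50)
  all_in <- tibble::tibble(chrom = "chr1", start = c(1L, 3L), end = c(5L, 9L))
  expect_equal(on_target_rate(all_in, panel), 100)
  expect_message(r0 <- on_target_rate(all_in[0, ], panel), "no reads")
  expect_true(is.na(r0))

  withr::with_seed(43, {
    for (i in 1:10) {
      pan <- random_panel(4)
      rd <- tibble::tibble(chrom = "chr1",
                           start = sample(0:300, 40, replace = TRUE))
      rd$end <- rd$start + sample(5:20, 40, replace = TRUE)
      brute <- mean(vapply(seq_len(nrow(rd)), function(i) {
        any(rd$start[i] < pan$end & rd$end[i] > pan$start)
      }, logical(1))) * 100
      expect_equal(on_target_rate(rd, pan), brute)
    }
  })
})

test_that("read subsampling is deterministic, bounded, and thins depth proportionally", {
  withr::with_seed(51, {
    panel <- tibble::tibble(chrom = "chr1", start = 0L, end = 200L)
    reads <- tibble::tibble(chrom = "chr1",
                            start = sample(0:150, 400, replace = TRUE))
    reads$end <- reads$start + 50L
  })
  expect_identical(subsample_reads(reads, 100, seed = 9),
                   subsample_reads(reads, 100, seed = 9))
  expect_equal(nrow(subsample_reads(reads, 0, seed = 9)), 0)
  expect_identical(sort(subsample_reads(reads, nrow(reads), 1)$start),
                   sort(reads$start))
  expect_error(subsample_reads(reads, nrow(reads) + 1, 1), "400")

  # binomial-thinning expectation: mean subsampled depth ~ (n/total) x full
  full_depth <- coverage_metrics(depth_from_reads(reads, panel),
                                 panel)$average_depth
  n <- 100
  obs <- vapply(1:50, function(s) {
    coverage_metrics(depth_from_reads(subsample_reads(reads, n, seed = s),
                                      panel), panel)$average_depth
  }, numeric(1))
  expected <- full_depth * n / nrow(reads)
  se <- stats::sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected), 3 * se + 1e-9)
})

test_that("saturation curves are monotone for nested read samples", {
  withr::with_seed(61, {
    panel <- random_panel(5, width_range = c(20, 40))
    reads <- tibble::tibble(
      chrom = "chr1",
      start = sample(0:max(panel$end), 500, replace = TRUE))
    reads$end <- reads$start + 30L
  })
  sat <- saturation_curve(reads, c(50, 150, 300, 500), seed = 3,
                          panel = panel)
  expect_equal(nrow(sat), 4)
  expect_true(all(diff(sat$average_depth) > 0))
  expect_true(all(diff(sat$coverage_rate) >= 0))
  # n = total reproduces the full metrics
  full <- coverage_metrics(depth_from_reads(reads, panel), panel)
  expect_equal(sat$average_depth[4], full$average_depth)
  expect_error(saturation_curve(reads, c(100, 100), 1, panel = panel),
               "strictly increasing")
})

test_that("coverage_rate(min_depth = 1) is non-decreasing for nested samples across datasets", {
  withr::with_seed(71, {
    seeds <- sample.int(1000, 20)
  })
  for (s in seeds) {
    withr::with_seed(s, {
      panel <- random_panel(4, width_range = c(10, 25))
      reads <- tibble::tibble(
        chrom = "chr1",
        start = sample(0:max(panel$end), 120, replace = TRUE))
      reads$end <- reads$start + sample(10:30, 120, replace = TRUE)
    })
    sat <- saturation_curve(reads, c(20, 60, 120), seed = s, panel = panel)
    expect_true(all(diff(sat$coverage_rate) >= 0))
  }
})
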