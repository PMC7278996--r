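test_that("venn regions handle disjoint and identical sets", {
  v <- venn_groups("x", "y", "z", labels = c("A", "B", "C"))
  expect_equal(v$region[match(c("x", "y", "z"), v$key)], c(1L, 2L, 3L))
  s <- c("a", "b", "c")
  v2 <- venn_groups(s, s, s, labels = c("A", "B", "C"))
  expect_true(all(v2$region == 7L))
  expect_error(venn_groups("x", "y", "z", labels = c("A", "A", "B")),
               "distinct")
})

test_that("venn partition agrees with a 3-bit membership oracle and is a partition", {
  withr::with_seed(99, {
    universe <- sprintf("k%03d", 1:100)
    for (i in 1:50) {
      a <- sample(universe, 50); b <- sample(universe, 50)
      c_ <- sample(universe, 50)
      v <- venn_groups(a, b, c_, labels = c("P1", "P2", "P3"))
      # disjoint and exhaustive
      expect_false(anyDuplicated(v$key) > 0)
      expect_setequal(v$key, union(union(a, b), c_))
      # brute-force membership per key
      oracle_region <- vapply(v$key, function(k) {
        bits <- c(k %in% a, k %in% b, k %in% c_)
        code <- sum(bits * c(1, 2, 4))
        c(`1` = 1L, `2` = 2L, `4` = 3L, `3` = 4L,
          `5` = 5L, `6` = 6L, `7` = 7L)[[as.character(code)]]
      }, integer(1))
      expect_equal(v$region, unname(oracle_region[v$key]))
    }
  })
})

test_that("category definitions classify the canonical support tuples", {
  # frozen expectations derived from the category definitions with the
  # >= reading of 'two of three polymerases'
  expect_equal(classify_category(c(3, 3), 3), 1L)
  expect_equal(classify_category(c(2, 2), 3), 2L)
  expect_equal(classify_category(c(3, 2), 3), 2L)
  expect_equal(classify_category(c(2, 0), 3), 3L)
  expect_equal(classify_category(c(1, 1), 3), 4L)
  expect_equal(classify_category(c(1, 0), 3), 4L)
  expect_error(classify_category(c(0, 0), 3), "all-zero")
  expect_error(classify_category(c(4, 0), 3), "must lie in")
})

test_that("the four categories partition every nonzero support tuple (P=3, R=2)", {
  # hand-derived expected category for all 15 nonzero tuples
  expected <- c(
    "0,1" = 4, "0,2" = 3, "0,3" = 3,
    "1,0" = 4, "1,1" = 4, "1,2" = 3, "1,3" = 3,
    "2,0" = 3, "2,1" = 3, "2,2" = 2, "2,3" = 2,
    "3,0" = 3, "3,1" = 3, "3,2" = 2, "3,3" = 1)
  tuples <- tidyr::expand_grid(c1 = 0:3, c2 = 0:3) |>
    dplyr::filter(c1 + c2 > 0)
  got <- classify_category(as.matrix(tuples), 3)
  expect_equal(got,
               unname(expected[paste(tuples$c1, tuples$c2, sep = ",")]),
               ignore_attr = TRUE)
  # each tuple gets exactly one category: predicates partition
  expect_true(all(got %in% 1:4))

  # 63 library-set patterns over 3 polymerases x 2 replicates: support
  # tallied by brute force, classification must match the tuple table
  libs <- tidyr::expand_grid(pol = 1:3, rep = 1:2)
  for (mask in 1:63) {
    sel <- libs[as.logical(bitwAnd(mask, 2^(0:5))), ]
    sup <- c(length(unique(sel$pol[sel$rep == 1])),
             length(unique(sel$pol[sel$rep == 2])))
    expect_equal(classify_category(sup, 3),
                 unname(expected[paste(sup[1], sup[2], sep = ",")]),
                 ignore_attr = TRUE)
  }
})

test_that("category predicates partition tuples for larger designs too", {
  for (P in 2:4) {
    for (R in 2:3) {
      tuples <- as.matrix(do.call(tidyr::expand_grid,
                                  setNames(rep(list(0:P), R),
                                           paste0("c", 1:R))))
      tuples <- tuples[rowSums(tuples) > 0, , drop = FALSE]
      got <- classify_category(tuples, P)
      expect_true(all(got %in% 1:4))
      # spot-check the extremes
      expect_equal(classify_category(rep(P, R), P), 1L)
      expect_equal(classify_category(rep(1, R), P), 4L)
    }
  }
})

test_that("adding a detection never degrades a variant's category", {
  withr::with_seed(123, {
    libs <- tidyr::expand_grid(pol = 1:3, rep = 1:2)
    support_of <- function(rows) {
      vapply(1:2, function(r)
        length(unique(libs$pol[rows][libs$rep[rows] == r])), integer(1))
    }
    for (i in 1:200) {
      n0 <- sample.int(5, 1)
      idx <- sample.int(6, n0)
      cat0 <- classify_category(support_of(idx), 3)
      extra <- sample(setdiff(1:6, idx), 1)
      cat1 <- classify_category(support_of(c(idx, extra)), 3)
      expect_lte(cat1, cat0)
    }
  })
})

test_that("categorize_all respects filter mode and reports percentages", {
  design <- default_design()
  # one variant detected (unfiltered) in all 6 libraries of each caller,
  # but passing filters in only one
  calls <- design |>
    dplyr::mutate(chrom = "chr1", pos = 10L, ref = "C", alt = "T",
                  passed = polymerase == "KAPA" & replicate == 1L)
  m <- build_detection_matrix(calls, design)
  a_all <- categorize_all(m, "strelka2", mode = "all")
  a_pass <- categorize_all(m, "strelka2", mode = "passed")
  expect_equal(a_all$category, 1L)
  expect_equal(a_pass$category, 4L)
  g <- glance(a_all)
  expect_equal(g$pct_category_1, 100)
  expect_equal(g$n_variants, 1)
})

test_that("cross-caller consensus intersects category-1/2 sets", {
  design <- default_design()
  # all callers see the same fully reproducible variant; strelka2 also
  # sees a private one
  base_calls <- design |>
    dplyr::mutate(chrom = "chr1", pos = 10L, ref = "C", alt = "T",
                  passed = TRUE)
  extra <- base_calls[base_calls$caller == "strelka2", ] |>
    dplyr::mutate(pos = 99L)
  m <- build_detection_matrix(rbind(base_calls, extra), design)
  asg <- lapply(setNames(unique(design$caller), unique(design$caller)),
                function(cl) categorize_all(m, cl))
  cons <- cross_caller_consensus(asg)
  expect_equal(cons$consensus, "chr1:10:C:T")
  expect_equal(sum(cons$venn$region == 7), 1)
  expect_equal(sum(cons$venn$region == 1), 1) # strelka2-private
  expect_warning(cross_caller_consensus(asg["strelka2"]), "single caller")
})

test_that("count_report counts match an independent recount of raw calls", {
  design <- default_design()
  calls <- random_calls(180, design, seed = 57)
  m <- build_detection_matrix(calls, design)
  rep_tbl <- count_report(m)
  # per-run totals against brute-force recount
  for (i in seq_len(nrow(design))) {
    sub <- calls[calls$caller == design$caller[i] &
                   calls$polymerase == design$polymerase[i] &
                   calls$replicate == design$replicate[i], ]
    row <- rep_tbl$run_counts[
      rep_tbl$run_counts$caller == design$caller[i] &
        rep_tbl$run_counts$polymerase == design$polymerase[i] &
        rep_tbl$run_counts$replicate == design$replicate[i], ]
    expect_equal(row$n_total, nrow(sub))
    expect_equal(row$n_passed, sum(sub$passed))
  }
  # venn region sizes sum to the per-(caller, replicate) variant union
  pv <- rep_tbl$polymerase_venn[rep_tbl$polymerase_venn$mode == "all", ]
  for (i in seq_len(nrow(pv))) {
    sub <- calls[calls$caller == pv$caller[i] &
                   calls$replicate == pv$replicate[i], ]
    expect_equal(pv$n_total[i],
                 dplyr::n_distinct(paste(sub$pos, sub$ref, sub$alt)))
  }
  # empty matrix -> all-zero report
  m0 <- build_detection_matrix(calls[0, ], design)
  rep0 <- count_report(m0)
  expect_true(all(rep0$run_counts$n_total == 0))
  expect_equal(rep0$consensus_counts$n_consensus, c(0L, 0L))
})
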