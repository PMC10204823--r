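# Turnover classification, site overlap, goodness-of-fit and tracking.

turnover_fixture <- function(start_counts, end_counts) {
  m <- make_table(rbind(start_counts, end_counts), samples = c("s_start", "s_end"))
  meta <- make_meta(c("s_start", "s_end"), "P1", "LRT", c("StartAZT", "EndAZT"))
  list(counts = m, meta = meta)
}

test_that("classify_turnover performs the retained/cleared/acquired set algebra", {
  # start {a,b,c}, end {b,c,d}
  fx <- turnover_fixture(c(2L, 3L, 1L, 0L), c(0L, 5L, 2L, 4L))
  res <- classify_turnover(fx$counts, fx$meta, "P1", "LRT")
  expect_setequal(res$retained, c("ASV_2", "ASV_3"))
  expect_identical(res$cleared, "ASV_1")
  expect_identical(res$acquired, "ASV_4")
  # identical samples: nothing cleared or acquired
  fx2 <- turnover_fixture(c(2L, 3L, 1L, 1L), c(2L, 3L, 1L, 1L))
  res2 <- classify_turnover(fx2$counts, fx2$meta, "P1", "LRT")
  expect_length(res2$cleared, 0)
  expect_length(res2$acquired, 0)
  # missing pair: skipped with a log record, not an error
  expect_message(
    out <- classify_turnover(fx$counts, fx$meta, "P1", "URT"),
    "skipped")
  expect_null(out)
})

test_that("classify_turnover equals a brute-force membership scan on random pairs", {
  set.seed(55)
  for (rep in 1:50) {
    start <- rpois(20, 1); end <- rpois(20, 1)
    if (sum(start) == 0) start[1] <- 1
    if (sum(end) == 0) end[2] <- 1
    fx <- turnover_fixture(as.integer(start), as.integer(end))
    res <- classify_turnover(fx$counts, fx$meta, "P1", "LRT")
    asvs <- colnames(fx$counts)
    brute <- list(retained = asvs[start > 0 & end > 0],
                  cleared = asvs[start > 0 & end == 0],
                  acquired = asvs[start == 0 & end > 0])
    expect_setequal(res$retained, brute$retained)
    expect_setequal(res$cleared, brute$cleared)
    expect_setequal(res$acquired, brute$acquired)
    # partition identities
    expect_setequal(union(res$retained, res$cleared), asvs[start > 0])
    expect_setequal(union(res$retained, res$acquired), asvs[end > 0])
    expect_length(intersect(res$cleared, res$acquired), 0)
  }
})

test_that("site_overlap assigns disjoint categories whose proportions sum to 1", {
  m <- make_table(rbind(c(1L, 1L, 0L), c(0L, 2L, 3L)), samples = c("l1", "u1"))
  meta <- make_meta(c("l1", "u1"), c("P1", "P1"), c("LRT", "URT"), "StartAZT")
  ov <- site_overlap(m, meta, "StartAZT")
  expect_equal(unname(ov$counts), c(1L, 1L, 1L))
  expect_equal(sum(ov$proportions), 1, tolerance = 1e-12)
  # single shared ASV
  m2 <- make_table(matrix(c(4L, 2L), 2, 1), samples = c("l1", "u1"))
  ov2 <- site_overlap(m2, meta, "StartAZT")
  expect_equal(unname(ov2$counts), c(0L, 0L, 1L))
  # disjoint communities
  m3 <- make_table(rbind(c(1L, 0L), c(0L, 1L)), samples = c("l1", "u1"))
  ov3 <- site_overlap(m3, meta, "StartAZT")
  expect_equal(unname(ov3$counts["both"]), 0L)
  expect_error(site_overlap(m, meta[1, ], "StartAZT"), "both sites")
})

test_that("site_overlap equals brute-force category assignment on random cohorts", {
  set.seed(66)
  for (rep in 1:30) {
    n_l <- sample(1:3, 1); n_u <- sample(1:3, 1)
    ids <- c(paste0("l", 1:n_l), paste0("u", 1:n_u))
    m <- make_table(matrix(rpois((n_l + n_u) * 10, 0.7), n_l + n_u, 10),
                    samples = ids)
    m[rowSums(m) == 0, 1] <- 1L
    meta <- make_meta(ids, paste0("P", seq_along(ids)),
                      rep(c("LRT", "URT"), c(n_l, n_u)), "EndAZT")
    ov <- site_overlap(m, meta, "EndAZT")
    in_l <- colSums(m[1:n_l, , drop = FALSE]) > 0
    in_u <- colSums(m[(n_l + 1):(n_l + n_u), , drop = FALSE]) > 0
    expect_equal(unname(ov$counts),
                 c(sum(in_l & !in_u), sum(!in_l & in_u), sum(in_l & in_u)))
    expect_equal(sum(ov$counts), sum(in_l | in_u))
  }
})

test_that("chi-squared goodness of fit matches hand evaluation", {
  perfect <- chisq_gof(c(10, 10, 10))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)
  skewed <- chisq_gof(c(50, 25, 25))
  expect_equal(skewed$statistic, 12.5, tolerance = 1e-12)
  expect_equal(skewed$df, 2)
  extreme <- chisq_gof(c(0, 0, 30))
  expect_equal(extreme$statistic, 60, tolerance = 1e-12)
  expect_lt(extreme$p_value, 0.001)
  expect_error(chisq_gof(c(0, 0)), "zero total")
  # custom expected proportions
  custom <- chisq_gof(c(30, 10), expected = c(3, 1))
  expect_equal(custom$statistic, 0)
})

test_that("tracked abundance respects the definitional zeros and completeness", {
  fx <- turnover_fixture(c(2L, 3L, 1L, 0L), c(0L, 5L, 2L, 4L))
  res <- classify_turnover(fx$counts, fx$meta, "P1", "LRT")
  tr <- tracked_relative_abundance(fx$counts, fx$meta, res$cleared, "LRT")
  # cleared set has zero abundance at the window-end sample by construction
  expect_equal(tr$samples$value[tr$samples$sample_id == "s_end"], 0)
  # the full ASV set accounts for all reads
  tr_all <- tracked_relative_abundance(fx$counts, fx$meta, colnames(fx$counts), "LRT")
  expect_true(all(tr_all$samples$value == 1))
  # empty set: all-zero series, not an error
  tr0 <- tracked_relative_abundance(fx$counts, fx$meta, character(0), "LRT")
  expect_true(all(tr0$samples$value == 0))
  # hand-computed medians on a 3-sample fixture
  m <- make_table(rbind(c(5L, 5L), c(2L, 8L), c(0L, 10L)),
                  samples = c("a", "b", "c"))
  meta <- make_meta(c("a", "b", "c"), c("P1", "P2", "P3"), "LRT", "StartAZT")
  tr2 <- tracked_relative_abundance(m, meta, "ASV_1", "LRT")
  expect_equal(sort(tr2$samples$value), c(0, 0.2, 0.5))
  expect_equal(tr2$summary$median[tr2$summary$phase == "StartAZT"], 0.2)
})

test_that("per-patient turnover tracking hits its construction zeros", {
  coh <- small_cohort()
  rar <- suppressMessages(rarefy(coh$counts, 800, seed = 4))
  meta <- coh$meta[coh$meta$sample_id %in% rownames(rar), ]
  res <- suppressMessages(turnover_by_patient(rar, meta, "LRT"))
  tt <- tracked_turnover_abundance(rar, meta, res, "cleared", "LRT")
  end_vals <- tt$samples$value[tt$samples$phase == "EndAZT"]
  expect_true(all(end_vals == 0))
  ta <- tracked_turnover_abundance(rar, meta, res, "acquired", "LRT")
  start_vals <- ta$samples$value[ta$samples$phase == "StartAZT"]
  expect_true(all(start_vals == 0))
})

test_that("turnover balance test flags a planted acquisition excess", {
  mk <- function(acquired_extra) {
    lapply(1:6, function(i) {
      structure(list(patient_id = paste0("P", i), site = "LRT",
                     window = c(start = "StartAZT", end = "EndAZT"),
                     retained = paste0("r", 1:10),
                     cleared = paste0("c", seq_len(5)),
                     acquired = paste0("a", seq_len(5 + acquired_extra))),
                class = "aztair_turnover")
    })
  }
  res <- turnover_balance_test(mk(10), "acquired_vs_cleared")
  expect_lt(res$test$p_value, 0.05)
  expect_equal(res$counts$acquired - res$counts$cleared, rep(10, 6))
  # acquired == cleared everywhere: no informative pairs
  expect_error(turnover_balance_test(mk(0), "acquired_vs_cleared"),
               "no informative pairs")
})
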