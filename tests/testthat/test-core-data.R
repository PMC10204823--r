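# Feature table / metadata / tree I-O, rarefaction, genus collapse and
# core-community summaries.

test_that("feature table TSV round-trips losslessly and reads back counts", {
  m <- make_table(rbind(c(3L, 0L), c(1L, 5L)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(m, path)
  back <- read_feature_table(path)
  expect_identical(unname(back), unname(m))
  expect_identical(rowSums(back), c(S1 = 3, S2 = 6))
  expect_identical(dimnames(back), dimnames(m))
})

test_that("invalid feature tables are rejected with the offending cell named", {
  m <- make_table(rbind(c(3L, 0L), c(1L, 5L)))
  bad <- m; storage.mode(bad) <- "double"; bad[2, 1] <- -1
  expect_error(validate_feature_table(bad), "S2.*ASV_1")
  bad2 <- m; rownames(bad2) <- c("S1", "S1")
  expect_error(validate_feature_table(bad2), "duplicate sample")
  bad3 <- m; colnames(bad3) <- c("A", "A")
  expect_error(validate_feature_table(bad3), "duplicate ASV")
  frac <- m; storage.mode(frac) <- "double"; frac[1, 1] <- 1.5
  expect_error(validate_feature_table(frac), "integer")
})

test_that("metadata validation enforces the closed site/phase vocabularies", {
  meta <- make_meta("S1", "P1", "LRT", "StartAZT")
  expect_silent(validate_metadata(meta))
  expect_error(validate_metadata(transform(meta, site = "BAL")), "BAL")
  expect_error(validate_metadata(transform(meta, phase = "Week3")), "Week3")
  dup <- rbind(meta, meta)
  expect_error(validate_metadata(dup), "duplicate sample_id")
  two <- make_meta(c("S1", "S2"), "P1", "LRT", c("StartAZT", "StartAZT"))
  two$sample_id <- c("S1", "S2")
  expect_error(validate_metadata(two), "more than one sample")
})

test_that("newick reading validates rootedness, lengths and leaf coverage", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tree <- read_tree(path)
  expect_length(tree$tip.label, 3)
  expect_equal(sum(tree$edge.length), 5)
  writeLines("(A:1,B:1", path)
  expect_error(read_tree(path), "parse error")
  writeLines("(((A:1,B:1):1,C:2):1,D:1);", path)
  expect_warning(read_tree(path, asv_ids = c("A", "B", "C")), "unused")
  expect_error(read_tree(path, asv_ids = c("A", "B", "C"), strict = TRUE))
  writeLines("((A:1,B:1):1,C:2);", path)
  expect_error(read_tree(path, asv_ids = c("A", "B", "C", "Z")), "Z")
})

test_that("rarefaction conserves counts, equalizes depth and drops shallow samples", {
  set.seed(1)
  m <- make_table(rbind(c(8L, 2L), c(5000L, 5055L), c(9000L, 0L)))
  expect_message(out <- rarefy(m, 10055, seed = 3), "dropped")
  expect_identical(rownames(out), "S2")
  expect_equal(unname(rowSums(out)), 10055)
  expect_identical(attr(out, "dropped_samples"), c("S1", "S3"))
  # exact-depth sample passes through unchanged
  exact <- suppressMessages(rarefy(m[2, , drop = FALSE], 10055, seed = 1))
  expect_identical(unname(exact[1, ]), unname(m[2, ]))
  # subsample: row sum hits depth, each count bounded by the original
  sub <- rarefy(m[1, , drop = FALSE], 5, seed = 9)
  expect_equal(unname(rowSums(sub)), 5)
  expect_true(all(sub <= m[1, ]))
  # determinism under a fixed seed
  expect_identical(rarefy(m[1, , drop = FALSE], 5, seed = 9), sub)
  expect_error(rarefy(m, 0), "positive integer")
})

test_that("genus collapse is additive and conserves per-sample totals", {
  m <- make_table(rbind(c(3L, 4L, 2L), c(1L, 0L, 7L)))
  tax <- c(ASV_1 = "G1", ASV_2 = "G1", ASV_3 = "G2")
  g <- collapse_to_genus(m, tax)
  expect_identical(g[, "G1"], c(S1 = 7L, S2 = 1L))
  expect_identical(rowSums(g), rowSums(m))
  # unmapped ASVs pool under the sentinel, still conserving totals
  g2 <- collapse_to_genus(m, tax[1:2])
  expect_true("Unclassified" %in% colnames(g2))
  expect_identical(rowSums(g2), rowSums(m))
  # all-distinct genera leave the table unchanged up to relabeling
  tax3 <- c(ASV_1 = "A", ASV_2 = "B", ASV_3 = "C")
  g3 <- collapse_to_genus(m, tax3)
  expect_identical(unname(g3[, c("A", "B", "C")]), unname(m))
})

test_that("core-community dominance applies the >0.1% / >=50% rule inclusively", {
  # one-ASV table: core is that ASV, dominance 1 everywhere
  m1 <- make_table(matrix(c(5L, 9L), ncol = 1))
  d1 <- core_community_dominance(m1)
  expect_equal(as.numeric(d1), c(1, 1))
  # ASV at 0.05% everywhere is excluded from the core
  m2 <- make_table(cbind(rep(1L, 4), rep(1999L, 4)))
  d2 <- core_community_dominance(m2)
  expect_false("ASV_1" %in% attr(d2, "core_asvs"))
  # boundary: above threshold in exactly 2 of 4 samples -> included (>= 50%)
  m3 <- make_table(cbind(c(50L, 50L, 1L, 1L), rep(10000L, 4)))
  d3 <- core_community_dominance(m3)
  expect_true("ASV_1" %in% attr(d3, "core_asvs"))
  expect_true(all(d3 >= 0 & d3 <= 1))
  expect_error(core_community_dominance(make_table(matrix(0L, 1, 1))), "empty")
})
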