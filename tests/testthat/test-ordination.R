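# PCoA geometry, PERMANOVA inference, OPS-to-sputum-centroid distances,
# and DPCoA.

test_that("PCoA reconstructs Euclidean configurations exactly", {
  # three collinear points at 1, 3, 7 -> pairwise distances 2, 4, 6
  pts <- cbind(c(1, 3, 7))
  D <- as.matrix(dist(pts))
  emb <- pcoa(D)
  expect_equal(emb$correction, "none")
  rec <- as.matrix(dist(emb$coordinates))
  expect_equal(unname(rec), unname(D), tolerance = 1e-8)
  # planted planar configuration
  set.seed(8)
  pts2 <- matrix(rnorm(12), 6, 2)
  D2 <- as.matrix(dist(pts2))
  rec2 <- as.matrix(dist(pcoa(D2)$coordinates))
  expect_equal(unname(rec2), unname(D2), tolerance = 1e-8)
  # equal distances d among 3 samples -> equilateral, all reconstructed = d
  D3 <- matrix(0.7, 3, 3); diag(D3) <- 0
  rec3 <- as.matrix(dist(pcoa(D3)$coordinates))
  expect_equal(unname(rec3[upper.tri(rec3)]), rep(0.7, 3), tolerance = 1e-8)
})

test_that("PCoA flags and corrects non-Euclidean matrices", {
  # a metric but non-Euclidean toy: star-like distances violating embeddability
  D <- matrix(c(0, 1, 1, 1,
                1, 0, 1, 1,
                1, 1, 0, 1.9,
                1, 1, 1.9, 0), 4, 4)
  emb <- pcoa(D)
  expect_equal(emb$correction, "lingoes")
  # corrected embedding still reproduces corrected distances among points
  expect_true(all(diff(emb$eigenvalues) <= 1e-8))     # sorted descending
  expect_true(all(emb$proportion_explained >= 0 & emb$proportion_explained <= 1))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA matches the from-definition oracle and exhaustive enumeration", {
  set.seed(21)
  pts <- rbind(matrix(rnorm(6, 0, 0.3), 3, 2), matrix(rnorm(6, 6, 0.3), 3, 2))
  D <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 3)
  res <- permanova(D, g, method = "exhaustive")
  expect_equal(res$f, oracle_permanova_f(D, g), tolerance = 1e-10)
  expect_equal(res$p_value, oracle_permanova_exhaustive_p(D, g), tolerance = 1e-12)
  # with 3+3 samples the best attainable exhaustive p is 72/720
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  # random-permutation p approaches the exhaustive one
  res_mc <- permanova(D, g, n_perm = 999, seed = 4)
  expect_lt(abs(res_mc$p_value - res$p_value), 0.05)
  # two tight, well-separated clusters of 5 are clearly significant
  pts10 <- rbind(matrix(rnorm(10, 0, 0.2), 5, 2), matrix(rnorm(10, 5, 0.2), 5, 2))
  res10 <- permanova(as.matrix(dist(pts10)), rep(c("a", "b"), each = 5),
                     n_perm = 999, seed = 2)
  expect_lte(res10$p_value, 0.05)
})

test_that("PERMANOVA is deterministic under seed and agrees with vegan::adonis2", {
  set.seed(99)
  pts <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(dist(pts))
  g <- rep(c("a", "b", "c"), each = 4)
  r1 <- permanova(D, g, n_perm = 199, seed = 5)
  r2 <- permanova(D, g, n_perm = 199, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  ad <- vegan::adonis2(as.dist(D) ~ g, permutations = 999)
  expect_equal(r1$f, ad$F[1], tolerance = 1e-10)
  expect_equal(r1$r2, ad$R2[1], tolerance = 1e-10)
  expect_error(permanova(D, c(rep("a", 11), "b")), "size < 2")
})

test_that("PERMANOVA type-I error is near nominal under the null", {
  set.seed(12)
  rej <- 0
  nsim <- 400
  for (s in 1:nsim) {
    pts <- matrix(rnorm(20), 10, 2)
    D <- as.matrix(dist(pts))
    g <- sample(rep(c("a", "b"), each = 5))
    p <- permanova(D, g, n_perm = 99, seed = s)$p_value
    if (p <= 0.05) rej <- rej + 1
  }
  expect_gt(rej / nsim, 0.02)
  expect_lt(rej / nsim, 0.09)
})

test_that("OPS-to-sputum-centroid distances match closed-form planar geometry", {
  # 3 sputum at known planar points, 2 OPS; centroid geometry by hand
  spu <- rbind(c(0, 0), c(2, 0), c(1, 3))      # centroid (1, 1)
  ops <- rbind(c(4, 1), c(1, 5))               # distances 3 and 4
  pts <- rbind(spu, ops)
  ids <- c("spu1", "spu2", "spu3", "ops1", "ops2")
  D <- as.matrix(dist(pts)); dimnames(D) <- list(ids, ids)
  meta <- make_meta(ids, paste0("P", 1:5),
                    c("LRT", "LRT", "LRT", "URT", "URT"), rep("EndAZT", 5))
  d <- distance_to_sputum_centroid(D, meta, "EndAZT")
  expect_equal(unname(d[c("ops1", "ops2")]), c(3, 4), tolerance = 1e-8)
  # a lone sputum sample: OPS distance = its pairwise distance
  meta2 <- meta[c(1, 4, 5), ]
  d2 <- distance_to_sputum_centroid(D[c(1, 4, 5), c(1, 4, 5)], meta2, "EndAZT")
  expect_equal(unname(d2), unname(D["spu1", c("ops1", "ops2")]), tolerance = 1e-8)
  # OPS identical to the lone sputum -> distance 0
  D0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  meta0 <- make_meta(c("a", "b"), c("P1", "P2"), c("LRT", "URT"), "EndAZT")
  expect_equal(unname(distance_to_sputum_centroid(D0, meta0, "EndAZT")), 0)
  expect_error(distance_to_sputum_centroid(D[4:5, 4:5], meta[4:5, ], "EndAZT"),
               "no sputum")
})

test_that("DPCoA satisfies the equal-distance closed form and centroid identities", {
  for (d in c(1, 3)) {
    genera <- paste0("G", 1:4)
    Dg <- matrix(d, 4, 4, dimnames = list(genera, genera)); diag(Dg) <- 0
    tab <- make_table(rbind(c(8L, 2L, 0L, 0L), c(0L, 0L, 6L, 4L), c(8L, 2L, 0L, 0L)),
                      asvs = genera)
    res <- dpcoa(tab, Dg, k = 4)
    p <- tab[1, ] / sum(tab[1, ]); q <- tab[2, ] / sum(tab[2, ])
    d2_expected <- (d^2 / 2) * sum((p - q)^2)
    d2_obs <- sum((res$sample_coordinates[1, ] - res$sample_coordinates[2, ])^2)
    expect_equal(d2_obs, d2_expected, tolerance = 1e-8)
    # identical samples coincide
    expect_equal(unname(res$sample_coordinates[1, ]),
                 unname(res$sample_coordinates[3, ]), tolerance = 1e-10)
  }
  # a sample composed 100% of one genus sits on that genus's point
  genera <- paste0("G", 1:3)
  Dg <- matrix(c(0, 1, 2, 1, 0, 1.5, 2, 1.5, 0), 3, 3,
               dimnames = list(genera, genera))
  tab <- make_table(rbind(c(10L, 0L, 0L), c(0L, 5L, 5L)), asvs = genera)
  res <- dpcoa(tab, Dg, k = 3)
  expect_equal(unname(res$sample_coordinates[1, ]),
               unname(res$genus_coordinates["G1", ]), tolerance = 1e-10)
  expect_error(dpcoa(tab, Dg, k = 5), "exceeds")
})

test_that("DPCoA restricts to the k most abundant genera with lexicographic ties", {
  genera <- c("Zeta", "Alpha", "Beta", "Gamma")
  Dg <- matrix(1, 4, 4, dimnames = list(genera, genera)); diag(Dg) <- 0
  # Zeta and Alpha tie on mean abundance; Alpha wins the k=3 cut by name? No:
  # ranking is by abundance first, name only breaks exact ties.
  tab <- make_table(rbind(c(4L, 4L, 2L, 1L), c(4L, 4L, 2L, 1L)), asvs = genera)
  res <- dpcoa(tab, Dg, k = 3)
  expect_setequal(res$genera, c("Alpha", "Zeta", "Beta"))
})

test_that("DPCoA agrees with ade4's implementation on sample distances", {
  skip_if_not_installed("ade4")
  set.seed(14)
  genera <- paste0("G", 1:6)
  pts <- matrix(rnorm(12), 6, 2, dimnames = list(genera, NULL))
  Dg <- as.matrix(dist(pts))
  tab <- make_table(matrix(rpois(30, 5) + 1L, 5, 6), asvs = genera)
  res <- dpcoa(tab, Dg, k = 6)
  ours <- dist(res$sample_coordinates)
  ref <- ade4::dpcoa(as.data.frame(tab), as.dist(Dg), scannf = FALSE, nf = 2)
  # ade4 returns sample (row) coordinates in $li over the same geometry
  theirs <- dist(as.matrix(ref$li))
  expect_equal(unname(as.vector(ours)), unname(as.vector(theirs)), tolerance = 1e-6)
})
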