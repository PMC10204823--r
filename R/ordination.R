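# Ordination and distance-based inference: PCoA with Lingoes correction,
# one-way PERMANOVA, per-phase OPS-to-sputum-centroid distances, and
# double principal coordinate analysis (DPCoA).

as_square_dist <- function(dm) {
  D <- as.matrix(dm)
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-10)))
    stop_aztair("distance matrix must be square and symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop_aztair("distance matrix must have a zero diagonal")
  if (any(D < 0)) stop_aztair("distances must be non-negative")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("s", seq_len(nrow(D)))
  diag(D) <- 0
  D
}

#' Principal coordinate analysis with automatic Lingoes correction
#'
#' Gower-centred eigendecomposition of a distance matrix (via [ape::pcoa()]).
#' When negative eigenvalues beyond `correction_tol` reveal a non-Euclidean
#' matrix — as is typical for UniFrac — the Lingoes correction is applied so
#' the full-rank embedding preserves (corrected) distances exactly; the
#' result is flagged via `$correction`.
#'
#' @param dm a [stats::dist] or symmetric matrix.
#' @param correction_tol tolerance below which negative eigenvalues are
#'   treated as numerical noise (default 1e-8).
#' @return object of class `"aztair_pcoa"`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (descending), `proportion_explained`,
#'   and `correction` (`"none"` or `"lingoes"`).
#' @export
pcoa <- function(dm, correction_tol = 1e-8) {
  D <- as_square_dist(dm)
  n <- nrow(D)
  if (n < 2L) stop_aztair("need >= 2 samples")
  if (all(D == 0)) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(D), "Axis.1"))
    return(structure(list(coordinates = coords, eigenvalues = 0,
                          proportion_explained = 1, correction = "none"),
                     class = "aztair_pcoa"))
  }
  scale_ref <- mean(D[upper.tri(D)]^2)
  res <- ape::pcoa(D)
  eig <- res$values$Eigenvalues
  correction <- "none"
  if (min(eig) < -correction_tol * max(scale_ref, 1)) {
    res <- ape::pcoa(D, correction = "lingoes")
    if (!is.null(res$vectors.cor)) {
      coords <- res$vectors.cor
      eigv <- res$values$Corr_eig
      rel <- res$values$Rel_corr_eig
      correction <- "lingoes"
    } else { # correction unnecessary after all
      coords <- res$vectors
      eigv <- res$values$Eigenvalues
      rel <- res$values$Relative_eig
    }
  } else {
    coords <- res$vectors
    eigv <- eig
    rel <- res$values$Relative_eig
  }
  k <- ncol(coords)
  colnames(coords) <- paste0("Axis.", seq_len(k))
  rownames(coords) <- rownames(D)
  structure(list(coordinates = coords,
                 eigenvalues = sort(eigv, decreasing = TRUE),
                 proportion_explained = rel[seq_len(k)],
                 correction = correction),
            class = "aztair_pcoa")
}

# All permutations of 1..n (n small), as a list of integer vectors.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  lev <- levels(groups)
  a <- length(lev)
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (g in lev) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssa <- sst - ssw
  f <- (ssa / (a - 1)) / (ssw / (n - a))
  c(f = f, r2 = ssa / sst)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Pseudo-F from among- vs within-group sums of squared distances, with a
#' permutation p-value `(1 + #{F_perm >= F_obs}) / (n_perm + 1)` so p is
#' never zero. With `strata`, labels are permuted only within strata (e.g.
#' within patients for repeated measures); with `method = "exhaustive"` all
#' label permutations are enumerated (small n only) and p is the exact
#' permutation fraction.
#'
#' @param dm [stats::dist] or symmetric matrix.
#' @param groups group labels (>= 2 groups, each with >= 2 samples).
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param strata optional vector of stratum labels restricting permutations.
#' @param method `"permutation"` (default) or `"exhaustive"`.
#' @return object of class `"aztair_permanova"`: list with `f`, `r2`,
#'   `p_value`, `n_perm`, `method`, `seed`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = NULL, strata = NULL,
                      method = c("permutation", "exhaustive")) {
  method <- match.arg(method)
  D <- as_square_dist(dm)
  n <- nrow(D)
  if (length(groups) != n) stop_aztair("groups must match the number of samples")
  groups <- droplevels(factor(groups))
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop_aztair("need >= 2 groups")
  if (any(sizes < 2L))
    stop_aztair("group(s) of size < 2: ", paste(names(sizes)[sizes < 2], collapse = ", "))
  d2 <- D^2
  obs <- permanova_f(d2, groups)
  eps <- 1e-12
  if (method == "exhaustive") {
    if (n > 9L) stop_aztair("exhaustive enumeration limited to n <= 9")
    if (!is.null(strata)) stop_aztair("strata not supported with exhaustive enumeration")
    perms <- all_permutations(n)
    fs <- vapply(perms, function(p) permanova_f(d2, groups[p])[["f"]], numeric(1))
    p_value <- mean(fs >= obs[["f"]] - eps)
    n_used <- length(perms)
  } else {
    strata_idx <- if (!is.null(strata)) split(seq_len(n), strata)
    count <- with_seed(seed, {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        if (is.null(strata)) {
          gp <- groups[sample.int(n)]
        } else {
          p <- seq_len(n)
          for (idx in strata_idx) p[idx] <- idx[sample.int(length(idx))]
          gp <- groups[p]
        }
        if (permanova_f(d2, gp)[["f"]] >= obs[["f"]] - eps) cnt <- cnt + 1L
      }
      cnt
    })
    p_value <- (1 + count) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(f = unname(obs[["f"]]), r2 = unname(obs[["r2"]]),
                 p_value = p_value, n_perm = n_used, method = method,
                 seed = seed),
            class = "aztair_permanova")
}

#' @export
print.aztair_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%s, %d permutations)\n",
              x$f, x$r2, x$p_value, x$method, x$n_perm))
  invisible(x)
}

#' Distance from each OPS sample to the sputum centroid, per phase
#'
#' For one treatment phase, all of that phase's samples are embedded by
#' corrected PCoA of the supplied (UniFrac) distance matrix; the centroid is
#' the coordinate mean of the sputum (LRT) samples, and the returned value
#' for each oropharyngeal-swab (URT) sample is its Euclidean distance to
#' that centroid in the embedding — the construction used by dispersion
#' analysis, chosen because UniFrac space is non-Euclidean and a mean
#' community profile would not be distance-consistent.
#'
#' @param dm distance matrix over (at least) the phase's samples.
#' @param meta sample metadata (see [validate_metadata()]).
#' @param phase one of [AZT_PHASES].
#' @return named numeric vector: distance to the sputum centroid for each
#'   URT sample of the phase.
#' @export
distance_to_sputum_centroid <- function(dm, meta, phase) {
  validate_metadata(meta)
  if (!phase %in% AZT_PHASES)
    stop_aztair("unknown phase: ", phase)
  D <- as_square_dist(dm)
  ids <- intersect(rownames(D), meta$sample_id[meta$phase == phase])
  m <- meta[match(ids, meta$sample_id), ]
  spu <- ids[m$site == "LRT"]
  ops <- ids[m$site == "URT"]
  if (length(spu) == 0L) stop_aztair("no sputum (LRT) samples in phase ", phase)
  if (length(ops) == 0L) stop_aztair("no OPS (URT) samples in phase ", phase)
  emb <- pcoa(D[ids, ids, drop = FALSE])
  coords <- emb$coordinates
  centroid <- colMeans(coords[spu, , drop = FALSE])
  delta <- sweep(coords[ops, , drop = FALSE], 2, centroid)
  stats::setNames(sqrt(rowSums(delta^2)), ops)
}

#' OPS-to-sputum-centroid distances across all phases
#'
#' Convenience wrapper applying [distance_to_sputum_centroid()] to each
#' phase present in the metadata (phases lacking either site are skipped).
#'
#' @inheritParams distance_to_sputum_centroid
#' @return data.frame with columns phase, sample_id, distance.
#' @export
ops_centroid_distances <- function(dm, meta) {
  res <- lapply(AZT_PHASES, function(ph) {
    m <- meta[meta$phase == ph & meta$sample_id %in% labels(stats::as.dist(dm)), ]
    if (!all(AZT_SITES %in% m$site)) return(NULL)
    d <- distance_to_sputum_centroid(dm, meta, ph)
    data.frame(phase = ph, sample_id = names(d), distance = unname(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Double principal coordinate analysis (DPCoA)
#'
#' Pavoine-style DPCoA: genera are embedded by (corrected) PCoA of their
#' pairwise (patristic) distances; each sample is placed at the
#' abundance-weighted centroid of its genus points; the cloud of sample
#' points, weighted by sample totals, is then rotated to its principal
#' axes. Sample and genus coordinates are returned in the same space.
#' The analysis is restricted to the `k` most abundant genera (by mean
#' relative abundance, ties broken by genus name), with per-sample
#' proportions renormalized over those genera.
#'
#' @param genus_counts genus-level feature table (see [collapse_to_genus()]).
#' @param genus_dist distances among genera (dist or matrix), e.g. patristic
#'   distances from [ape::cophenetic.phylo()] of a genus-level tree.
#' @param k number of most-abundant genera to retain (default 15).
#' @param correction_tol Lingoes-correction tolerance, as in [pcoa()].
#' @return list of class `"aztair_dpcoa"`: `sample_coordinates`,
#'   `genus_coordinates`, `eigenvalues`, `proportion_explained`, `genera`
#'   (the retained genera) and `correction`.
#' @export
dpcoa <- function(genus_counts, genus_dist, k = 15, correction_tol = 1e-8) {
  validate_feature_table(genus_counts)
  D <- as_square_dist(genus_dist)
  if (k > ncol(genus_counts))
    stop_aztair("k = ", k, " exceeds the ", ncol(genus_counts), " available genera")
  rel <- genus_counts / rowSums(genus_counts)
  mean_ab <- colMeans(rel)
  ord <- order(-mean_ab, colnames(genus_counts))
  top <- colnames(genus_counts)[ord][seq_len(k)]
  absent <- setdiff(top, rownames(D))
  if (length(absent))
    stop_aztair("genus distance matrix missing: ", paste(absent, collapse = ", "))
  X <- genus_counts[, top, drop = FALSE]
  totals <- rowSums(X)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " sample(s) with no reads in the retained genera dropped")
    X <- X[totals > 0, , drop = FALSE]
    totals <- rowSums(X)
  }
  P <- X / totals
  emb <- pcoa(D[top, top, drop = FALSE], correction_tol = correction_tol)
  Z <- emb$coordinates                       # genera x axes, distance-preserving
  Y <- P %*% Z                               # samples at weighted genus centroids
  w <- totals / sum(totals)
  mu <- colSums(w * Y)
  Yc <- sweep(Y, 2, mu)
  Zc <- sweep(Z, 2, mu)
  cov_w <- crossprod(Yc, w * Yc)
  ev <- eigen(cov_w, symmetric = TRUE)
  keep <- ev$values > max(ev$values[1], 0) * 1e-12
  if (!any(keep)) keep <- 1L
  V <- ev$vectors[, keep, drop = FALSE]
  eigv <- ev$values[keep]
  sample_coords <- Yc %*% V
  genus_coords <- Zc %*% V
  ax <- paste0("Axis.", seq_len(ncol(V)))
  dimnames(sample_coords) <- list(rownames(X), ax)
  dimnames(genus_coords) <- list(top, ax)
  pos <- sum(ev$values[ev$values > 0])
  structure(list(sample_coordinates = sample_coords,
                 genus_coordinates = genus_coords,
                 eigenvalues = eigv,
                 proportion_explained = if (pos > 0) eigv / pos else rep(0, length(eigv)),
                 genera = top,
                 correction = emb$correction),
            class = "aztair_dpcoa")
}
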