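# UniFrac distances, computed by explicit branch classification: every edge
# of the rooted tree is weighted by its branch length and by which of the two
# communities have member taxa descending from it.

# Logical incidence matrix: rows = edges, cols = tips; TRUE when the tip
# descends from the edge's child node.
edge_tip_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  E <- matrix(FALSE, nrow(tree$edge), ntip,
              dimnames = list(NULL, tree$tip.label))
  for (k in seq_along(desc)) E[k, desc[[k]]] <- TRUE
  E
}

# Align sample count vectors (named, or a character set of observed taxa)
# to the tree tip order. Errors on observed taxa missing from the tree.
align_to_tips <- function(x, tree, what = "sample") {
  if (is.character(x)) x <- stats::setNames(rep(1, length(x)), x)
  if (is.null(names(x))) stop_aztair(what, " must be named by ASV id")
  absent <- setdiff(names(x)[x > 0], tree$tip.label)
  if (length(absent))
    stop_aztair(what, " has ASV(s) missing from tree: ", paste(absent, collapse = ", "))
  out <- stats::setNames(rep(0, length(tree$tip.label)), tree$tip.label)
  out[names(x)] <- x
  out
}

#' Unweighted UniFrac distance between two communities
#'
#' Fraction of observed branch length unique to one community: the summed
#' length of branches leading exclusively to taxa of one of the two samples,
#' divided by the summed length of branches leading to taxa of either.
#' Presence only; always in `[0, 1]`.
#'
#' @param a,b communities: named count vectors (ASV id -> reads) or
#'   character vectors of observed ASV ids.
#' @param tree rooted "phylo" with branch lengths covering all observed ASVs.
#' @return distance in `[0, 1]`.
#' @export
unweighted_unifrac <- function(a, b, tree) {
  pa <- align_to_tips(a, tree, "a") > 0
  pb <- align_to_tips(b, tree, "b") > 0
  if (!any(pa) && !any(pb)) stop_aztair("both samples are empty")
  E <- edge_tip_matrix(tree)
  in_a <- as.vector(E %*% pa) > 0
  in_b <- as.vector(E %*% pb) > 0
  L <- tree$edge.length
  union <- sum(L[in_a | in_b])
  if (union == 0) return(0)
  sum(L[xor(in_a, in_b)]) / union
}

#' Weighted UniFrac distance between two communities
#'
#' `sum_b L_b | P_a(b) - P_b(b) |`, where `P_s(b)` is the fraction of sample
#' `s` reads descending from branch `b`; abundances are converted to
#' proportions first, so the distance is invariant to sequencing depth.
#' With `normalized = TRUE` (default) the raw value is divided by its
#' maximum attainable value `sum_b L_b (P_a(b) + P_b(b))`, bounding the
#' result to `[0, 1]`.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized divide by the maximum attainable value (default TRUE).
#' @return distance (raw, or in `[0, 1]` if normalized).
#' @export
weighted_unifrac <- function(a, b, tree, normalized = TRUE) {
  xa <- align_to_tips(a, tree, "a")
  xb <- align_to_tips(b, tree, "b")
  if (sum(xa) == 0 || sum(xb) == 0) stop_aztair("empty sample")
  pa <- xa / sum(xa)
  pb <- xb / sum(xb)
  E <- edge_tip_matrix(tree)
  fa <- as.vector(E %*% pa)
  fb <- as.vector(E %*% pb)
  L <- tree$edge.length
  raw <- sum(L * abs(fa - fb))
  if (!normalized) return(raw)
  denom <- sum(L * (fa + fb))
  if (denom == 0) return(0)
  raw / denom
}

#' All-pairs UniFrac distance matrix
#'
#' Applies [unweighted_unifrac()] or [weighted_unifrac()] to every pair of
#' samples in a feature table. The tree is pruned to the table's ASVs; every
#' ASV with reads must be a tip.
#'
#' @param counts feature table (samples x ASVs), typically rarefied.
#' @param tree rooted "phylo" covering the table's ASVs.
#' @param metric `"unweighted_unifrac"` or `"weighted_unifrac"`.
#' @param normalized for the weighted metric, normalize to `[0, 1]`
#'   (default TRUE).
#' @return a [stats::dist] object with `attr(, "metric")` set.
#' @export
distance_matrix <- function(counts, tree,
                            metric = c("unweighted_unifrac", "weighted_unifrac"),
                            normalized = TRUE) {
  validate_feature_table(counts)
  metric <- match.arg(metric)
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop_aztair("empty sample(s): ",
                paste(rownames(counts)[totals == 0], collapse = ", "))
  used <- colnames(counts)[colSums(counts) > 0]
  absent <- setdiff(used, tree$tip.label)
  if (length(absent))
    stop_aztair("table ASV(s) missing from tree: ", paste(absent, collapse = ", "))
  tips <- intersect(tree$tip.label, colnames(counts))
  sub <- if (length(setdiff(tree$tip.label, tips))) ape::keep.tip(tree, tips) else tree
  E <- edge_tip_matrix(sub)
  L <- sub$edge.length
  X <- counts[, sub$tip.label, drop = FALSE]
  n <- nrow(X)
  if (metric == "unweighted_unifrac") {
    O <- (X > 0) %*% t(E) > 0           # samples x edges: any descendant observed
    C <- O %*% (L * t(O))               # C[a,b] = sum L over edges observed in both
    Tt <- diag(C)
    un <- outer(Tt, Tt, "+") - 2 * C    # branch length unique to one sample
    uni <- outer(Tt, Tt, "+") - C       # branch length in either sample
    D <- ifelse(uni > 0, un / uni, 0)
  } else {
    P <- X / totals
    B <- P %*% t(E)                     # samples x edges: descending proportion
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        raw <- sum(L * abs(B[i, ] - B[j, ]))
        if (normalized) {
          denom <- sum(L * (B[i, ] + B[j, ]))
          raw <- if (denom > 0) raw / denom else 0
        }
        D[i, j] <- D[j, i] <- raw
      }
    }
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  out <- stats::as.dist(D)
  attr(out, "metric") <- if (metric == "weighted_unifrac" && !normalized)
    "weighted_unifrac_raw" else metric
  out
}
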