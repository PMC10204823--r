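# Within-sample (alpha) diversity: Chao1 richness, Shannon index, Camargo
# evenness and Faith's phylogenetic diversity.

check_counts <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop_aztair("counts must be finite non-negative integers")
  if (sum(x) == 0) stop_aztair("all-zero sample")
  x
}

#' Bias-corrected Chao1 richness
#'
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` where `f1`/`f2` are the numbers of
#' singleton and doubleton ASVs. Always at least the observed richness;
#' equal to it when there are no singletons.
#'
#' @param x one sample's integer counts.
#' @return estimated richness (real, >= observed richness).
#' @export
chao1 <- function(x) {
  x <- check_counts(x)
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i log p_i)` over observed ASVs, in nats.
#'
#' @param x one sample's integer counts.
#' @return `H` in `[0, log(S_obs)]`.
#' @export
shannon <- function(x) {
  x <- check_counts(x)
  unname(vegan::diversity(x, index = "shannon"))
}

#' Camargo evenness
#'
#' `E = 1 - sum_{i<j} |p_i - p_j| / S` over the `S` observed (nonzero) ASVs.
#' 1 for perfectly even communities; decreases as abundance concentrates.
#'
#' @param x one sample's integer counts.
#' @return evenness in `(0, 1]`.
#' @export
camargo_evenness <- function(x) {
  x <- check_counts(x)
  p <- x[x > 0] / sum(x)
  s <- length(p)
  if (s == 1L) return(1)
  1 - sum(stats::dist(p, method = "manhattan")) / s
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting a sample's observed
#' ASVs; with `include_root = TRUE` (the default, the rooted-PD convention)
#' the subtree is anchored at the tree root.
#'
#' @param x one sample's counts, named by ASV id (or a character vector of
#'   observed ASV ids).
#' @param tree rooted "phylo" object whose tips include the observed ASVs.
#' @param include_root include the path from the subtree down to the root
#'   (default `TRUE`); with `FALSE`, branches above the observed taxa's most
#'   recent common ancestor are excluded.
#' @return summed branch length (>= 0).
#' @export
faith_pd <- function(x, tree, include_root = TRUE) {
  if (is.character(x)) {
    taxa <- x
  } else {
    x <- check_counts(x)
    if (is.null(names(x))) stop_aztair("counts must be named by ASV id")
    taxa <- names(x)[x > 0]
  }
  absent <- setdiff(taxa, tree$tip.label)
  if (length(absent))
    stop_aztair("observed ASV(s) missing from tree: ", paste(absent, collapse = ", "))
  if (length(taxa) == 0L) stop_aztair("no observed ASVs")
  E <- edge_tip_matrix(tree)
  observed_edge <- as.vector(E %*% (tree$tip.label %in% taxa)) > 0
  pd <- sum(tree$edge.length[observed_edge])
  if (!include_root) pd <- pd - root_path_length(tree, taxa)
  pd
}

# Summed branch length on the path from the MRCA of `taxa` (the tip itself
# for a single taxon) up to the root.
root_path_length <- function(tree, taxa) {
  node <- if (length(taxa) == 1L) match(taxa, tree$tip.label)
          else ape::getMRCA(tree, taxa)
  root <- length(tree$tip.label) + 1L
  len <- 0
  while (!is.na(node) && node != root) {
    k <- which(tree$edge[, 2] == node)
    if (length(k) == 0L) break
    len <- len + tree$edge.length[k]
    node <- tree$edge[k, 1]
  }
  len
}

#' Alpha diversity for every sample of a table
#'
#' Computes the requested metrics per sample and returns a tidy long-format
#' data.frame; when `meta` is supplied, `site` and `phase` columns are
#' joined in.
#'
#' @param counts feature table (samples x ASVs), typically rarefied.
#' @param tree rooted "phylo"; required for `faith_pd`.
#' @param metrics subset of `c("chao1", "shannon", "camargo_evenness",
#'   "faith_pd")`.
#' @param meta optional sample metadata (see [validate_metadata()]).
#' @return data.frame with columns sample_id, (site, phase,) metric, value.
#' @export
alpha_diversity <- function(counts, tree = NULL,
                            metrics = c("chao1", "shannon", "camargo_evenness", "faith_pd"),
                            meta = NULL) {
  validate_feature_table(counts)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if ("faith_pd" %in% metrics && is.null(tree))
    stop_aztair("faith_pd requires a tree")
  res <- lapply(metrics, function(m) {
    vals <- switch(m,
      chao1 = apply(counts, 1, chao1),
      shannon = apply(counts, 1, shannon),
      camargo_evenness = apply(counts, 1, camargo_evenness),
      faith_pd = {
        tips <- intersect(tree$tip.label, colnames(counts))
        if (length(setdiff(colnames(counts)[colSums(counts) > 0], tips)))
          stop_aztair("table has observed ASVs missing from tree")
        sub <- if (length(setdiff(tree$tip.label, tips)))
          ape::keep.tip(tree, tips) else tree
        E <- edge_tip_matrix(sub)
        O <- (counts[, sub$tip.label, drop = FALSE] > 0) %*% t(E) > 0
        as.vector(O %*% sub$edge.length)
      })
    data.frame(sample_id = rownames(counts), metric = m, value = as.numeric(vals),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(meta)) {
    validate_metadata(meta)
    out <- merge(out, meta[, c("sample_id", "site", "phase")],
                 by = "sample_id", sort = FALSE)
    out <- out[, c("sample_id", "site", "phase", "metric", "value")]
  }
  rownames(out) <- NULL
  out
}
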