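# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths (and helper
# packages) the implementations use: descendant sets come from a plain
# recursion over the edge table, statistics from direct formula evaluation
# or exhaustive enumeration.

oracle_chao1 <- function(x) {
  s <- sum(x > 0); f1 <- sum(x == 1); f2 <- sum(x == 2)
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

oracle_camargo <- function(x) {
  p <- x[x > 0] / sum(x)
  s <- length(p)
  tot <- 0
  if (s > 1) for (i in 1:(s - 1)) for (j in (i + 1):s) tot <- tot + abs(p[i] - p[j])
  unname(1 - tot / s)
}

# Descendant tip labels below each edge's child node, by plain recursion.
oracle_edge_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  lapply(seq_len(nrow(tree$edge)), function(k) desc(tree$edge[k, 2]))
}

# Rooted Faith PD: total length of edges with >= 1 observed descendant tip.
oracle_pd <- function(tree, taxa) {
  tips <- oracle_edge_tips(tree)
  keep <- vapply(tips, function(tt) any(tt %in% taxa), logical(1))
  sum(tree$edge.length[keep])
}

# Unweighted UniFrac by explicit classification of every branch as
# shared/unique via its descendant set.
oracle_unweighted_unifrac <- function(tree, a, b) {
  tips <- oracle_edge_tips(tree)
  in_a <- vapply(tips, function(tt) any(tt %in% a), logical(1))
  in_b <- vapply(tips, function(tt) any(tt %in% b), logical(1))
  L <- tree$edge.length
  uni <- sum(L[in_a | in_b])
  if (uni == 0) return(0)
  sum(L[xor(in_a, in_b)]) / uni
}

# Weighted UniFrac from per-branch descending proportions.
oracle_weighted_unifrac <- function(tree, xa, xb, normalized = TRUE) {
  tips <- oracle_edge_tips(tree)
  pa <- xa / sum(xa); pb <- xb / sum(xb)
  fa <- vapply(tips, function(tt) sum(pa[tt]), numeric(1))
  fb <- vapply(tips, function(tt) sum(pb[tt]), numeric(1))
  L <- tree$edge.length
  raw <- sum(L * abs(fa - fb))
  if (!normalized) return(raw)
  raw / sum(L * (fa + fb))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_signed_rank_p <- function(x, y) {
  d <- (x - y)[x - y != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# PERMANOVA pseudo-F computed directly from the definition.
oracle_permanova_f <- function(D, groups) {
  n <- nrow(D)
  sst <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) sst <- sst + D[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      s <- 0
      for (i in idx) for (j in idx) if (i < j) s <- s + D[i, j]^2
      ssw <- ssw + s / length(idx)
    }
  }
  a <- length(unique(groups))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# Exhaustive permutation p for PERMANOVA (all n! relabellings).
oracle_permanova_exhaustive_p <- function(D, groups) {
  n <- nrow(D)
  perm_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  f_obs <- oracle_permanova_f(D, groups)
  fs <- vapply(perm_all(seq_len(n)), function(p) oracle_permanova_f(D, groups[p]),
               numeric(1))
  mean(fs >= f_obs - 1e-12)
}

# Random rooted tree plus random integer communities over its tips.
random_instance <- function(n_tips, n_samples = 2, max_count = 20) {
  tree <- ape::rtree(n_tips, br = function(k) stats::runif(k, 0.1, 2))
  tree$tip.label <- paste0("t", seq_len(n_tips))
  counts <- matrix(stats::rpois(n_samples * n_tips, 3), n_samples, n_tips,
                   dimnames = list(paste0("s", seq_len(n_samples)), tree$tip.label))
  # ensure no empty sample
  for (i in seq_len(n_samples)) if (sum(counts[i, ]) == 0) counts[i, 1] <- 1L
  storage.mode(counts) <- "integer"
  list(tree = tree, counts = counts)
}
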