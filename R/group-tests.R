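# Non-parametric group comparisons: Kruskal-Wallis omnibus with Dunn's
# post hoc z-tests and Holm step-down adjustment, and the paired Wilcoxon
# signed-rank test.

#' Kruskal-Wallis with Dunn's post hoc test and Holm adjustment
#'
#' Tie-corrected Kruskal-Wallis omnibus test across groups, followed by
#' Dunn's pairwise z-tests on the joint ranks with Holm's step-down
#' adjustment across all pairs (the multiplicity family is the set of
#' pairwise comparisons made in this one call).
#'
#' By convention, data with zero rank variance (all values identical) give
#' statistic 0 and p = 1 rather than an undefined ratio.
#'
#' @param values numeric vector of per-sample values.
#' @param groups group labels, same length as `values`; >= 2 groups with
#'   >= 2 observations each.
#' @return object of class `"aztair_group_test"`: a list with `statistic`,
#'   `df`, `p_value` (omnibus), `pairwise` (data.frame: group1, group2, z,
#'   p_raw, p_adj), `adjust_method` and `n`.
#' @export
compare_groups <- function(values, groups) {
  if (length(values) != length(groups))
    stop_aztair("values and groups must have equal length")
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  groups <- droplevels(groups)
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop_aztair("need >= 2 groups")
  if (any(sizes < 2L))
    stop_aztair("group(s) with < 2 observations: ",
                paste(names(sizes)[sizes < 2], collapse = ", "))
  n <- length(values)
  if (length(unique(values)) == 1L) {
    kw_stat <- 0; kw_p <- 1
  } else {
    kw <- stats::kruskal.test(values, groups)
    kw_stat <- unname(kw$statistic); kw_p <- kw$p.value
  }
  # Dunn's z statistics on joint ranks with tie correction
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_term
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  pw <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(s2 * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  pairwise <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = pw["z", ], p_raw = pw["p", ],
    p_adj = stats::p.adjust(pw["p", ], method = "holm"),
    stringsAsFactors = FALSE)
  rownames(pairwise) <- NULL
  structure(list(statistic = kw_stat, df = nlevels(groups) - 1L, p_value = kw_p,
                 pairwise = pairwise, adjust_method = "holm", n = n),
            class = "aztair_group_test")
}

#' @export
print.aztair_group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  cat("Dunn's post hoc (Holm-adjusted):\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on per-patient paired values; zero differences
#' are dropped (the standard convention). Exact p-values are used when the
#' sample is small and untied, the normal approximation otherwise (the
#' [stats::wilcox.test()] default).
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_effective` (pairs remaining after dropping zero differences) and
#'   `exact` (logical).
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stop_aztair("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  d <- d[d != 0]
  if (length(d) == 0L)
    stop_aztair("no informative pairs: all paired differences are zero")
  if (length(d) < 5L)
    warning("fewer than 5 informative pairs; the signed-rank test has little power")
  exact <- length(d) < 50 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_effective = length(d), exact = exact)
}
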