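# Rarefaction, genus aggregation and core-community summaries.

#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (a single multivariate-hypergeometric draw per sample, via
#' [vegan::rrarefy()]). Samples whose total read count falls below `depth`
#' are dropped and reported in the `"dropped_samples"` attribute.
#'
#' Presence/absence downstream (turnover, site overlap, unweighted UniFrac)
#' is defined on the rarefied table: an ASV is "present" when it retains at
#' least one read after subsampling.
#'
#' @param counts feature table (samples x ASVs, integers).
#' @param depth target depth, >= 1.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return rarefied integer matrix with equal row sums (`depth`); attribute
#'   `"dropped_samples"` lists excluded sample ids and `"depth"` records the
#'   depth used.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  validate_feature_table(counts)
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1 || depth != round(depth))
    stop_aztair("depth must be a positive integer")
  depth <- as.integer(depth)
  totals <- rowSums(counts)
  drop <- rownames(counts)[totals < depth]
  keep <- counts[totals >= depth, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop_aztair("no sample reaches depth ", depth)
  # rrarefy's "observed counts" heuristic misfires on tables without
  # singletons; counts here are validated integers, so silence just that
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(keep, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(keep)
  if (length(drop))
    message(length(drop), " sample(s) below depth ", depth, " dropped: ",
            paste(drop, collapse = ", "))
  structure(out, dropped_samples = drop, depth = depth)
}

#' Collapse an ASV table to genus level
#'
#' Sums counts of ASVs sharing a genus label. ASVs absent from the map are
#' pooled under `sentinel`. Per-sample totals are conserved exactly.
#'
#' @param counts feature table (samples x ASVs).
#' @param tax named character vector ASV -> genus (see [read_taxonomy()]).
#' @param sentinel genus label for unmapped ASVs.
#' @return integer matrix, samples x genera.
#' @export
collapse_to_genus <- function(counts, tax, sentinel = "Unclassified") {
  validate_feature_table(counts)
  genus <- unname(tax[colnames(counts)])
  genus[is.na(genus)] <- sentinel
  groups <- factor(genus)
  out <- t(rowsum(t(counts), groups))
  colnames(out) <- levels(groups)
  storage.mode(out) <- "integer"
  out
}

#' Core-community dominance per sample
#'
#' The core community is the set of ASVs whose within-sample relative
#' abundance exceeds `abundance_threshold` in at least a fraction
#' `prevalence_threshold` of samples (defaults: >0.1% in >= 50% of samples).
#' Returns, per sample, the summed relative abundance of the core set — a
#' measure of how much of each community the common, prevalent taxa account
#' for.
#'
#' @param counts feature table (samples x ASVs), typically rarefied.
#' @param abundance_threshold relative-abundance cutoff (default 0.001).
#' @param prevalence_threshold fraction of samples that must exceed the
#'   abundance cutoff (default 0.5, inclusive).
#' @return named numeric vector in `[0, 1]` (one value per sample), with the
#'   core ASV ids in attribute `"core_asvs"`.
#' @export
core_community_dominance <- function(counts, abundance_threshold = 0.001,
                                     prevalence_threshold = 0.5) {
  validate_feature_table(counts)
  totals <- rowSums(counts)
  if (nrow(counts) == 0L || all(totals == 0))
    stop_aztair("empty feature table")
  rel <- counts / totals
  prevalence <- colMeans(rel > abundance_threshold)
  core <- colnames(counts)[prevalence >= prevalence_threshold]
  dominance <- rowSums(rel[, core, drop = FALSE])
  structure(stats::setNames(dominance, rownames(counts)), core_asvs = core)
}
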