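# ASV turnover over treatment windows: retained / cleared / acquired
# classification, site-overlap (Venn) proportions, and cross-site tracking
# of the relative abundance of cleared or acquired taxa.
#
# Presence means >= 1 read in the (rarefied) table, so windows are compared
# at equal sequencing effort; rarefaction can turn very low counts into
# absence, which is a documented caveat of presence-based turnover.

present_asvs <- function(counts, sample_id) {
  colnames(counts)[counts[sample_id, ] > 0]
}

# Earliest sample for (patient, site, phase); NA when absent. Where several
# exist (possible across crossover arms) the earliest by time_months is
# used, with a log record via message().
find_sample <- function(meta, patient, site, phase) {
  rows <- meta[meta$patient_id == patient & meta$site == site & meta$phase == phase, ]
  if (nrow(rows) == 0L) return(NA_character_)
  if (nrow(rows) > 1L) {
    rows <- rows[order(rows$time_months), ]
    message("patient ", patient, " has ", nrow(rows), " samples for (", site,
            ", ", phase, "); using earliest")
  }
  rows$sample_id[1L]
}

#' Classify ASV turnover for one patient, site and window
#'
#' Partition of a patient's ASVs over a window from `start_phase` to
#' `end_phase` at one site: `retained` = present at both ends, `cleared` =
#' present only at the start, `acquired` = present only at the end
#' (presence = at least one read in the rarefied table).
#'
#' @param counts rarefied feature table.
#' @param meta sample metadata.
#' @param patient patient id.
#' @param site `"LRT"` or `"URT"`.
#' @param start_phase,end_phase window endpoints (phases).
#' @return list of class `"aztair_turnover"` with `patient_id`, `site`,
#'   `window`, and character vectors `retained`, `cleared`, `acquired`;
#'   `NULL` (with a message) when either endpoint sample is missing.
#' @export
classify_turnover <- function(counts, meta, patient, site,
                              start_phase = "StartAZT", end_phase = "EndAZT") {
  validate_feature_table(counts)
  validate_metadata(meta)
  s_start <- find_sample(meta, patient, site, start_phase)
  s_end <- find_sample(meta, patient, site, end_phase)
  if (is.na(s_start) || is.na(s_end) ||
      !all(c(s_start, s_end) %in% rownames(counts))) {
    message("patient ", patient, " skipped (", site, ", ", start_phase, " -> ",
            end_phase, "): missing paired sample")
    return(NULL)
  }
  at_start <- present_asvs(counts, s_start)
  at_end <- present_asvs(counts, s_end)
  res <- list(patient_id = patient, site = site,
              window = c(start = start_phase, end = end_phase),
              retained = intersect(at_start, at_end),
              cleared = setdiff(at_start, at_end),
              acquired = setdiff(at_end, at_start))
  # partition identities, asserted on every run
  stopifnot(setequal(union(res$retained, res$cleared), at_start),
            setequal(union(res$retained, res$acquired), at_end),
            length(intersect(res$cleared, res$acquired)) == 0L)
  class(res) <- "aztair_turnover"
  res
}

#' Turnover classification for every patient of a site
#'
#' @inheritParams classify_turnover
#' @return named list of [classify_turnover()] results (patients with a
#'   complete pair only).
#' @export
turnover_by_patient <- function(counts, meta, site,
                                start_phase = "StartAZT", end_phase = "EndAZT") {
  patients <- unique(meta$patient_id)
  res <- lapply(patients, function(p)
    classify_turnover(counts, meta, p, site, start_phase, end_phase))
  names(res) <- patients
  res[!vapply(res, is.null, logical(1))]
}

#' Site-overlap (Venn) classification of ASVs within a phase
#'
#' Assigns each ASV observed in a phase to one of three disjoint
#' categories: present only in LRT samples, only in URT samples, or in
#' both sites (presence = >= 1 read in >= 1 sample of the site in that
#' phase).
#'
#' @param counts rarefied feature table.
#' @param meta sample metadata.
#' @param phase one of [AZT_PHASES].
#' @return list with `counts` (named integer: lrt_only, urt_only, both),
#'   `proportions` (summing to 1), and `asvs` (the category membership).
#' @export
site_overlap <- function(counts, meta, phase) {
  validate_feature_table(counts)
  validate_metadata(meta)
  ids <- intersect(rownames(counts), meta$sample_id[meta$phase == phase])
  m <- meta[match(ids, meta$sample_id), ]
  lrt_ids <- ids[m$site == "LRT"]
  urt_ids <- ids[m$site == "URT"]
  if (length(lrt_ids) == 0L || length(urt_ids) == 0L)
    stop_aztair("phase ", phase, " lacks samples at both sites")
  in_lrt <- colSums(counts[lrt_ids, , drop = FALSE]) > 0
  in_urt <- colSums(counts[urt_ids, , drop = FALSE]) > 0
  asvs <- list(lrt_only = colnames(counts)[in_lrt & !in_urt],
               urt_only = colnames(counts)[!in_lrt & in_urt],
               both = colnames(counts)[in_lrt & in_urt])
  cnt <- vapply(asvs, length, integer(1))
  total <- sum(cnt)
  if (total == 0L) stop_aztair("no ASVs observed in phase ", phase)
  list(counts = cnt, proportions = cnt / total, asvs = asvs)
}

#' Chi-squared goodness-of-fit test on category counts
#'
#' Pearson X^2 against expected proportions (uniform across categories by
#' default), df = k - 1.
#'
#' @param category_counts named integer vector (>= 2 categories).
#' @param expected expected proportions (default uniform); rescaled to sum
#'   to 1.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chisq_gof <- function(category_counts, expected = NULL) {
  x <- as.numeric(category_counts)
  if (length(x) < 2L) stop_aztair("need >= 2 categories")
  if (sum(x) == 0) stop_aztair("zero total count")
  p <- if (is.null(expected)) rep(1 / length(x), length(x)) else expected / sum(expected)
  ct <- suppressWarnings(stats::chisq.test(x, p = p))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = unname(ct$expected))
}

#' Tracked relative abundance of an ASV set across phases
#'
#' For every sample of a site, the summed relative abundance of a fixed ASV
#' set (e.g. the taxa cleared or acquired during treatment), grouped by
#' phase — the within-sample fraction of reads the set accounts for over
#' the whole study.
#'
#' @param counts rarefied feature table.
#' @param meta sample metadata.
#' @param asv_set character vector of ASV ids (typically from
#'   [classify_turnover()]); an empty set gives an all-zero series.
#' @param site `"LRT"` or `"URT"`.
#' @return list with `samples` (data.frame: sample_id, phase, value) and
#'   `summary` (per-phase median and quartiles).
#' @export
tracked_relative_abundance <- function(counts, meta, asv_set, site) {
  validate_feature_table(counts)
  validate_metadata(meta)
  ids <- intersect(rownames(counts), meta$sample_id[meta$site == site])
  if (length(ids) == 0L) stop_aztair("no samples for site ", site)
  m <- meta[match(ids, meta$sample_id), ]
  set <- intersect(asv_set, colnames(counts))
  vals <- if (length(set)) {
    rowSums(counts[ids, set, drop = FALSE]) / rowSums(counts[ids, , drop = FALSE])
  } else rep(0, length(ids))
  samples <- data.frame(sample_id = ids, phase = m$phase, value = unname(vals),
                        stringsAsFactors = FALSE)
  qs <- do.call(rbind, lapply(split(samples$value, factor(samples$phase, AZT_PHASES)),
                              function(v) {
    if (length(v) == 0L) return(data.frame(n = 0L, q1 = NA_real_, median = NA_real_, q3 = NA_real_))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), q1 = q[1], median = q[2], q3 = q[3])
  }))
  summary <- cbind(phase = rownames(qs), qs)
  rownames(summary) <- NULL
  list(samples = samples, summary = summary)
}

#' Within-patient tracking of cleared or acquired taxa across phases
#'
#' Evaluates, for each patient, the summed relative abundance of that
#' patient's own cleared (or acquired) ASV set in that patient's samples at
#' a site, across all phases — the within-patient longitudinal kinetics of
#' the taxa lost or gained during the treatment window. By construction the
#' cleared set has zero abundance at the window-end sample and the acquired
#' set zero at the window-start sample.
#'
#' @param counts rarefied feature table.
#' @param meta sample metadata.
#' @param results named list of [classify_turnover()] results (names =
#'   patient ids), e.g. from [turnover_by_patient()]; the sets tracked are
#'   taken per patient from here.
#' @param set `"cleared"` or `"acquired"`.
#' @param site site whose samples to evaluate (the sets may come from the
#'   other site, e.g. LRT-cleared taxa tracked in the URT).
#' @return list with `samples` (data.frame: patient_id, sample_id, phase,
#'   value) and `summary` (per-phase n, quartiles and median).
#' @export
tracked_turnover_abundance <- function(counts, meta, results,
                                       set = c("cleared", "acquired"), site) {
  set <- match.arg(set)
  validate_feature_table(counts)
  validate_metadata(meta)
  out <- list()
  for (r in results) {
    ids <- intersect(rownames(counts),
                     meta$sample_id[meta$site == site &
                                    meta$patient_id == r$patient_id])
    if (length(ids) == 0L) next
    taxa <- intersect(r[[set]], colnames(counts))
    vals <- if (length(taxa)) {
      rowSums(counts[ids, taxa, drop = FALSE]) / rowSums(counts[ids, , drop = FALSE])
    } else rep(0, length(ids))
    out[[r$patient_id]] <- data.frame(
      patient_id = r$patient_id, sample_id = ids,
      phase = meta$phase[match(ids, meta$sample_id)], value = unname(vals),
      stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, out)
  rownames(samples) <- NULL
  qs <- do.call(rbind, lapply(split(samples$value, factor(samples$phase, AZT_PHASES)),
                              function(v) {
    if (length(v) == 0L) return(data.frame(n = 0L, q1 = NA_real_, median = NA_real_, q3 = NA_real_))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), q1 = q[1], median = q[2], q3 = q[3])
  }))
  summary <- cbind(phase = rownames(qs), qs)
  rownames(summary) <- NULL
  list(samples = samples, summary = summary)
}

#' Paired test on per-patient turnover category counts
#'
#' Compares, across patients, two per-patient ASV counts derived from
#' turnover classification with the paired Wilcoxon signed-rank test:
#' `"start_vs_end"` = total present at window start vs at window end,
#' `"acquired_vs_retained"`, and `"acquired_vs_cleared"`.
#'
#' @param results list of [classify_turnover()] results (one per patient),
#'   e.g. from [turnover_by_patient()]; >= 5 patients recommended.
#' @param contrast which category counts to compare.
#' @return list with the per-patient count data.frame (`counts`) and the
#'   [wilcoxon_paired()] output (`test`).
#' @export
turnover_balance_test <- function(results,
                                  contrast = c("start_vs_end",
                                               "acquired_vs_retained",
                                               "acquired_vs_cleared")) {
  contrast <- match.arg(contrast)
  if (length(results) == 0L) stop_aztair("no turnover results supplied")
  cnt <- do.call(rbind, lapply(results, function(r) {
    data.frame(patient_id = r$patient_id,
               retained = length(r$retained),
               cleared = length(r$cleared),
               acquired = length(r$acquired),
               stringsAsFactors = FALSE)
  }))
  cnt$start_total <- cnt$retained + cnt$cleared
  cnt$end_total <- cnt$retained + cnt$acquired
  xy <- switch(contrast,
    start_vs_end = list(cnt$start_total, cnt$end_total),
    acquired_vs_retained = list(cnt$acquired, cnt$retained),
    acquired_vs_cleared = list(cnt$acquired, cnt$cleared))
  rownames(cnt) <- NULL
  list(counts = cnt, contrast = contrast,
       test = wilcoxon_paired(xy[[1]], xy[[2]]))
}
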