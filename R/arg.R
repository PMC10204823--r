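# Antibiotic-resistance-gene (ARG) carriage scoring from qPCR copy numbers:
# 16S normalisation, per-gene 0-1 scaling, cumulative score, and
# stable-vs-increased patient stratification.

#' Validate an ARG qPCR panel
#'
#' Required columns: `sample_id`, `copies_16s` (> 0) and one non-negative
#' column per panel gene (default the seven-gene macrolide/tetracycline
#' panel, [ARG_GENES]).
#'
#' @param panel data.frame.
#' @param genes panel gene column names.
#' @return the validated data.frame, invisibly.
#' @export
validate_arg_panel <- function(panel, genes = ARG_GENES) {
  need <- c("sample_id", "copies_16s", genes)
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols))
    stop_aztair("ARG panel missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(panel$sample_id)) stop_aztair("duplicate sample_id in ARG panel")
  if (any(!is.finite(panel$copies_16s) | panel$copies_16s <= 0))
    stop_aztair("copies_16s must be positive")
  for (g in genes)
    if (any(!is.finite(panel[[g]]) | panel[[g]] < 0))
      stop_aztair("gene ", g, " has negative or non-finite copies")
  invisible(panel)
}

#' Read an ARG qPCR panel from TSV
#' @param path file path.
#' @param genes panel gene column names (default [ARG_GENES]).
#' @return validated data.frame.
#' @export
read_arg_panel <- function(path, genes = ARG_GENES) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  panel$sample_id <- as.character(panel$sample_id)
  validate_arg_panel(panel, genes)
  panel
}

#' Normalise ARG copy numbers to 16S copies
#'
#' `value_g = copies_g / copies_16s` per gene — resistance-gene burden per
#' 16S rRNA gene copy, invariant to the absolute amount of template.
#'
#' @param panel validated ARG panel (see [validate_arg_panel()]).
#' @param genes panel gene column names.
#' @return data.frame: sample_id plus one normalised column per gene.
#' @export
normalize_arg <- function(panel, genes = ARG_GENES) {
  validate_arg_panel(panel, genes)
  out <- data.frame(sample_id = panel$sample_id, stringsAsFactors = FALSE)
  for (g in genes) out[[g]] <- panel[[g]] / panel$copies_16s
  out
}

#' Cumulative ARG carriage score
#'
#' Per gene, the 16S-normalised values are min-max scaled to `[0, 1]`
#' across all samples in the analysis set, giving each gene equal weight;
#' genes with zero range contribute 0 everywhere. The cumulative score is
#' the sum of the scaled values (bounded by the panel size).
#'
#' @param panel validated ARG panel; >= 2 samples (scaling needs a range).
#' @param genes panel gene column names.
#' @return list with `normalized` (per-gene ratios), `scaled` (per-gene
#'   values in `[0, 1]`) and `cumulative` (data.frame: sample_id, score).
#' @export
cumulative_arg_score <- function(panel, genes = ARG_GENES) {
  validate_arg_panel(panel, genes)
  if (nrow(panel) < 2L)
    stop_aztair("min-max scaling needs >= 2 samples; use normalize_arg() for raw ratios")
  norm <- normalize_arg(panel, genes)
  scaled <- norm
  for (g in genes) {
    v <- norm[[g]]
    rng <- range(v)
    scaled[[g]] <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0, length(v))
  }
  cumulative <- data.frame(sample_id = panel$sample_id,
                           score = rowSums(scaled[, genes, drop = FALSE]),
                           stringsAsFactors = FALSE)
  list(normalized = norm, scaled = scaled, cumulative = cumulative)
}

#' Stratify patients by change in cumulative ARG carriage
#'
#' For patients with sputum samples at both the start and end of treatment,
#' the fold change of the cumulative ARG score (EndAZT / StartAZT) is
#' computed; patients above the cohort median fold change are labelled
#' `"increased"`, the rest (at or below the median) `"stable"`. Scores of 0
#' at either endpoint are handled by adding the smallest positive cumulative
#' score in the cohort as a pseudocount to both terms; `mode =
#' "difference"` uses End - Start instead of a ratio.
#'
#' @param scores result of [cumulative_arg_score()] (or its `cumulative`
#'   data.frame).
#' @param meta sample metadata (see [validate_metadata()]); only LRT
#'   samples at `"StartAZT"` and `"EndAZT"` are used.
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return data.frame of class `"aztair_strata"`: patient_id, score_start,
#'   score_end, fold_change, stratum; attribute `"median_change"` records
#'   the cohort median.
#' @export
stratify_resistance <- function(scores, meta, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  if (is.list(scores) && !is.data.frame(scores)) scores <- scores$cumulative
  if (!all(c("sample_id", "score") %in% names(scores)))
    stop_aztair("scores must have columns sample_id, score")
  validate_metadata(meta)
  m <- meta[meta$site == "LRT" & meta$phase %in% c("StartAZT", "EndAZT"), ]
  m <- merge(m, scores, by = "sample_id")
  wide <- merge(
    stats::setNames(m[m$phase == "StartAZT", c("patient_id", "score")],
                    c("patient_id", "score_start")),
    stats::setNames(m[m$phase == "EndAZT", c("patient_id", "score")],
                    c("patient_id", "score_end")),
    by = "patient_id")
  if (nrow(wide) == 0L)
    stop_aztair("no patient has sputum scores at both StartAZT and EndAZT")
  if (mode == "ratio") {
    pos <- c(wide$score_start, wide$score_end)
    pos <- pos[pos > 0]
    pseudo <- if (any(wide$score_start == 0 | wide$score_end == 0) && length(pos))
      min(pos) else 0
    wide$fold_change <- (wide$score_end + pseudo) / (wide$score_start + pseudo)
  } else {
    wide$fold_change <- wide$score_end - wide$score_start
  }
  med <- stats::median(wide$fold_change)
  wide$stratum <- ifelse(wide$fold_change > med, "increased", "stable")
  if (all(wide$stratum == "stable"))
    warning("all fold changes at or below the median; every patient labelled 'stable'")
  wide <- wide[order(wide$patient_id), ]
  rownames(wide) <- NULL
  structure(wide, median_change = med, mode = mode, class = c("aztair_strata", "data.frame"))
}
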