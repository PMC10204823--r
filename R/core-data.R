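# Core data objects: ASV feature tables, sample metadata, phylogenies and
# taxonomy maps, with the TSV/newick I/O used by every downstream stage.
#
# Conventions: a feature table is a plain integer matrix, samples in rows,
# ASVs in columns, with unique dimnames (the community-matrix convention of
# vegan). Metadata is a data.frame keyed by sample_id. Trees are ape "phylo"
# objects. Taxonomy is a named character vector asv_id -> genus.

#' Treatment phases of the study design
#'
#' The five-phase longitudinal design around an azithromycin course:
#' before treatment, at treatment start, at treatment end, one month after,
#' and three or more months after.
#'
#' @format Character vector of length 5.
#' @export
AZT_PHASES <- c("PreAZT", "StartAZT", "EndAZT", "PostAZT_1mo", "PostAZT_ge3mo")

#' Sampling sites
#'
#' `"LRT"` = lower respiratory tract (sputum); `"URT"` = upper respiratory
#' tract (oropharyngeal swab, OPS).
#'
#' @format Character vector of length 2.
#' @export
AZT_SITES <- c("LRT", "URT")

#' Antibiotic resistance gene panel
#'
#' The seven-gene macrolide/tetracycline resistance panel assayed by qPCR:
#' erm(B), erm(F), mel, msr(E), mef, tet(M), tet(W). Column names use
#' alphanumeric forms of the gene symbols.
#'
#' @format Character vector of length 7.
#' @export
ARG_GENES <- c("ermB", "ermF", "mel", "msrE", "mef", "tetM", "tetW")

#' Validate an ASV feature table
#'
#' Checks the invariants every stage relies on: a numeric matrix of
#' non-negative integers with unique sample (row) and ASV (column) names.
#'
#' @param counts matrix, samples x ASVs.
#' @return the validated matrix, invisibly (integer storage).
#' @export
validate_feature_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_aztair("feature table must be a numeric matrix (samples x ASVs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_aztair("feature table must have sample (row) and ASV (column) names")
  if (anyDuplicated(rownames(counts)))
    stop_aztair("duplicate sample ids: ",
                paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_aztair("duplicate ASV ids: ",
                paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_aztair(sprintf(
      "non-negative integer counts required; offending cell: sample '%s', ASV '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, 1], bad[1, 2]])))
  }
  storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Read an ASV feature table from TSV
#'
#' Expects a tab-separated file with sample ids in the first column and one
#' column per ASV; cells are integer read counts.
#'
#' @param path file path.
#' @return validated integer matrix, samples x ASVs, in file order.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_aztair("feature table needs a sample-id column and >= 1 ASV column")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_aztair("non-numeric cell in feature table")
  rownames(m) <- ids
  validate_feature_table(m)
  storage.mode(m) <- "integer"
  m
}

#' Write an ASV feature table to TSV
#'
#' Emits the same dialect `read_feature_table()` consumes, so tables
#' round-trip losslessly.
#'
#' @param counts validated feature table.
#' @param path file path.
#' @export
write_feature_table <- function(counts, path) {
  validate_feature_table(counts)
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate sample metadata
#'
#' Required columns: `sample_id`, `patient_id`, `site` (one of [AZT_SITES]),
#' `phase` (one of [AZT_PHASES]) and `time_months` (signed months relative to
#' azithromycin start). `sample_id` must be unique and, where `counts` is
#' supplied, cover every sample of the feature table; `(patient_id, site,
#' phase)` may identify at most one sample.
#'
#' @param meta data.frame.
#' @param counts optional feature table to check coverage against.
#' @return the validated data.frame, invisibly.
#' @export
validate_metadata <- function(meta, counts = NULL) {
  need <- c("sample_id", "patient_id", "site", "phase", "time_months")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop_aztair("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop_aztair("duplicate sample_id in metadata: ",
                paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  bad_site <- setdiff(unique(meta$site), AZT_SITES)
  if (length(bad_site))
    stop_aztair("unknown site token(s): ", paste(bad_site, collapse = ", "),
                "; allowed: ", paste(AZT_SITES, collapse = ", "))
  bad_phase <- setdiff(unique(meta$phase), AZT_PHASES)
  if (length(bad_phase))
    stop_aztair("unknown phase token(s): ", paste(bad_phase, collapse = ", "),
                "; allowed: ", paste(AZT_PHASES, collapse = ", "))
  if (!is.numeric(meta$time_months))
    stop_aztair("time_months must be numeric")
  key <- interaction(meta$patient_id, meta$site, meta$phase, drop = TRUE)
  if (anyDuplicated(key))
    stop_aztair("(patient_id, site, phase) identifies more than one sample: ",
                paste(unique(as.character(key)[duplicated(key)]), collapse = ", "))
  if (!is.null(counts)) {
    uncovered <- setdiff(rownames(counts), meta$sample_id)
    if (length(uncovered))
      stop_aztair("feature-table sample(s) missing from metadata: ",
                  paste(uncovered, collapse = ", "))
  }
  invisible(meta)
}

#' Read sample metadata from TSV
#'
#' @param path file path to a TSV with the columns listed in
#'   [validate_metadata()].
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  meta$patient_id <- as.character(meta$patient_id)
  validate_metadata(meta)
  meta
}

#' Write sample metadata to TSV
#' @param meta validated metadata data.frame.
#' @param path file path.
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from newick
#'
#' Wraps [ape::read.tree()] with the validation downstream phylogenetic
#' metrics need: a single rooted tree whose tip labels cover the ASVs in use.
#' Edges without branch lengths are set to 0 with a warning; the tree must
#' retain positive total length.
#'
#' @param path newick file path.
#' @param asv_ids optional character vector of ASV ids that must be tip
#'   labels. Extra tips are allowed (pruned on demand downstream); with
#'   `strict = TRUE` they raise an error instead of a warning.
#' @param strict error (rather than warn) on tips absent from `asv_ids`.
#' @return an [ape::read.tree()] "phylo" object.
#' @export
read_tree <- function(path, asv_ids = NULL, strict = FALSE) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop_aztair("newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop_aztair("newick parse error: no tree found in ", path)
  if (inherits(tree, "multiPhylo")) stop_aztair("expected a single tree, found several")
  if (!ape::is.rooted(tree)) stop_aztair("tree must be rooted")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop_aztair("negative branch lengths are not allowed")
  if (sum(tree$edge.length) <= 0) stop_aztair("tree must have positive total length")
  if (!is.null(asv_ids)) {
    absent <- setdiff(asv_ids, tree$tip.label)
    if (length(absent))
      stop_aztair("ASV(s) missing from tree: ", paste(absent, collapse = ", "))
    extra <- setdiff(tree$tip.label, asv_ids)
    if (length(extra)) {
      msg <- paste0("tree has ", length(extra), " tip(s) unused by the table")
      if (strict) stop_aztair(msg) else warning(msg, "; they will be pruned on demand")
    }
  }
  tree
}

#' Read a taxonomy map (ASV -> genus) from TSV
#'
#' Two columns: `asv_id`, `genus`. ASVs without an assignment may carry the
#' sentinel label (see `sentinel`).
#'
#' @param path file path.
#' @param sentinel label to substitute for empty/NA genus entries.
#' @return named character vector, names = ASV ids.
#' @export
read_taxonomy <- function(path, sentinel = "Unclassified") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("asv_id", "genus") %in% names(df)))
    stop_aztair("taxonomy file needs columns asv_id, genus")
  if (anyDuplicated(df$asv_id))
    stop_aztair("duplicate asv_id in taxonomy map")
  genus <- as.character(df$genus)
  genus[is.na(genus) | genus == ""] <- sentinel
  stats::setNames(genus, as.character(df$asv_id))
}

#' Write a taxonomy map to TSV
#' @param tax named character vector (names = ASV ids, values = genus).
#' @param path file path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(
    data.frame(asv_id = names(tax), genus = unname(tax), stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
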