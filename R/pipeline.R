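# End-to-end pipeline: chains the analysis stages over input files or a
# simulated cohort, writing TSV outputs and a run manifest. This is the
# programmatic face of the command-line wrapper in
# `system.file("scripts", "aztair-pipeline.R", package = "aztair")`.

write_tsv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

dist_to_df <- function(dm) {
  M <- as.matrix(dm)
  data.frame(sample_id = rownames(M), M, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Inputs may be given as file paths (`counts_path`, `meta_path`,
#' `tree_path`, `taxonomy_path`, `arg_path`) or the cohort can be simulated
#' (`simulate = TRUE`, the default when no paths are given). Defaults match
#' the study parameters: rarefaction depth 10 055, 999 permutations, core
#' thresholds 0.1% / 50%, 15 genera for DPCoA, the seven-gene ARG panel.
#'
#' @param counts_path,meta_path,tree_path,taxonomy_path,arg_path input file
#'   paths (TSV / newick), or `NULL` to simulate.
#' @param simulate generate a synthetic cohort instead of reading inputs.
#' @param cohort overrides for [cohort_config()] (list), used when
#'   simulating.
#' @param depth rarefaction depth.
#' @param n_perm PERMANOVA permutations.
#' @param k_genera genera retained in DPCoA.
#' @param core_abundance,core_prevalence core-community thresholds.
#' @param seed integer seed controlling simulation, rarefaction and
#'   permutations.
#' @return list of class `"aztair_run_config"`.
#' @export
pipeline_config <- function(counts_path = NULL, meta_path = NULL,
                            tree_path = NULL, taxonomy_path = NULL,
                            arg_path = NULL,
                            simulate = is.null(counts_path),
                            cohort = list(),
                            depth = 10055, n_perm = 999, k_genera = 15,
                            core_abundance = 0.001, core_prevalence = 0.5,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (!simulate) {
    for (p in c("counts_path", "meta_path", "tree_path", "taxonomy_path")) {
      if (is.null(cfg[[p]])) stop_aztair("missing input path: ", p)
      if (!file.exists(cfg[[p]])) stop_aztair("input does not exist: ", cfg[[p]])
    }
    if (!is.null(arg_path) && !file.exists(arg_path))
      stop_aztair("input does not exist: ", arg_path)
  }
  structure(cfg, class = "aztair_run_config")
}

# Mean patristic distance between the ASVs of each genus pair; a genus-level
# distance matrix suitable for DPCoA.
genus_patristic <- function(tree, taxonomy) {
  coph <- ape::cophenetic.phylo(tree)
  genera <- sort(unique(taxonomy[rownames(coph)]))
  D <- matrix(0, length(genera), length(genera), dimnames = list(genera, genera))
  members <- split(rownames(coph), taxonomy[rownames(coph)])
  for (i in seq_along(genera)) {
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- mean(coph[members[[genera[i]]], members[[genera[j]]]])
    }
  }
  D
}

#' Run the analysis pipeline
#'
#' Executes one stage (or `"all"`) over the configured inputs, writing TSV
#' outputs plus a YAML manifest (seeds, parameters, package version) into
#' `out_dir`. Stages: `simulate` (emit the synthetic cohort files), `alpha`
#' (rarefied alpha diversity + group tests), `beta` (UniFrac matrices, PCoA,
#' PERMANOVA per site, OPS-to-sputum-centroid distances, DPCoA), `turnover`
#' (per-patient turnover, site overlap + chi-squared, tracked abundances,
#' balance tests), `arg` (ARG scores and patient strata).
#'
#' @param stage one of `"all"`, `"simulate"`, `"alpha"`, `"beta"`,
#'   `"turnover"`, `"arg"`.
#' @param out_dir output directory (created if needed).
#' @param config an [pipeline_config()] object.
#' @return invisibly, the list of written file paths.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "alpha", "beta", "turnover", "arg"),
                         out_dir, config = pipeline_config()) {
  stage <- match.arg(stage)
  if (!inherits(config, "aztair_run_config"))
    stop_aztair("config must come from pipeline_config()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_atomic(df, path)
    written <<- c(written, path)
    path
  }

  arg_panel <- NULL
  if (config$simulate) {
    cc <- do.call(cohort_config, utils::modifyList(list(seed = config$seed),
                                                   config$cohort))
    cohort <- simulate_cohort(cc)
    counts <- cohort$counts; meta <- cohort$meta; tree <- cohort$tree
    taxonomy <- cohort$taxonomy; arg_panel <- cohort$arg
    if (stage %in% c("simulate", "all")) {
      emit(data.frame(sample_id = rownames(counts), counts, check.names = FALSE),
           "simulated_counts.tsv")
      emit(meta, "simulated_metadata.tsv")
      emit(data.frame(asv_id = names(taxonomy), genus = unname(taxonomy)),
           "simulated_taxonomy.tsv")
      emit(arg_panel, "simulated_arg_panel.tsv")
      tree_path <- file.path(out_dir, "simulated_tree.nwk")
      ape::write.tree(tree, tree_path)
      written <- c(written, tree_path)
    }
  } else {
    counts <- read_feature_table(config$counts_path)
    meta <- read_metadata(config$meta_path)
    taxonomy <- read_taxonomy(config$taxonomy_path)
    tree <- read_tree(config$tree_path, asv_ids = colnames(counts))
    if (!is.null(config$arg_path)) arg_panel <- read_arg_panel(config$arg_path)
  }
  validate_metadata(meta, counts)

  if (stage != "simulate") {
    rar <- rarefy(counts, config$depth, seed = derive_seed(config$seed, 11))
    meta_r <- meta[meta$sample_id %in% rownames(rar), ]
  }

  if (stage %in% c("alpha", "all")) {
    alpha <- alpha_diversity(rar, tree = tree, meta = meta_r)
    emit(alpha, "alpha_diversity.tsv")
    tests <- list()
    for (site in AZT_SITES) {
      for (metric in unique(alpha$metric)) {
        sub <- alpha[alpha$site == site & alpha$metric == metric, ]
        if (length(unique(sub$phase)) < 2 || min(table(sub$phase)) < 2) next
        gt <- compare_groups(sub$value, sub$phase)
        tests[[paste(site, metric)]] <- cbind(
          site = site, metric = metric, kw_statistic = gt$statistic,
          kw_p = gt$p_value, gt$pairwise)
      }
    }
    emit(do.call(rbind, tests), "alpha_group_tests.tsv")
    dom <- core_community_dominance(rar, config$core_abundance, config$core_prevalence)
    emit(data.frame(sample_id = names(dom), dominance = unname(dom)),
         "core_dominance.tsv")
  }

  if (stage %in% c("beta", "all")) {
    perm_rows <- list()
    for (metric in c("unweighted_unifrac", "weighted_unifrac")) {
      dm <- distance_matrix(rar, tree, metric)
      emit(dist_to_df(dm), paste0(metric, "_distances.tsv"))
      if (metric == "unweighted_unifrac") {
        emb <- pcoa(dm)
        emit(data.frame(sample_id = rownames(emb$coordinates),
                        emb$coordinates[, seq_len(min(4, ncol(emb$coordinates))),
                                        drop = FALSE], check.names = FALSE),
             "pcoa_coordinates.tsv")
        cen <- ops_centroid_distances(dm, meta_r)
        if (!is.null(cen)) emit(cen, "ops_centroid_distances.tsv")
      }
      for (site in AZT_SITES) {
        ids <- meta_r$sample_id[meta_r$site == site]
        ids <- intersect(labels(dm), ids)
        ph <- meta_r$phase[match(ids, meta_r$sample_id)]
        if (length(unique(ph)) < 2 || min(table(ph)) < 2) next
        sub <- as.matrix(dm)[ids, ids]
        pr <- permanova(sub, ph, n_perm = config$n_perm,
                        seed = derive_seed(config$seed, 23))
        perm_rows[[paste(metric, site)]] <- data.frame(
          metric = metric, site = site, f = pr$f, r2 = pr$r2,
          p_value = pr$p_value, n_perm = pr$n_perm,
          seed = derive_seed(config$seed, 23))
      }
    }
    emit(do.call(rbind, perm_rows), "permanova.tsv")
    genus_tab <- collapse_to_genus(rar, taxonomy)
    gd <- genus_patristic(tree, taxonomy)
    k <- min(config$k_genera, ncol(genus_tab))
    dp <- dpcoa(genus_tab, gd, k = k)
    emit(data.frame(sample_id = rownames(dp$sample_coordinates),
                    dp$sample_coordinates[, seq_len(min(2, ncol(dp$sample_coordinates))),
                                          drop = FALSE], check.names = FALSE),
         "dpcoa_samples.tsv")
    emit(data.frame(genus = rownames(dp$genus_coordinates),
                    dp$genus_coordinates[, seq_len(min(2, ncol(dp$genus_coordinates))),
                                         drop = FALSE], check.names = FALSE),
         "dpcoa_genera.tsv")
  }

  if (stage %in% c("turnover", "all")) {
    long <- list(); cnt <- list(); venn <- list(); track <- list()
    windows <- list(treatment = c("StartAZT", "EndAZT"),
                    no_treatment = c("PreAZT", "StartAZT"),
                    post = c("EndAZT", "PostAZT_1mo"))
    for (site in AZT_SITES) {
      for (wname in names(windows)) {
        wnd <- windows[[wname]]
        res <- turnover_by_patient(rar, meta_r, site, wnd[1], wnd[2])
        if (length(res) == 0) next
        for (r in res) {
          for (catg in c("retained", "cleared", "acquired")) {
            if (length(r[[catg]]) == 0) next
            long[[length(long) + 1L]] <- data.frame(
              patient_id = r$patient_id, site = site, window = wname,
              category = catg, asv_id = r[[catg]], stringsAsFactors = FALSE)
          }
        }
        bt <- turnover_balance_test(res, "start_vs_end")
        cnt[[paste(site, wname)]] <- cbind(site = site, window = wname,
                                           bt$counts)
        if (wname == "treatment" && site == "LRT") {
          # kinetics of each patient's own LRT-cleared/acquired taxa, at
          # both sites
          for (tr_site in AZT_SITES) {
            for (setn in c("cleared", "acquired")) {
              ta <- tracked_turnover_abundance(rar, meta_r, res, setn, tr_site)
              track[[paste(tr_site, setn)]] <- cbind(site = tr_site,
                                                     asv_set = setn, ta$summary)
            }
          }
        }
      }
    }
    for (phase in intersect(AZT_PHASES, unique(meta_r$phase))) {
      ov <- tryCatch(site_overlap(rar, meta_r, phase), error = function(e) NULL)
      if (is.null(ov)) next
      gof <- chisq_gof(ov$counts)
      venn[[phase]] <- data.frame(phase = phase, t(ov$counts),
                                  chisq = gof$statistic, p_value = gof$p_value)
    }
    emit(do.call(rbind, long), "turnover_long.tsv")
    emit(do.call(rbind, cnt), "turnover_counts.tsv")
    emit(do.call(rbind, venn), "site_overlap.tsv")
    emit(do.call(rbind, track), "tracked_abundance.tsv")
  }

  if (stage %in% c("arg", "all")) {
    if (is.null(arg_panel)) {
      message("no ARG panel supplied; skipping arg stage")
    } else {
      sc <- cumulative_arg_score(arg_panel)
      emit(sc$cumulative, "arg_cumulative.tsv")
      emit(sc$scaled, "arg_scaled.tsv")
      strata <- stratify_resistance(sc, meta)
      emit(as.data.frame(strata), "arg_strata.tsv")
    }
  }

  manifest <- list(
    package = "aztair",
    version = as.character(utils::packageVersion("aztair")),
    stage = stage, seed = config$seed,
    depth = config$depth, n_perm = config$n_perm,
    k_genera = config$k_genera,
    core_abundance = config$core_abundance,
    core_prevalence = config$core_prevalence,
    simulated = config$simulate,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outputs = basename(written))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(c(written, file.path(out_dir, "manifest.yaml")))
}
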