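# Synthetic cohort generator: Dirichlet-multinomial communities over a
# simulated ASV phylogeny, with a five-phase paired-site longitudinal design,
# planted treatment effects (clearance, suppressed acquisition, genus
# enrichment), and a qPCR ARG panel with a planted resistance subgroup.
# Ground truth for every planted effect is recorded so recovery can be
# tested against it.

AIRWAY_GENERA <- c(
  "Streptococcus", "Prevotella_7", "Veillonella", "Haemophilus", "Neisseria",
  "Fusobacterium", "Rothia", "Actinomyces", "Gemella", "Granulicatella",
  "Porphyromonas", "Leptotrichia", "Capnocytophaga", "Campylobacter",
  "Selenomonas", "Megasphaera", "Oribacterium", "Solobacterium",
  "Atopobium", "Lachnoanaerobaculum", "Alloprevotella", "Bergeyella",
  "Tannerella", "Treponema_2", "Fretibacterium", "Pseudopropionibacterium",
  "Lactobacillus", "Moraxella", "Staphylococcus", "Mycoplasma")

PHASE_TIMES <- c(PreAZT = -4, StartAZT = 0, EndAZT = 3,
                 PostAZT_1mo = 4, PostAZT_ge3mo = 6)

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the shape of a 24-patient, paired-site, five-phase
#' crossover cohort: pre-treatment specimens available only for the
#' placebo-first half, lower richness in the URT than the LRT, a rarefaction
#' depth of 10 055 reads, treatment-induced clearance of low-abundance taxa
#' (stronger in the LRT) with suppressed acquisition during treatment and an
#' acquisition burst afterwards, mutually exclusive Streptococcus/
#' Prevotella_7 enrichment tied to the planted resistance stratum, a ~4-fold
#' cumulative ARG increase at treatment end in the "increased" half of the
#' cohort, and lower bacterial density in that subgroup.
#'
#' @param n_patients number of patients (>= 2; default 24).
#' @param n_asvs number of ASVs in the pool (default 300).
#' @param depth rarefaction depth the cohort is built around (default 10055).
#' @param clearance_fraction fraction of a patient's start-of-treatment taxa
#'   cleared by treatment in the LRT (default 0.2).
#' @param urt_clearance_factor multiplier on `clearance_fraction` for the
#'   URT (default 0.6; the treatment effect is weaker in the upper airway).
#' @param natural_turnover fraction of taxa replaced per untreated ~3-month
#'   window (default 0.4, giving retained fractions near 0.4-0.45 of the
#'   window's ASV union).
#' @param treated_acquisition fraction of start richness acquired during
#'   treatment (default 0.05; acquisition is suppressed under treatment).
#' @param post_burst_acquisition acquisition fraction in the month after
#'   treatment (default 0.15; turnover resumes but richness stays below
#'   baseline).
#' @param post_clearance clearance fraction in the month after treatment
#'   (default 0.05).
#' @param late_turnover symmetric turnover between the two post-treatment
#'   phases (default 0.2).
#' @param enrichment_factor multiplier applied to the patient's designated
#'   genus at treatment end, decaying afterwards (default 3).
#' @param resistance_increase_fraction fraction of patients in the
#'   "increased" ARG stratum (default 0.5).
#' @param arg_fold_increase cumulative ARG fold change planted at EndAZT in
#'   the increased stratum (default 4).
#' @param dm_concentration Dirichlet concentration of per-sample
#'   compositions around the patient mean (default 500).
#' @param floor_weight weight of the uniform floor mixed into each expected
#'   composition so every present taxon stays detectable at the rarefaction
#'   depth (default 0.3).
#' @param richness_lrt,richness_urt per-patient baseline richness by site
#'   (defaults 110 / 80).
#' @param depth_factor_range sequencing depth per sample, as multiples of
#'   `depth` (default c(1.3, 2)).
#' @param shallow_fraction fraction of URT samples deliberately sequenced
#'   below the rarefaction depth (default 0.1), emulating swab specimens
#'   that fail the read threshold.
#' @param shallow_depth_factor depth multiplier for shallow samples
#'   (default 0.6).
#' @param density_meanlog named log-scale means of 16S copies per uL for the
#'   two strata (defaults: stable 4e5, increased 8e4).
#' @param density_sdlog between-patient log-sd of density (default 0.8).
#' @param arg_baseline_meanlog,arg_baseline_sdlog log-scale location/spread
#'   of baseline per-gene ratios (ARG copies per 16S copy).
#' @param seed integer seed; all generation is deterministic given it.
#' @return validated list of class `"aztair_cohort_config"`.
#' @export
cohort_config <- function(n_patients = 24, n_asvs = 300, depth = 10055,
                          clearance_fraction = 0.2, urt_clearance_factor = 0.6,
                          natural_turnover = 0.4, treated_acquisition = 0.05,
                          post_burst_acquisition = 0.15, post_clearance = 0.05,
                          late_turnover = 0.2, enrichment_factor = 3,
                          resistance_increase_fraction = 0.5,
                          arg_fold_increase = 4,
                          dm_concentration = 500, floor_weight = 0.3,
                          richness_lrt = 110, richness_urt = 80,
                          depth_factor_range = c(1.3, 2),
                          shallow_fraction = 0.1, shallow_depth_factor = 0.6,
                          density_meanlog = c(stable = log(4e5), increased = log(8e4)),
                          density_sdlog = 0.8,
                          arg_baseline_meanlog = log(2e-4), arg_baseline_sdlog = 1,
                          seed = NULL) {
  cfg <- as.list(environment())
  fracs <- c("clearance_fraction", "urt_clearance_factor", "natural_turnover",
             "treated_acquisition", "post_burst_acquisition", "post_clearance",
             "late_turnover", "resistance_increase_fraction",
             "shallow_fraction", "floor_weight")
  for (f in fracs)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_aztair(f, " must be in [0, 1]")
  if (n_patients < 2) stop_aztair("n_patients must be >= 2")
  if (n_asvs < 2) stop_aztair("n_asvs must be >= 2")
  if (depth < 100) stop_aztair("depth must be >= 100")
  if (richness_lrt + richness_urt > n_asvs)
    stop_aztair("per-patient richness exceeds the ASV pool")
  if (!all(c("stable", "increased") %in% names(density_meanlog)))
    stop_aztair("density_meanlog needs named entries 'stable' and 'increased'")
  structure(cfg, class = "aztair_cohort_config")
}

#' Null-cohort configuration
#'
#' A no-effect counterpart of [cohort_config()]: no planted clearance,
#' acquisition change, genus enrichment, ARG increase or density
#' difference, and no turnover of any kind, so every phase is an exchangeable
#' redraw of the same per-patient community. Used to check that the
#' pipeline's tests reject at close to their nominal level.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [cohort_config()].
#' @return `"aztair_cohort_config"` object.
#' @export
null_cohort_config <- function(seed = NULL, ...) {
  cohort_config(clearance_fraction = 0, urt_clearance_factor = 1,
                natural_turnover = 0, treated_acquisition = 0,
                post_burst_acquisition = 0, post_clearance = 0,
                late_turnover = 0, enrichment_factor = 1,
                arg_fold_increase = 1,
                density_meanlog = c(stable = log(2e5), increased = log(2e5)),
                seed = seed, ...)
}

#' Simulate a rooted ASV phylogeny
#'
#' Random rooted bifurcating topology ([ape::rtree()]) with exponential
#' branch lengths, tips labelled `ASV_1..n`; deterministic under `seed`.
#'
#' @param n_asvs number of tips (>= 2).
#' @param seed integer seed.
#' @return rooted "phylo" object.
#' @export
simulate_tree <- function(n_asvs, seed = NULL) {
  if (n_asvs < 2) stop_aztair("n_asvs must be >= 2")
  with_seed(seed, {
    tree <- ape::rtree(n_asvs, br = function(k) stats::rexp(k, rate = 10))
    tree$tip.label <- paste0("ASV_", seq_len(n_asvs))
    tree
  })
}

# Replace `k_out` random members of `support` (uniformly) with `k_in` taxa
# drawn from `pool`; returns list(support, cleared, acquired).
shift_support <- function(support, pool, k_out, k_in, w = NULL, low_bias = FALSE) {
  k_out <- min(k_out, length(support))
  cleared <- if (k_out > 0) {
    if (low_bias && !is.null(w)) {
      ranked <- support[order(w[support])]                # low abundance first
      candidates <- ranked[seq_len(max(k_out, ceiling(0.75 * length(ranked))))]
      sample(candidates, k_out)
    } else sample(support, k_out)
  } else character(0)
  pool <- setdiff(pool, support)
  k_in <- min(k_in, length(pool))
  acquired <- if (k_in > 0) sample(pool, k_in) else character(0)
  list(support = c(setdiff(support, cleared), acquired),
       cleared = cleared, acquired = acquired)
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Generates the complete data bundle the pipeline consumes — ASV count
#' table, sample metadata, rooted phylogeny, taxonomy map and ARG qPCR
#' panel — plus the `truth` record of every planted effect. See
#' [cohort_config()] for what is emulated.
#'
#' Per patient, a baseline community (a patient-specific reweighting of a
#' shared skewed genus structure) persists across phases; phase-to-phase
#' presence changes follow the configured turnover and treatment rules, and
#' clearance is applied to the expected composition itself, so cleared taxa
#' have exactly zero reads at treatment end. Per-sample compositions are
#' Dirichlet draws around the patient's phase composition, and reads are
#' multinomial at the sample's sequencing depth.
#'
#' @param config an [cohort_config()] object.
#' @return list of class `"aztair_cohort"`: `counts` (samples x ASVs),
#'   `meta`, `tree`, `taxonomy`, `arg` (qPCR panel for LRT samples), `truth`
#'   (per-patient strata, per-site cleared/acquired sets, per-sample expected
#'   composition and density), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "aztair_cohort_config"))
    stop_aztair("config must come from cohort_config()")
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_patients
    asv_ids <- paste0("ASV_", seq_len(cfg$n_asvs))
    tree <- ape::rtree(cfg$n_asvs, br = function(k) stats::rexp(k, rate = 10))
    tree$tip.label <- asv_ids

    # skewed genus structure; the two narrative genera get the top weights
    genera <- AIRWAY_GENERA
    gw <- 1 / seq_along(genera)
    names(gw) <- c(genera[1:2], sample(genera[-(1:2)]))
    taxonomy <- stats::setNames(
      sample(names(gw), cfg$n_asvs, replace = TRUE, prob = gw), asv_ids)
    for (g in c("Streptococcus", "Prevotella_7"))   # guarantee both exist
      if (!g %in% taxonomy) taxonomy[sample(cfg$n_asvs, 1)] <- g

    asv_w_global <- gw[taxonomy] * stats::rlnorm(cfg$n_asvs, 0, 1)
    names(asv_w_global) <- asv_ids

    pids <- sprintf("P%02d", seq_len(n))
    placebo_first <- seq_len(n) <= ceiling(n / 2)
    n_inc <- round(cfg$resistance_increase_fraction * n)
    stratum <- rep("stable", n)
    if (n_inc > 0) stratum[sample(n, n_inc)] <- "increased"
    enriched <- ifelse(stratum == "increased", "Streptococcus", "Prevotella_7")
    patients <- data.frame(patient_id = pids, placebo_first = placebo_first,
                           stratum = stratum, enriched_genus = enriched,
                           stringsAsFactors = FALSE)

    rows <- list(); meta_rows <- list(); comp_rows <- list()
    truth_cleared <- list(); truth_acquired <- list()
    arg_rows <- list(); density <- c()
    enrich_mult <- c(PreAZT = 1, StartAZT = 1, EndAZT = cfg$enrichment_factor,
                     PostAZT_1mo = 1 + (cfg$enrichment_factor - 1) / 2,
                     PostAZT_ge3mo = 1 + (cfg$enrichment_factor - 1) / 4)

    for (i in seq_len(n)) {
      pid <- pids[i]
      w <- asv_w_global * stats::rlnorm(cfg$n_asvs, 0, 0.6)
      names(w) <- asv_ids
      truth_cleared[[pid]] <- list(); truth_acquired[[pid]] <- list()
      dens_patient <- cfg$density_meanlog[[stratum[i]]] +
        stats::rnorm(1, 0, cfg$density_sdlog)
      arg_base <- stats::rlnorm(7, cfg$arg_baseline_meanlog, cfg$arg_baseline_sdlog)

      for (site in AZT_SITES) {
        rich <- if (site == "LRT") cfg$richness_lrt else cfg$richness_urt
        f_clear <- cfg$clearance_fraction *
          if (site == "URT") cfg$urt_clearance_factor else 1
        # baseline support; the URT shares most of the LRT community
        if (site == "LRT") {
          base <- sample(asv_ids, rich, prob = w)
          lrt_base <- base
        } else {
          n_core <- round(0.75 * rich)
          core <- sample(lrt_base, min(n_core, length(lrt_base)), prob = w[lrt_base])
          extras <- sample(setdiff(asv_ids, lrt_base), rich - length(core))
          base <- c(core, extras)
        }
        supports <- list()
        if (placebo_first[i]) {
          supports$PreAZT <- base
          k <- round(cfg$natural_turnover * length(base))
          tr <- shift_support(base, asv_ids, k, k, w)
          supports$StartAZT <- tr$support
        } else {
          supports$StartAZT <- base
        }
        s_start <- supports$StartAZT
        tr <- shift_support(s_start, asv_ids,
                            round(f_clear * length(s_start)),
                            round(cfg$treated_acquisition * length(s_start)),
                            w, low_bias = TRUE)
        supports$EndAZT <- tr$support
        truth_cleared[[pid]][[site]] <- tr$cleared
        truth_acquired[[pid]][[site]] <- tr$acquired
        tr2 <- shift_support(supports$EndAZT, asv_ids,
                             round(cfg$post_clearance * length(supports$EndAZT)),
                             round(cfg$post_burst_acquisition * length(supports$EndAZT)),
                             w)
        supports$PostAZT_1mo <- tr2$support
        k3 <- round(cfg$late_turnover * length(supports$PostAZT_1mo))
        tr3 <- shift_support(supports$PostAZT_1mo, asv_ids, k3, k3, w)
        supports$PostAZT_ge3mo <- tr3$support

        for (phase in names(supports)) {
          sup <- supports[[phase]]
          ww <- w[sup]
          idx_enriched <- taxonomy[sup] == enriched[i]
          ww[idx_enriched] <- ww[idx_enriched] * enrich_mult[[phase]]
          s <- (1 - cfg$floor_weight) * ww / sum(ww) +
            cfg$floor_weight / length(sup)
          sid <- paste(pid, site, phase, sep = "_")
          shallow <- site == "URT" &&
            stats::runif(1) < cfg$shallow_fraction
          depth_s <- if (shallow) {
            round(cfg$depth * cfg$shallow_depth_factor)
          } else {
            round(cfg$depth * stats::runif(1, cfg$depth_factor_range[1],
                                           cfg$depth_factor_range[2]))
          }
          p <- as.vector(rdirichlet(1, cfg$dm_concentration * s))
          reads <- stats::rmultinom(1, depth_s, p)[, 1]
          row <- stats::setNames(integer(cfg$n_asvs), asv_ids)
          row[sup] <- reads
          rows[[sid]] <- row
          comp <- stats::setNames(numeric(cfg$n_asvs), asv_ids)
          comp[sup] <- s
          comp_rows[[sid]] <- comp
          meta_rows[[sid]] <- data.frame(
            sample_id = sid, patient_id = pid, site = site, phase = phase,
            time_months = unname(PHASE_TIMES[phase]), stringsAsFactors = FALSE)

          if (site == "LRT") {
            copies <- stats::rlnorm(1, dens_patient, 0.3)
            density[sid] <- copies
            mult <- if (stratum[i] == "increased") {
              switch(phase, PreAZT = 1, StartAZT = 1,
                     EndAZT = cfg$arg_fold_increase *
                       stats::rlnorm(1, 0, 0.2),
                     PostAZT_1mo = 1 + (cfg$arg_fold_increase - 1) / 2,
                     PostAZT_ge3mo = 1 + (cfg$arg_fold_increase - 1) / 4)
            } else {
              switch(phase, EndAZT = 1.1, 1)
            }
            ratios <- arg_base * mult * stats::rlnorm(7, 0, 0.3)
            arg_rows[[sid]] <- data.frame(
              sample_id = sid, copies_16s = copies,
              as.list(stats::setNames(ratios * copies, ARG_GENES)),
              stringsAsFactors = FALSE)
          } else {
            density[sid] <- stats::rlnorm(1, dens_patient, 0.3)
          }
        }
      }
    }

    counts <- do.call(rbind, rows)
    storage.mode(counts) <- "integer"
    meta <- do.call(rbind, meta_rows)
    rownames(meta) <- NULL
    arg <- do.call(rbind, arg_rows)
    rownames(arg) <- NULL
    composition <- do.call(rbind, comp_rows)
    validate_feature_table(counts)
    validate_metadata(meta, counts)
    validate_arg_panel(arg)

    structure(list(
      counts = counts, meta = meta, tree = tree, taxonomy = taxonomy,
      arg = arg,
      truth = list(patients = patients, cleared = truth_cleared,
                   acquired = truth_acquired, composition = composition,
                   density = density),
      config = cfg), class = "aztair_cohort")
  })
}

#' @export
print.aztair_cohort <- function(x, ...) {
  cat(sprintf("Synthetic airway cohort: %d patients, %d samples, %d ASVs\n",
              nrow(x$truth$patients), nrow(x$counts), ncol(x$counts)))
  cat("phases:", paste(AZT_PHASES, collapse = ", "), "\n")
  invisible(x)
}
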