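# Shared in-code fixtures.

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

star_tree <- function(n, brlen = 1) {
  tips <- paste0("t", seq_len(n))
  txt <- paste0("(", paste0(tips, ":", brlen, collapse = ","), ");")
  ape::read.tree(text = txt)
}

# Minimal valid metadata for a vector of sample descriptors.
make_meta <- function(sample_id, patient_id, site, phase,
                      time_months = rep(0, length(sample_id))) {
  tm <- c(PreAZT = -4, StartAZT = 0, EndAZT = 3, PostAZT_1mo = 4,
          PostAZT_ge3mo = 6)
  data.frame(sample_id = sample_id, patient_id = patient_id, site = site,
             phase = phase, time_months = unname(tm[phase]),
             stringsAsFactors = FALSE)
}

make_table <- function(mat, samples = NULL, asvs = NULL) {
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(mat)))
  if (is.null(asvs)) asvs <- paste0("ASV_", seq_len(ncol(mat)))
  m <- as.matrix(mat)
  dimnames(m) <- list(samples, asvs)
  storage.mode(m) <- "integer"
  m
}

# A small cohort for pipeline-level tests (fast but structurally complete).
small_cohort <- function(seed = 11, ...) {
  simulate_cohort(cohort_config(
    n_patients = 6, n_asvs = 120, depth = 800,
    richness_lrt = 50, richness_urt = 36, seed = seed, ...))
}
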