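---
title: "Methods: longitudinal paired-site airway microbiota analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal paired-site airway microbiota analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aztair)
```

`aztair` analyses 16S amplicon cohorts sampled at paired airway sites
(sputum = lower respiratory tract, LRT; oropharyngeal swab = upper
respiratory tract, URT) across five phases around an azithromycin course:
`PreAZT`, `StartAZT`, `EndAZT`, `PostAZT_1mo`, `PostAZT_ge3mo`. This
vignette documents the statistical procedures, the choices behind them, and
what the synthetic validation cohort does and does not establish.

## Rarefaction and presence

All diversity and turnover analyses operate on a rarefied table: each
sample is subsampled without replacement to a common depth (default
10 055 reads), samples below that depth are dropped and reported. We use a
**single** multivariate-hypergeometric draw per sample with a recorded
seed, rather than averaging repeated draws: a single draw keeps every
downstream presence/absence statement attached to one concrete, exactly
reproducible table, which matters because turnover is defined on presence.

"Presence" everywhere downstream means *at least one read in the rarefied
table*. The documented caveat is that rarefaction can convert genuinely
present low-count taxa into absences; presence-based turnover therefore
carries a noise floor set by the rarefaction depth, which the null-cohort
calibration below quantifies.

## Alpha diversity and group tests

Four per-sample metrics:

* **Chao1** (bias-corrected): `S_obs + f1(f1−1)/(2(f2+1))`, with `f1`, `f2`
  the singleton and doubleton counts. Always ≥ observed richness; equal to
  it exactly when `f1 ∈ {0, 1}`.
* **Shannon** `H = −Σ p_i ln p_i`, natural log (nats). The log base is a
  pure convention; natural log is the default of the R ecosystem tools this
  package sits beside.
* **Camargo evenness** `E = 1 − Σ_{i<j}|p_i − p_j|/S`, computed over the
  observed (nonzero) taxa only — the common convention; including absent
  taxa would conflate evenness with richness.
* **Faith's PD**: total branch length of the tree subtending the observed
  taxa. The default follows the rooted-PD convention (the path down to the
  root is included), so PD is monotone under adding observed taxa and
  well-defined for single-taxon samples; `include_root = FALSE` switches to
  the subtree-below-the-MRCA variant.

Phase comparisons use the tie-corrected Kruskal–Wallis test with Dunn's
pairwise z-tests and Holm's step-down adjustment, at α = 0.05. Data with
zero rank variance (all values identical) are defined to give statistic 0
and p = 1, rather than an undefined tie-correction ratio. The Holm family
is **all pairwise comparisons within one metric-site call** — the
multiplicity unit a practitioner actually inspects; a global
across-metrics family would tie each metric's conclusions to how many other
metrics happened to be computed. Paired contrasts use the two-sided
Wilcoxon signed-rank test, dropping zero differences; exact p-values when
n < 50 and the absolute differences are untied, normal approximation
otherwise.

## Phylogenetic beta diversity and ordination

Both UniFrac forms are computed by explicit branch classification. For
each edge of the rooted tree, the incidence of descendant taxa in each
sample gives:

* unweighted: `d = Σ L_b [unique to one sample] / Σ L_b [in either]`;
* weighted: `d = Σ L_b |P_A(b) − P_B(b)|`, with `P_S(b)` the fraction of
  sample S's reads descending from branch b. The default is the
  **normalized** variant (divided by `Σ L_b (P_A(b) + P_B(b))`, the maximum
  attainable value), so weighted and unweighted distances share the [0, 1]
  scale and can be compared; the raw variant is available by flag.

PCoA uses Gower double-centring; when negative eigenvalues beyond a 1e-8
tolerance reveal a non-Euclidean matrix (typical for UniFrac), the Lingoes
correction is applied automatically and flagged in the result. The
corrected embedding is full-rank and distance-preserving, which the
centroid construction relies on.

**OPS-to-sputum-centroid distances.** For each phase, all of that phase's
samples are embedded by corrected PCoA; the centroid is the coordinate mean
of the sputum samples, and each swab sample's statistic is its Euclidean
distance to that centroid — the construction used by distance-based
dispersion analysis. A mean community profile is deliberately *not* used:
UniFrac space is non-Euclidean, so an averaged profile is not
distance-consistent, whereas the embedded centroid is. Embeddings are
per-phase (each phase's samples only) so that a phase's statistic does not
depend on samples from other phases.

**PERMANOVA** is one-way: pseudo-F from among/within sums of squared
distances, p-value `(1 + #{F* ≥ F}) / (n_perm + 1)` with 999 permutations
by default, so p is never exactly zero. Labels are permuted freely by
default; a `strata` argument restricts permutations to within patients for
repeated-measures designs, and an exhaustive mode enumerates all
relabellings for small n (used by the test suite as its own oracle).

**DPCoA** follows Pavoine's construction: genera are embedded by corrected
PCoA of their pairwise distances (here, mean patristic distances between
member ASVs), each sample is placed at the abundance-weighted centroid of
its genus points, and the sample cloud — weighted by sample totals — is
rotated to its principal axes; genus and sample coordinates share the
space. The analysis is restricted to the k = 15 most abundant genera by
mean relative abundance, with exact ties broken lexicographically so the
selection is deterministic. In the equal-distance limit (all genus
distances d) the squared sample distance reduces to
`(d²/2) Σ (p_i − q_i)²`; note the d² — the distance-preserving species
embedding fixes the scale, and the test suite asserts this closed form at
two different d.

## Turnover

For one patient, site and window (default `StartAZT → EndAZT`), presence
at the two endpoint samples partitions taxa into **retained** (both),
**cleared** (start only) and **acquired** (end only); the partition
identities are asserted on every call. The no-treatment contrast uses the
`PreAZT → StartAZT` window of patients who started with placebo; the
post-treatment contrast uses `EndAZT → PostAZT_1mo`. Should a patient have
several samples for one (site, phase) — possible across crossover arms —
the earliest by `time_months` is used and logged.

Site-overlap assigns each ASV observed in a phase to LRT-only / URT-only /
both, tested against uniform expected proportions by chi-squared goodness
of fit (the expected vector is configurable; uniform is the default
because the three categories are a priori exchangeable under no site
structure). Per-patient category counts are compared across patients with
the paired signed-rank test (`start_vs_end`, `acquired_vs_retained`,
`acquired_vs_cleared`).

Tracking evaluates each patient's *own* cleared or acquired set in that
patient's samples across all phases and either site. This within-patient
formulation is essential at moderate ASV-pool sizes: pooling all patients'
cleared sets saturates the pool and the tracked fraction loses meaning.

## ARG carriage scoring

qPCR copy numbers for the seven-gene panel (erm(B), erm(F), mel, msr(E),
mef, tet(M), tet(W)) are normalised to 16S rRNA gene copies (burden per
bacterial genome equivalent, dimensionless), then min–max scaled to [0, 1]
per gene **across all sputum samples in the analysis set** — one scaling
population, because the score's purpose is longitudinal comparison of one
number per sample; per-phase scaling would break comparability across
phases. Zero-range genes contribute 0. The cumulative score (0–7) is the
sum.

Patients with sputum scores at both `StartAZT` and `EndAZT` are split at
the cohort **median fold change** (End/Start) into "increased" (above the
median) and "stable" (at or below — placing exact-median patients in
"stable" yields an even split for even cohorts). A zero score at either
endpoint is handled by adding the smallest positive cumulative score in the
cohort as a pseudocount to both terms; an absolute-difference mode is
available where ratios are unsuitable. The fold-change reading of "median
change" was chosen because carriage spans orders of magnitude;
the difference mode is retained for sensitivity analysis.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes, with recorded ground truth. Per patient, a baseline community —
a patient-specific log-normal reweighting (sd 0.6) of a shared 30-genus
skewed (Zipf-weighted) structure over 300 ASVs — persists across phases.
Defaults (all in `cohort_config()`):

* 24 patients, paired sites, five phases; pre-treatment samples only for
  the placebo-first half; LRT richness 110 vs URT 80 taxa per patient,
  with the URT drawing 75% of its taxa from the patient's LRT community;
* sequencing depth 1.3–2× the 10 055-read rarefaction depth, with 10% of
  URT samples deliberately shallow (0.6×) to emulate swabs failing the
  read threshold;
* per-sample compositions are Dirichlet draws (concentration 500) around
  the patient's phase composition; reads are multinomial — the standard
  overdispersed (Dirichlet-multinomial) model for amplicon counts;
* each phase composition mixes a 30% uniform floor over the present taxa
  into the weight-derived proportions. The floor guarantees that every
  planted-present taxon has expected abundance ≥ ~0.27% (≳ 27 reads at
  depth), so presence recovery is limited by the planted truth rather than
  by detection dropout — the property the recovery tests quantify;
* treatment effects between `StartAZT` and `EndAZT`: clearance of 20% of
  the patient's taxa (chosen from the lower 75% by abundance; 0.6× that
  fraction in the URT), applied to the *composition*, so cleared taxa have
  exactly zero reads at treatment end; acquisition suppressed to 5%;
  3-fold enrichment of the patient's designated genus at treatment end,
  decaying through the post phases;
* natural turnover of 40% per untreated ~3-month window, which yields
  retained fractions near 0.43 of each window's ASV union; post-treatment
  acquisition burst 15% with 5% clearance, then 20% symmetric late
  turnover — turnover resumes while richness remains below baseline;
* ARG panel: per-patient baseline gene ratios are log-normal
  (median 2×10⁻⁴ per 16S copy, log-sd 1); the "increased" half of the
  cohort (whose enriched genus is Streptococcus) gets a ~4-fold ratio
  increase at treatment end, decaying afterwards; the "stable"
  (Prevotella_7-enriched) half stays ~flat. Bacterial density is
  log-normal with median 4×10⁵ 16S copies/µL for stable patients and
  8×10⁴ for increased patients (log-sd 0.8 between patients, 0.3 within).

`null_cohort_config()` switches off every planted effect and all turnover,
giving exchangeable phase redraws per patient for calibration.

**What passing tests show — and what they do not.** The generator
reproduces the *statistical* features the pipeline's inferences rely on:
per-patient persistence, overdispersed counts, planted presence dynamics,
site asymmetry, an ARG subgroup. It does not simulate sequencing reads,
chimeras, contamination, taxonomic misassignment, or compositional
artefacts of PCR; and with a 300-ASV pool, cohort-pooled quantities that
depend on pool saturation (e.g. the site-overlap Venn across all patients
of a phase) compress relative to a real dataset with thousands of ASVs, in
which sputum-only taxa dominate the union. Recovery results therefore
validate the *algorithms*, not instrument-level robustness on real data.

## Numerical choices and degenerate inputs

* Lingoes correction triggers below eigenvalue −1e-8 (relative to the
  squared-distance scale); smaller negative eigenvalues are treated as
  noise.
* All-zero samples are errors for diversity metrics; empty ASV sets are
  legal for tracking (all-zero series).
* Newick branches without lengths default to 0 with a warning; trees must
  retain positive total length. Tips absent from the count table are
  pruned on demand.
* Exact-median patients stratify as "stable"; an all-tied cohort labels
  everyone "stable" with a warning.
* Permutation p-values use the (x+1)/(n+1) convention; exhaustive
  enumeration includes the identity relabelling.
* All randomness (simulation, rarefaction, permutations) flows from
  user-supplied seeds; sub-seeds are derived deterministically and kept
  below 2³¹.

## Problem sizes used by the validation suite

Metric oracles run on 100 random instances of ≤ 10 taxa; permutation
oracles enumerate all relabellings at n ∈ {6, 8} and 2⁶–2⁸ sign
assignments; Kruskal–Wallis calibration uses 1000 null simulations of
3 × 8 observations; turnover oracles use 200 random toy cohorts; recovery
runs 50 replicates each of the default, clearance-0.3 and null
configurations at full cohort size (24 patients, 300 ASVs, depth 10 055).
These sizes make the whole suite complete in a couple of minutes on one
CPU while leaving the recovery assertions' Monte-Carlo error well inside
their tolerance bands.

## Known limitations

* Unweighted-UniFrac PERMANOVA across phases has modest power at this
  cohort size when between-patient variation dominates, as it does in the
  generator (and in real airway cohorts); the within-patient `strata`
  option exists for exactly that situation.
* The ARG module consumes qPCR copy numbers; amplification efficiency and
  probe chemistry are upstream concerns. Amplicon + qPCR data cannot
  attribute resistance genes to specific taxa.
* Genus-level DPCoA distances summarise member-ASV patristic distances by
  their mean, which shrinks distances between heterogeneous genera.
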