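Package: aztair
Title: Longitudinal Paired-Site Airway Microbiota Analysis Under Azithromycin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of paired upper- and
    lower-airway 16S amplicon data collected around a macrolide
    (azithromycin) treatment window. Implements rarefaction and
    genus-level aggregation of ASV count tables, phylogenetic and
    non-phylogenetic alpha diversity (Chao1, Shannon, Camargo evenness,
    Faith's PD), unweighted and weighted UniFrac distances with PCoA,
    PERMANOVA and double principal coordinate analysis (DPCoA),
    per-phase distances from oropharyngeal-swab samples to the sputum
    centroid, retained/cleared/acquired ASV turnover classification with
    cross-site abundance tracking, and qPCR-based antibiotic-resistance-
    gene carriage scoring with patient stratification. A synthetic
    cohort generator with recorded ground truth emulates the data
    structure of a five-phase crossover study so the whole pipeline can
    be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    ade4,
    picante,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
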