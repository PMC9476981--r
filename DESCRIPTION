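Package: endoflow
Title: Endopolyploidy and Genome Size Analysis of Flow-Cytometric DNA Histograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gates DNA-content fluorescence histograms into doubling-series
    ploidy classes (2C, 4C, 8C, ...), estimates absolute genome size against an
    internal reference standard, and computes the endopolyploidy parameter
    suite: endoreduplication index (EI), mean C-value (MCV), mean ploidy of
    endopolyploid nuclei (E4P), proportion of nuclei at or above 4C, maximal
    endocycle number (ECmax) and the tissue-specific mean DNA content (meanDNA)
    that combines genome size with endopolyploidy level. Includes the
    between-species/organ comparison layer (Shapiro-Wilk/Levene gatekeeping,
    ANOVA + Tukey HSD or Kruskal-Wallis + Dunn with Benjamini-Hochberg
    adjustment, compact letter displays, Spearman matrices, across-species
    coefficients of variation, centred PCA) and a seeded synthetic-data
    generator emulating plant flow-cytometry measurements, so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
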