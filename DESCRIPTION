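Package: beadanova
Title: Factorial ANOVA Differential Expression for Illumina BeadChip
    Experiments
Version: 1.0.0
Author: Package Author
Maintainer: Package Author <maintainer@example.org>
Description: Per-probe three-way factorial ANOVA (sex, genotype, chip batch,
    sex-by-genotype interaction) for Illumina BeadChip expression data, with
    Fisher least-significant-difference contrasts, signed fold changes, and
    Benjamini-Hochberg false discovery rate control.  Includes detection
    p-value filtering, quantile-anchored cubic-spline normalization, batch
    assessment and mean-centering adjustment, permutation-based FDR
    calibration against random re-combinations of the design labels,
    hypergeometric gene-set enrichment, complete-linkage hierarchical
    clustering of z-scored profiles, transcription-factor and receptor
    shortest-path subnetwork extraction from typed interaction graphs, a
    synthetic BeadChip experiment generator with known spike-in truth, and a
    YAML-configured end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
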