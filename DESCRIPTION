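Package: strepArray
Title: Two-Color Genomic-DNA Reference Microarray Analysis of Streptomyces
    Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification and classification pipeline for two-color
    expression microarrays hybridized against a genomic-DNA common
    reference, as used to compare the MI and MII developmental stages of
    Streptomyces coelicolor between liquid and solid cultures. Implements
    spot-level net intensities with a background-SD surrogate rule,
    log2(cDNA/gDNA) Mg values, probe-weighted cyclic loess and global
    median normalization, probe-to-gene summarization, empirical-Bayes
    moderated two-group statistics with Benjamini-Hochberg FDR control,
    and a coefficient-of-variation based three-way classification of
    per-gene log2(MII/MI) abundances across culture conditions. A
    synthetic-experiment generator with known ground truth supports
    end-to-end validation without any array data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
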