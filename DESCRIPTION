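Package: circscape
Title: CircRNA Expression Landscape Analysis for Neural Differentiation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing circular RNA (circRNA) expression landscapes
    from back-splice junction (BSJ) read counts: caller harmonization and
    abundance filtering, reads-per-million and circular-to-linear ratio
    statistics, median-of-ratios normalization, global expression-shift
    testing with a D'Agostino-Pearson normality gate and an exact Wilcoxon
    matched-pairs signed-rank test, circular-linear coupling regression,
    BSJ-targeting shRNA/agoshRNA construct design with an off-target
    mismatch scan, single-cell cluster composition bias analysis, and
    cortical-migration depth binning. A synthetic-data generator provides a
    fully testable surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    Biostrings,
    BiocGenerics
Suggests:
    DESeq2,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
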