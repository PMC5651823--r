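Package: nattriad
Title: Healthy/Tumor-Adjacent/Tumor Transcriptome Triad Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of three-condition (healthy, tumor-adjacent normal,
    tumor) bulk RNA-seq designs integrated across cohorts. Provides
    upper-quartile CPM normalization, control-gene factor estimation and
    removal of unwanted variation, negative-binomial likelihood-ratio
    differential expression with Bonferroni/fold-change/abundance gates,
    classification of genes into the nine expression models obtained by
    crossing the NAT-vs-healthy and tumor-vs-NAT calls, cross-tissue
    sharing statistics under a Poisson-Binomial independence null,
    extraction and single-sample scoring (ssGSEA) of tumor-adjacent
    specific activation (TASA) signatures, two-reference simplex-constrained
    expression deconvolution, comparison of tumor differential expression
    against healthy versus tumor-adjacent controls, and a synthetic-data
    generator with recorded ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    fgsea,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
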