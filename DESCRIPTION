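Package: concore
Title: Cross-Study Consensus Core Differential Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating many RNA-seq differential-expression
    contrasts into a consensus "common core" of dysregulated genes, in the
    style of large disease-model meta-analyses (e.g. MeCP2/Rett-syndrome
    mouse compendia). Provides significance-masked fold-change matrices
    with direction harmonisation of gain-of-function contrasts, support
    thresholding into up/down cores, threshold-grid summaries, biotype
    composition, chromosome-positional analysis via a permutation-based
    binary segmentation, pre-ranked weighted Kolmogorov-Smirnov gene-set
    enrichment with a gene-permutation null, direction-stratified overlap
    tests, a desk-scale negative-binomial Wald differential-expression
    caller with median-of-ratios normalisation, a replicate down-sampling
    power analysis with Rand-index stability, and synthetic-data
    generators with planted ground truth for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), Matrix, yaml, fgsea, DESeq2, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
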