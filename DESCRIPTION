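Package: phosphoLFQ
Title: Label-Free Phosphoproteomics Quantification by Extracted Ion
    Chromatograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free quantification of phosphopeptides from centroided
    MS1 spectra by extracted ion chromatogram (XIC) peak-area integration
    with match-between-runs zero-fill, technical-replicate averaging,
    total-intensity normalization, and per-phosphopeptide differential
    regulation statistics (pooled-variance Student's t test, log2 fold
    changes, volcano classification, Venn partitioning, fold-change
    heatmaps). Includes phosphosite-assignment confidence via delta
    scores over positional isoforms, mzML input/output, and a fully
    deterministic synthetic LC-MS study generator with ground truth for
    end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    mzR,
    ggplot2,
    pheatmap,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'synthetic.R'
    'xic.R'
    'abundance.R'
    'diffphos.R'
    'siteloc.R'
    'io.R'
    'phosphoLFQ-package.R'
    'plots.R'
    'pipeline.R'
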