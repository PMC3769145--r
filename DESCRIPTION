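Package: methnorm
Title: Data-Driven Preprocessing and Quality Metrics for Illumina 450K
    Methylation Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Background-equalisation and quantile-normalisation methods for
    paired methylated/unmethylated signal intensities from Infinium
    HumanMethylation450 BeadChips, together with three data-quality metrics
    built on probes with known expected behaviour (imprinted DMR probes,
    SNP genotyping control probes, X-chromosome probes) and a cross-dataset
    procedure for ranking preprocessing methods. Includes a synthetic-array
    simulator that emulates Type II background inflation, dye bias,
    sample-level intensity scaling and chip-position background gradients,
    so the whole pipeline is testable without real array data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
biocViews: DNAMethylation, Microarray, Preprocessing, QualityControl,
    Normalization, TwoChannel
RoxygenNote: 7.3.3
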