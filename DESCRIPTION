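Package: mirflux
Title: Tissue-Resolved miRNA Ageing and Inter-Tissue Trafficking Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for tissue-resolved small-RNA profiling of
    ageing in Caenorhabditis elegans. Implements TPM and quantile
    normalization of miRNA count matrices, read- and UMI-based detection
    calling, Box-Cox-transformed t-tests for age-dependent differential
    miRNA expression (Age-DEMIRs), classification of potentially
    inter-tissue transported miRNAs (PITT-miRs) from the contrast between
    promoter-reporter transcription and sequencing-based abundance, a
    permutation-tested directed tissue-to-tissue miRNA trafficking network
    with Yeo-Johnson z-scores, extracellular-vesicle loading-ratio and
    selective-secretion statistics, seed-match plus anti-correlation miRNA
    target inference with autonomous versus non-autonomous partitioning,
    and category enrichment. Ships a synthetic-data generator with planted
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    stringi,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    car,
    MASS,
    jsonlite
Config/testthat/edition: 3
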