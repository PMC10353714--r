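Package: leukosv
Title: Somatic Structural-Variant Integration and Recurrence Analysis for
    Pediatric B-Cell Precursor ALL Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to merge optical genome mapping (OGM) structural-variant
    calls from dual calling pipelines with copy-number and SNP-array segment
    tracks, subtract matched-normal (germline) calls, apply probe- and
    size-based filters, detect minimal altered regions (MARs) recurrent
    across a leukemia cohort, integrate small-variant evidence (double hits),
    evaluate copy-number risk rules (IKZF1plus, hyperdiploid aneuploidy
    profiles), approximate putative fusion genes from translocation
    breakends, and quantify cross-platform concordance. Includes a synthetic
    tumor/normal cohort simulator with per-platform caller emulation and
    ground truth, emulating the ETV6::RUNX1-positive and classical
    hyperdiploid B-cell precursor ALL subtypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
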