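Package: ptrtkit
Title: Identification of Tumor-Reactive T Cells from Paired Single-Cell
    Expression and TCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying potentially tumor-reactive T cells (pTRTs)
    in paired scRNA-seq / scV(D)J-seq data. Implements per-cluster tumor
    enrichment (Ro/e), clonal expansion (normalized Shannon entropy),
    proliferation and TCR-signaling activation indices; TCR-sharing-based
    tracing of pTRT-relevant cells; specificity ranking of candidate marker
    genes for the tumor-reactive compartment; exclusion of virus-specific
    clonotypes; and estimation of marker-positive CD8 T-cell fractions in
    bulk RNA-seq by signature-based non-negative deconvolution. A synthetic
    cohort generator with planted ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
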