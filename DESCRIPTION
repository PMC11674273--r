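Package: rthclat
Title: Rapid qPCR-Based Classification of Skin Sensitizers with THP-1 Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the RT h-CLAT workflow for binary skin-sensitizer
    assessment from THP-1 cell gene expression. Converts raw quantification
    cycles (Cq) to fold changes by the comparative Cq method with GAPDH
    normalization, applies the replicate-majority decision rule on the
    HMOX1/JUN marker panel (sensitizer if either gene shows a two-fold or
    greater increase in at least two of three replicates), and scores calls
    against murine local lymph node assay (LLNA) categories. Also provides
    the RNA-Seq marker-discovery cascade (low-count filtering, TPM, a
    simplified negative-binomial Wald test with median-of-ratios
    normalization and Benjamini-Hochberg adjustment, sensitizer-specific
    gene selection and ranking), the qPCR-versus-RNA-Seq concordance rule
    used to reduce twelve candidate markers to five, threshold sweeps, and
    synthetic-data generators for all inputs. Bundled fixtures reproduce
    the published validation tables end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    S4Vectors,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
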