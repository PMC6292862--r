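Package: haplocnv
Title: Haplotype-Based Mixed-Model GWAS and Read-Depth Copy-Number Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a haplotype sliding-window genome-wide association
    workflow for livestock pseudo-phenotypes (deregressed breeding values),
    using a leave-one-chromosome-out mixed linear model with AI-REML variance
    components and generalized least squares marker tests, together with the
    downstream evidence chain used to resolve an associated locus into a
    copy-number variant: read-depth coverage profiling by haplotype group,
    gain-region calling, tandem-duplication read-pair signatures, log-R-ratio
    probe-intensity analysis with GC-wave correction, and qPCR relative
    quantification by the delta-delta-Ct method. A founder-mosaic simulator
    generates every input with known ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
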