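Package: onpls
Title: Multi-Block Integration of Omics Data by OnPLS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Symmetric multi-block integration of transcriptomic, proteomic and
    metabolomic matrices with OnPLS, the multi-block generalisation of O2PLS.
    Provides matrix-level preprocessing (log2 transform, low-intensity
    censoring, dye-swap combination, per-sample centering and wild-type
    reference scaling), decomposition of each block into globally joint,
    locally joint and unique variation with a full variance ledger, variable
    selection by VIP with jack-knife confidence intervals, direction-arrow and
    variance-decomposition reports, pathway-painting export files for MapMan
    and Paintomics, and a synthetic multi-omics generator with known ground
    truth for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
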