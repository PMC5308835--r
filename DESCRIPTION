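Package: screenet
Title: Seed-Gene Co-Expression Screening and Candidate Network Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putative upstream regulators of a seed gene from paired
    expression datasets. Screens every transcript for Pearson correlation to a
    designated seed gene within each dataset, intersects the per-dataset
    passing sets with direction-concordance checking, and grows size-capped,
    interconnectivity-maximizing networks over user-supplied gene-gene
    interaction evidence, scored by right-tailed Fisher's exact tests.
    Includes a planted-module synthetic data generator (shared latent factor,
    hub-centred interaction evidence) so the full pipeline is testable without
    external downloads, plus readers for GEO Series Matrix and plain TSV
    expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
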