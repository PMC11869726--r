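Package: convergentretro
Title: Convergent Retrosynthesis Route Extraction, Planning and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with convergent synthesis routes, in which a
    library of target molecules is produced from shared (common)
    intermediates. Extracts experimentally validated convergent routes from
    atom-mapped reaction corpora (reactant/reagent partitioning by atom-map
    contribution, per-document synthesis graphs, role assignment and
    direction/cycle/stereoisomer/duplicate filtering); plans a whole compound
    library jointly with a multi-target multi-step retrosynthetic search
    driven by a pluggable single-step policy; extracts, ranks and summarizes
    convergent routes from the search graph; and scores proposed routes
    against reference routes with solvability, accuracy and route F1 metrics.
    Ships a synthetic toy-chemistry universe with a known ground truth and an
    oracle policy so the full pipeline is testable without external data or a
    trained model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    data.table,
    igraph,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
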