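Package: dagflow
Title: Pattern-Based Dataflow Workflow Engine for Sequence Analysis Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dataflow workflow system for composing and executing
    bioinformatics pipelines as directed acyclic graphs. Workflows are built
    from explicit control patterns (sequence, synchronous merge and fork,
    multi-choice switch, do-while iteration) and data patterns (nested
    lists, dot and cross product expansion, data select, data collect,
    multi-FASTA list splitting). Tools are invoked through a generic wrapper
    with success/fail/dummy token semantics. Includes importers for two
    simplified foreign workflow dialects (an XML processor dialect and a
    JSON step dialect) with optional substitution of remote web-service
    calls by local tools, and an optimizer that condenses maximal external
    sub-workflows into single delegated nodes so a foreign engine is invoked
    once per component. Ships a deterministic stub tool suite, synthetic
    data generators and two case-study fixture workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
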