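Package: miappe
Title: MIAPPE 1.1 Plant Phenotyping Metadata: Model, Validation and Interoperable Serializations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reference implementation of the MIAPPE 1.1 (Minimum Information
    About a Plant Phenotyping Experiment) metadata standard. Provides a typed
    object graph covering the eleven checklist sections (investigation, study,
    person, data file, biological material, environment, experimental factor,
    event, observation unit, sample, observed variable), a deterministic
    checklist validator with a stable rule registry, lossless readers and
    writers for four serializations (ISA-Tab archives, BrAPI v1.3-shaped JSON
    document sets, multi-worksheet spreadsheet workbooks, and RDF instantiating
    the Plant Phenotyping Experiment Ontology), pairwise format converters, a
    command-line interface, and a seeded generator of synthetic field-trial,
    glasshouse, forest-tree, time-series, sensor and crossing-population
    datasets for exercising the standard's hard cases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
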