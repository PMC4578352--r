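Package: enmkit
Title: Nanomaterial Safety Data Management and NanoQSAR Modelling
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An embeddable toolkit for engineered-nanomaterial (ENM) safety
    data: a substance/protocol-application/measurement data model with
    deterministic identifiers and a stable JSON study serialization, a
    configurable spreadsheet template parser (row, column and dynamic-block
    layouts driven by a JSON mapping), bundles of substances and endpoints
    with conversion to a modelling matrix using Dixon's Q-test replicate
    aggregation, a PMML subset (data and transformation dictionaries) for
    feature selection and derived-field arithmetic, multiple linear
    regression NanoQSAR modelling with a leverage applicability domain and a
    JSON train/predict algorithm-exchange protocol, Tanimoto fingerprint
    similarity search over component structures, and a transport-agnostic
    service layer mirroring the substance/bundle REST resource layout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    digest,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    readxl,
    httpuv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
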