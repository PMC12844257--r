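Package: clickscreen
Title: Design and Screening of Click-Chemistry N-Acyl Sulfonamide Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the design and biological triage of combinatorial
    1,2,3-triazole N-acyl sulfonamide libraries built by copper(I)-catalyzed
    azide-alkyne cycloaddition (CuAAC) followed by sulfonamide N-acylation.
    Provides building-block validation and virtual enumeration of the
    two-step product space, parallel-synthesis bookkeeping (synthesis
    success rate, isolated yields), differential scanning fluorimetry
    melt-curve analysis with robust per-plate thermal-shift hit calling,
    four-parameter logistic IC50 fitting for enzymatic confirmation, and a
    deterministic synthetic-data generator so that every stage of the
    cascade can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
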