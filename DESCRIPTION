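Package: dartnam
Title: Exposure-Led Non-Animal Risk Assessment Toolkit for Developmental
    and Reproductive Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for next-generation risk assessment (NGRA) of
    developmental and reproductive toxicity (DART) without animal data:
    dictionary-based biomarker extraction from literature corpora with
    class-specific hit-count thresholds and pooling, baseline-expression
    coverage analysis of in vitro test systems against the mined marker
    sets, a reduced maternal-foetal physiologically based kinetic (PBK)
    simulator with permeability-limited placental transfer, Bayesian
    concentration-response point-of-departure (PoD) inference for
    transcriptomic counts (log Student's-t Poisson hinge model),
    continuous stress biomarkers and 4PL percent-inhibition curves, and
    bioactivity-exposure ratio (BER) decision logic. Includes synthetic
    data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
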