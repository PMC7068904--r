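Package: kneealign
Title: Orthogonal-Design Optimization of Tibial Component Alignment in
    Total Knee Arthroplasty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening and optimizing tibial-component implantation
    parameters in total knee arthroplasty. Builds and validates the L9(3^4)
    Taguchi orthogonal array over varus angle, posterior slope and external
    rotation, evaluates each run either against a packaged reference
    finite-element response table, a desk-scale elastic-foundation contact
    surrogate of the femoral-condyle/polyethylene-liner articulation, or a
    planted analytic response, then performs range analysis (level means,
    ranges, factor ranking, optimal level combination) and verifies the
    predicted optimum. Includes delimited-text I/O for designs, responses and
    pressure maps, a YAML-configured pipeline, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
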