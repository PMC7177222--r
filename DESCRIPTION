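Package: qvroute
Title: Quarantine Vehicle Routing for Transferring High-Risk Individuals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and solves the quarantine vehicle scheduling problem that
    arises when high-risk individuals scattered across a set of areas must be
    transferred to a single isolated region during an epidemic. Provides the
    problem data model with feasibility rules for splitting an area's
    individuals across vehicles, two independent evaluators of the
    sum-of-exposure-times objective (a closed-form recursion and a discrete
    event simulation), a hybrid water wave optimization and neighborhood
    search solver, a nearest-area greedy dispatcher baseline, a seeded
    synthetic instance generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
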