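Package: grnsets
Title: Model Sets and Practical Indistinguishability for Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates a combinatorial family of Hill-function ordinary
    differential equation models of the three-gene regulatory network
    (eud-1, nhr-40, sult-1) controlling the mouth-form decision in the
    nematode Pristionchus pacificus, fits every structure to time-course
    expression data by multiplicative-error maximum likelihood with
    Latin-hypercube multistart bounded quasi-Newton optimization, and
    extracts model sets: collections of network structures that fit each
    experiment acceptably, together with their cross-experiment
    intersection. Includes a synthetic-data generator emulating the
    experimental design, misspecification sweeps over sampling and noise
    regimes, cost-curve ranking with acceptability thresholds, and
    decision-tree classification of structural features that predict
    acceptable fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
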