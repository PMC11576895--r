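Package: mpbpk
Title: Minimal Physiologically Based Pharmacokinetic Modelling of
    Antibody Size, Charge, FcRn and Target Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimal physiologically based pharmacokinetic (mPBPK) model
    for monoclonal antibodies and antibody fragments that links molecular
    weight and size (two-pore transcapillary transport and size-based renal
    clearance), net surface charge (pinocytosis scaling, non-specific
    membrane binding, interstitial distribution), FcRn binding and
    endosomal recycling, and target-mediated drug disposition to plasma and
    lumped tight/leaky tissue pharmacokinetics. Includes local sensitivity
    analysis, multi-start nonlinear least-squares parameter estimation with
    Latin-hypercube starts, and a synthetic-data generator for fitting
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
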