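Package: cipaord
Title: Cardiomyocyte Simulation and Torsade Risk Metrics for the CiPA Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates drug effects on the human ventricular action potential
    with an endocardial O'Hara-Rudy myocyte model whose rapid delayed
    rectifier current (IKr) is represented by a Markov chain with
    state-dependent drug binding and closed-state trapping, while six other
    ionic currents are blocked through Hill equations. Computes a panel of
    candidate proarrhythmia metrics including the net-charge metric qNet,
    classifies compounds into three torsade-de-pointes risk categories with
    proportional-odds logistic regression (training and leave-one-out error),
    quantifies repolarization robustness as the minimal IKr conductance
    reduction that triggers an early afterdepolarization, and calibrates
    ionic conductance scaling factors against action-potential-duration
    rate-dependence targets with an evolutionary search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    MASS,
    digest,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
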