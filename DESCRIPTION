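Package: psrtt
Title: Forgetful Observer and Hierarchical Gaussian Filter Models for
    Probabilistic Serial Reaction Time Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and trial-by-trial model fitting for probabilistic
    serial reaction time tasks in which four stimuli are generated from
    hierarchically switching Markov transition matrices.  Implements a
    forgetful Dirichlet-categorical observer (effective transition counts
    that decay towards an asymptotic prior), a three-level hierarchical
    Gaussian filter comparator over unnormalised transition propensities,
    profile-likelihood fitting of log reaction times, BIC model comparison,
    confusion and parameter-recovery analyses, covariate-adjusted group
    contrasts, and permutation tests on within-block speeding curves.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
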