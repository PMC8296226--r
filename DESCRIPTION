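Package: orflow
Title: Interaction-Based Surgical Workflow Segmentation from Staff Movement
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing the phases of a surgical operation from
    indoor-positioning trajectories of the operating-room staff. Pairwise
    staff interaction is quantified per phase segment with longest-common-
    subsequence (LCSS) trajectory similarity, discretized into low/medium/high
    levels, and used to classify six neurosurgical phases with a discrete
    Bayesian network whose structure is learned by score-based hill climbing
    and whose parameters are maximum-likelihood conditional probability
    tables. Includes a synthetic operating-room movement simulator with
    role-specific activity zones and phase-dependent cooperation, descriptive
    movement statistics, exact posterior inference by variable elimination,
    a naive Bayes baseline, and repeated random holdout evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
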