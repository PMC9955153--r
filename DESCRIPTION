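Package: jqnkld
Title: Jackson Queueing-Network Models and Kullback-Leibler Divergence
    Rates for Cell-Signalling Cascades
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models a phosphorylation cascade as an open Jackson queueing
    network in which the phosphate mediator is the customer and each
    signalling kinase is a single-server node. Provides the product-form
    steady state (traffic equations, utilizations, Little's-law queue
    lengths), a discrete-event simulator that validates the product form
    empirically, the information-theoretic core (Kullback-Leibler
    divergence of the signalling state against the pre-stimulus steady
    state, its constrained extremum under a signal-duration budget, and
    the resulting conservation of the divergence rate across cascade
    steps), an estimator of the divergence rate from fold-phosphorylation
    time courses, a synthetic antibody-array time-course generator with
    known ground truth, and replicate statistics (mean/SD, mean
    differences, Cohen's d) for testing rate conservation across a
    cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
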