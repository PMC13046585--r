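Package: dynchoice
Title: Modeling Dynamic Risky Choice in Two-Stage Decision Trees
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying dynamic (multistage) decision making under
    risk.  Builds two-stage decision trees whose backward-induction and
    forward-lottery evaluations point to opposite first-stage choices,
    generates full experimental designs and simulated participants,
    fits True-and-Error (TE) multinomial models of four-presentation
    choice patterns with G-squared tests of nested restrictions, and
    implements a Decision Field Theory-Planning accumulator (mental
    simulation with threshold shift, sampling bias, daydreaming,
    non-planning and switch-point mechanisms) with simulation-based
    likelihood fitting and four-fold cross-validated model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
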