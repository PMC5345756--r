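Package: preclinseq
Title: Group Sequential Designs for Small Two-Group Preclinical Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Planning and evaluation of group sequential designs for
    small-sample two-group animal experiments.  Computes O'Brien-Fleming,
    Pocock and Haybittle-Peto stopping boundaries by recursive numerical
    integration over the correlated interim test statistics, simulates
    staged experiments under frequentist sequential, default Bayes factor
    and Bayesian credible-interval stopping rules, estimates Monte Carlo
    operating characteristics (power, type I error, expected animal
    consumption, winner's-curse effect-size inflation), calibrates rule
    thresholds to a target type I error by simulation with common random
    numbers, and evaluates the positive predictive value of significant
    findings under prior distributions of true effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
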