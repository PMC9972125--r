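Package: sumclass
Title: Uncertainty Intervals for Summed-Score Classification Accuracy
    and Consistency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Model-based classification accuracy (classification rate,
    sensitivity, specificity) and classification consistency for decisions
    made by cutting a summed score, under a unidimensional linear factor
    model. Indices are computed from the model-implied bivariate normal
    distributions of the summed score with the latent trait and with a
    parallel administration, and their sampling uncertainty is quantified
    by percentile-bootstrap confidence intervals and by Bayesian credible
    intervals from a conjugate Gibbs sampler, with equal-tail and
    highest-posterior-density summaries. A simulation harness scores
    coverage, balance, relative bias and interval width of the three
    interval methods over a factorial design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    coda,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
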