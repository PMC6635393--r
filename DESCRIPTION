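Package: puffddm
Title: Pulse-Based Drift-Diffusion Modelling of Somatosensory Evidence Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing a head-fixed mouse decision task in which
    animals accumulate randomly timed left/right whisker air puffs over a cue
    period and report the side with more puffs after a delay. Implements a
    five-parameter pulse accumulator model (leak/instability, accumulator
    diffusion noise, per-pulse sensory noise, bias, lapse) with grid-based
    propagation of the accumulator distribution and an exact Gaussian
    likelihood, maximum-likelihood fitting with random restarts, trial
    subsampling and Hessian-based acceptance filters, BIC model comparison,
    logistic regression of choice on temporally binned evidence with bootstrap
    uncertainty and perturbation-onset-aligned weight averaging, psychometric
    summaries with Jeffreys binomial intervals and four-parameter logistic
    fits, and a synthetic-task generator that emulates the task statistics,
    behavioural agents and impairment interventions (sensation, retention,
    action, lapse-flip) for end-to-end validation on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    pracma,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
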