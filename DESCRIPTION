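Package: discountfit
Title: Delay Discounting, Mental Time Travel, and ROI Connectivity Analysis
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing two-group, two-session brain stimulation
    studies of delay of gratification. Implements quasi-hyperbolic,
    one-parameter hyperbolic and generalized hyperbolic discount models with
    softmax choice, per-participant Bayesian estimation by adaptive MCMC with
    session-chained priors, Pareto-smoothed importance-sampling leave-one-out
    model comparison (LOOIC), discount-curve area under the curve, a
    synthetic cohort generator (choices, log-normal response times,
    stimulation effects), nonparametric group statistics (Mann-Whitney U with
    effect size r = Z/sqrt(N), Bonferroni correction, Spearman correlation),
    a two-stage response-time contrast analysis of mental time-travel data,
    and ROI-level GLM and psychophysiological-interaction (PPI) construction
    with a canonical double-gamma HRF and discrete-cosine high-pass filter.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
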