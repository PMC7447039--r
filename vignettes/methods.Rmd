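---
title: "Methods: discount models, Bayesian estimation, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discount models, Bayesian estimation, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`discountfit` implements the analysis chain of a two-group (active
stimulation over the right temporoparietal junction vs. a vertex control
site), two-session (pre/post continuous theta-burst stimulation) study of
delay of gratification: discount-model fitting and comparison for an
intertemporal choice task, nonparametric group statistics on pre-to-post
parameter changes, a response-time contrast analysis of a mental
time-travel task, and an ROI-level GLM/PPI construction for
value-dependent connectivity. Because no participant data ship with the
package, a synthetic cohort generator is a first-class module: it encodes
the statistical structure the analyses assume, and every statistical claim
the test-suite makes is a claim about that generator.

## Choice models

Choices are between a fixed smaller-sooner option (10 CHF today) and a
larger-later reward $A$ (10–20 CHF) at delay $D$ (1–180 days). Three
discount families give the subjective value of the delayed option:

* quasi-hyperbolic ("beta–delta"): $SV = A\,\beta\,\delta^D$, with
  present bias $\beta \in (0,1]$ and daily decay $\delta \in (0,1]$;
* one-parameter hyperbolic: $SV = A/(1 + kD)$, $k$ in day$^{-1}$;
* generalized hyperbolic: $SV = A/(1 + kD)^s$; the exponent $s$ governs
  discounting particularly at long delays and has been related to
  subjective time perception. $s = 1$ recovers the hyperbolic model.

A softmax links value to choice,
$P(\mathrm{LL}) = 1/(1 + e^{-\beta_{temp}(SV - 10)})$, with inverse
temperature $\beta_{temp}$ per CHF. Per-trial probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ before logging so extreme $\beta_{temp}$ values
cannot produce infinite log-likelihoods during sampling.

The discount-curve summary `auc_discount_curve()` integrates
$SV(D)/A$ over $[0, 180]$ days with both axes normalized, so the area
lies in $(0, 1]$ and smaller values mean steeper discounting. The source
analyses do not state their AUC convention; we adopt the Myerson–Green
normalized convention and validate the adaptive quadrature against the
closed form $\big((1+kD)^{1-s}-1\big)/\big(k(1-s)D\big)$ (and its $s=1$
logarithmic limit) to $10^{-8}$.

## Bayesian estimation

Each participant–session–model combination is fitted separately, as in
the original analysis. Sampling is adaptive random-walk Metropolis on the
unconstrained scale (log for positive parameters, logit for unit-interval
parameters): 2 chains of 4,000 samples, the first 1,000 per chain
discarded as burn-in, leaving 6,000 retained draws. During burn-in the
proposal covariance is adapted to the chain history (Haario-style) and
the global scale tuned towards a ~0.30 acceptance rate; at the end of
burn-in the proposal is frozen using the covariance of the second half of
the burn-in draws. Convergence is monitored with split-R-hat; any value
above 1.1 flags the fit (never silently). Sampler correctness is checked
against a dense-grid posterior on a unimodal toy target (total variation
< 0.05 at 6,000 retained draws).

**Priors.** "Noninformative" priors are realized as independent
Normal(0, 2.5) distributions on the unconstrained scale — not the wider
SD-10 variant one might first reach for. The reason is identifiability:
the generalized model's likelihood has a long $k$–$s$ ridge (for small
$kD$, only $k \cdot s$ is constrained), and under an effectively
unbounded prior the posterior median of $s$ can run off by two orders of
magnitude on simulated 162-trial datasets, degrading parameter recovery
and convergence. SD 2.5 still spans roughly four orders of magnitude per
parameter (95% prior mass for $k$: $5\times10^{-5}$–$1.6$/day), far wider
than any behaviourally plausible range.

**Session chaining.** Pre-session fits use these flat priors; the
post-session prior is the pre-session posterior, moment-matched by
independent Gaussians on the unconstrained scale with the scale inflated
by 2 (floored at 0.1). The original description — pre-session "parameter
estimates as priors" — is ambiguous between point estimates and the full
posterior; moment-matching with inflation preserves the information
without over-constraining, and the chained posterior provably relaxes to
the flat-prior posterior as the inflation factor grows (tested at factor
100).

**Model comparison.** `psis_loo()` computes Pareto-smoothed
importance-sampling leave-one-out cross-validation from the pointwise
log-likelihood matrix: per-trial importance weights proportional to the
inverse likelihood, with the largest 20% of weights replaced by quantiles
of a generalized Pareto distribution fitted by probability-weighted
moments. Pareto $k > 0.7$ on any trial attaches a warning. Group-level
ranking uses the arithmetic mean of per-participant LOOIC
($-2\times$elpd), matching the published "mean LOOIC" phrasing; no
standard-error decision rule is applied because only means are reported.
A caveat the tests make explicit: with very small datasets (e.g. 5 trials
and a flat prior) every observation is influential, all Pareto $k$ exceed
0.7, and PSIS is *documented* to be unreliable — the exact-LOO
equivalence check therefore uses a plausibility-centred prior under which
the weights are well behaved.

## The synthetic cohort

`simulate_cohort()` generates the stated world: two groups of 30
participants, two sessions, the full 9 reward × 9 delay cross presented
twice per session (162 choice trials), and a 2×2×2 mental time-travel
design with 9 events per cell (72 per session, 36 per run). Defaults that
the source material fixes are taken from it; everything else is declared
here once:

* Population distributions are log-normal with median $k = 0.01$/day,
  $s = 1$, $\beta_{temp} = 1$/CHF and log-scale SDs 0.5/0.3/0.5 —
  plausible magnitudes, explicitly arbitrary and configurable.
* The stimulation effect multiplies post-session $s$ by `ctbs_effect_s`
  (default 1.3) in the active group only; $k$ and $\beta_{temp}$ are
  unaffected, mirroring the selective published effect.
* Pre-to-post test–retest noise is multiplicative log-normal (SD 0.1) on
  all parameters in both groups; with the effect set to 1 this yields the
  null world used for type-I calibration.
* A per-participant log-normal susceptibility factor (SD 0.5) scales both
  the effect on $s$ and the RT interaction coefficient, inducing the
  positive cross-task correlation the pooled Spearman analysis targets.
* Log response times follow
  $\log RT = b_0 + u_i + 0.04\,[\text{future persp.}] +
  0.04\,[\text{nonpersonal}] + 0.05\,[\text{future event}] -
  0.032\,[\text{post}][\text{future}] + 0.045\,w_i\,[\text{active}][\text{post}][\text{future}] + \varepsilon$,
  with $b_0 = \log 1.5$ s, participant SD 0.15, residual SD 0.25. The
  two interaction coefficients are the published values; the main effects
  are only bounded below (> 0.033) in the source, so 0.04/0.05 were
  chosen once. RTs are truncated at the 3 s response window (~1.4% of
  trials), which biases the recovered interaction down by ~0.003
  log-units — visible in, and accounted for by, the generator tests. No
  omitted responses are generated (omission rates are not reported).

What a green test does **not** establish: the generator draws i.i.d.
log-normal parameters and Gaussian log-RT noise, with no event-level
random effects, no learning or fatigue beyond the built-in session
effect, no response omissions, and no relation between choice noise and
RT. Conclusions about the analysis chain transfer to real data only to
the extent these idealizations do.

## Response-time analysis

The published mixed model (random participant and event intercepts and
slopes) is deliberately replaced by a transparent two-stage summary: per
participant and session, the future-minus-past mean log-RT difference;
per participant, the post-minus-pre change of that difference; between
groups, a Mann-Whitney test. In balanced complete designs the group
difference of these scores *equals* the fixed-effects three-way
regression coefficient (asserted algebraically in the tests), while
remaining auditable without an external mixed-model engine. Event-level
random effects are out of scope.

## Group statistics

`mann_whitney()` uses mid-ranks, the tie-corrected normal approximation,
and no continuity correction — the combination that reproduces the
published Z-to-p mapping (Z = 1.97 → one-tailed p = 0.02). A continuity
flag exists but defaults off, since whether the original software applied
one is unverifiable. The exact-enumeration oracle in the test-suite
bounds the approximation error at 0.062/0.045/0.035 for equal group
sizes 4/5/6. Effect sizes are $r = |Z|/\sqrt{N}$ with $N$ the combined
sample size (60), which reproduces every printed value; the same
convention is used for within-group tests. One-tailed directions are
always explicit arguments, never inferred from data. Baseline
normalization divides post-minus-pre differences by pre values and
refuses zero baselines rather than imputing.

## ROI GLM and PPI

The haemodynamic kernel is the standard double-gamma (response delay 6 s,
undershoot delay 16 s, dispersions 1, ratio 1/6), unit-peak normalized.
Designs are built on a TR/16 microtime grid: 3 s boxcars per condition,
zero-duration delta sticks for motor events, and parametric modulators
mean-centred per condition before convolution (the source is silent on
centring; the convention avoids collinearity with the condition
regressor). Drift removal projects out discrete-cosine components with
periods above 128 s. The PPI regressor is the element-wise product of the
filtered, mean-centred seed series with the convolved value-modulated
regressor — the direct multiplication described in the source, with no
deconvolution step; this diverges from some PPI conventions and is
documented as such. The synthetic BOLD generator couples a target series
to the seed in proportion to the psychological regressor, so a between-
session reduction in coupling yields, on average, a negative post-minus-
pre PPI estimate — the directional signature the replication criterion
checks over 500 replicates.

## Numerical choices and degenerate inputs

* Probability floor $10^{-12}$ before logs; likelihood of an empty trial
  set is an error unless a prior-only fit is requested explicitly.
* Fewer than 20 trials or a single observed choice type: warn-and-fit,
  flagged `weakly_identified`.
* All-identical group samples: $Z = 0$, two-tailed $p = 1$.
* Rank-deficient design matrices are an error naming the collinear
  columns; a noiseless seed series is correctly rejected in the PPI GLM
  because the physiological regressor is then an exact linear combination
  of the task regressors.
* Report tables round half-up to 2 decimals, matching printed values.
* All randomness flows from one master seed through named, hashed
  substreams (< 2^31), so every artefact — CSVs, fits, the pipeline
  report JSON — is byte-reproducible.

## Known limitations

Per-participant estimation only (no joint hierarchical model, as in the
source); no fMRI preprocessing, voxelwise maps, or cluster-level
inference — the imaging module operates on already-extracted ROI series;
the mental time-travel events are abstract factor levels; and the
pipeline's statistical power at default synthetic effect sizes is modest,
as the published effects themselves are (r ≈ 0.23–0.32).
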