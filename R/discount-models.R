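#' Discount model parameter sets
#'
#' Construct and validate a parameter set for one of the three discount
#' models used throughout the package: quasi-hyperbolic ("beta-delta"),
#' one-parameter hyperbolic, or generalized hyperbolic. Only the fields
#' belonging to the chosen model may be set.
#'
#' @param model One of `"quasi_hyperbolic"`, `"hyperbolic"`,
#'   `"generalized_hyperbolic"`.
#' @param k Discount rate per day (> 0); hyperbolic and generalized models.
#' @param s Dimensionless scaling exponent (> 0); generalized model only.
#'   Governs the strength of discounting particularly at long delays.
#' @param beta Present-bias weight in (0, 1]; quasi-hyperbolic only.
#' @param delta Per-day exponential decay in (0, 1]; quasi-hyperbolic only.
#' @param beta_temp Softmax inverse temperature per CHF (> 0).
#' @return An object of class `discount_params`.
#' @export
#' @examples
#' discount_params("generalized_hyperbolic", k = 0.01, s = 1.5, beta_temp = 1)
discount_params <- function(model = c("quasi_hyperbolic", "hyperbolic",
                                      "generalized_hyperbolic"),
                            k = NULL, s = NULL, beta = NULL, delta = NULL,
                            beta_temp = NULL) {
  model <- match.arg(model)
  want <- discount_model_fields(model)
  got <- list(k = k, s = s, beta = beta, delta = delta, beta_temp = beta_temp)
  for (f in names(got)) {
    if (f %in% want) {
      if (is.null(got[[f]]))
        stop(sprintf("model '%s' requires parameter '%s'", model, f))
    } else if (!is.null(got[[f]])) {
      stop(sprintf("parameter '%s' does not belong to model '%s'", f, model))
    }
  }
  if (!is.null(k) && (!is.finite(k) || k <= 0))
    stop("parameter 'k' must be > 0")
  if (!is.null(s) && (!is.finite(s) || s <= 0))
    stop("parameter 's' must be > 0")
  if (!is.null(beta) && (beta <= 0 || beta > 1))
    stop("parameter 'beta' must be in (0, 1]")
  if (!is.null(delta) && (delta <= 0 || delta > 1))
    stop("parameter 'delta' must be in (0, 1]")
  if (!is.null(beta_temp) && (!is.finite(beta_temp) || beta_temp <= 0))
    stop("parameter 'beta_temp' must be > 0")
  structure(c(list(model = model), got[want]), class = "discount_params")
}

#' @rdname discount_params
#' @export
discount_model_fields <- function(model) {
  switch(model,
    quasi_hyperbolic = c("beta", "delta", "beta_temp"),
    hyperbolic = c("k", "beta_temp"),
    generalized_hyperbolic = c("k", "s", "beta_temp"),
    stop("unknown model: ", model)
  )
}

#' @export
print.discount_params <- function(x, ...) {
  vals <- unlist(x[setdiff(names(x), "model")])
  cat("<discount_params> model:", x$model, "\n")
  print(round(vals, 6))
  invisible(x)
}

#' Subjective value under quasi-hyperbolic (beta-delta) discounting
#'
#' SV = reward x beta x delta^delay. `beta` captures present bias (the
#' intercept of the discount function at delay 0, applied at all delays);
#' `delta` the per-day exponential decay.
#'
#' @param reward Objective delayed reward in CHF (> 0). Vectorised.
#' @param delay Delay in days (>= 0). Vectorised.
#' @param beta Present bias in (0, 1].
#' @param delta Per-day decay in (0, 1].
#' @return Subjective value in CHF.
#' @export
sv_quasi_hyperbolic <- function(reward, delay, beta, delta) {
  check_pos(reward, "reward"); check_nonneg(delay, "delay")
  if (any(beta <= 0 | beta > 1)) stop("parameter 'beta' must be in (0, 1]")
  if (any(delta <= 0 | delta > 1)) stop("parameter 'delta' must be in (0, 1]")
  reward * beta * delta^delay
}

#' Subjective value under one-parameter hyperbolic discounting
#'
#' SV = reward / (1 + k x delay); `k` (per day) sets the shape of the
#' discount function at all delays.
#'
#' @inheritParams sv_quasi_hyperbolic
#' @param k Discount rate per day (> 0).
#' @return Subjective value in CHF.
#' @export
sv_hyperbolic <- function(reward, delay, k) {
  check_pos(reward, "reward"); check_nonneg(delay, "delay")
  if (any(k <= 0)) stop("parameter 'k' must be > 0")
  reward / (1 + k * delay)
}

#' Subjective value under generalized hyperbolic discounting
#'
#' SV = reward / (1 + k x delay)^s. The scaling exponent `s` determines the
#' strength of discounting particularly at long delays and has been linked
#' to subjective time perception; `s = 1` recovers the one-parameter
#' hyperbolic model.
#'
#' @inheritParams sv_hyperbolic
#' @param s Scaling exponent (> 0).
#' @return Subjective value in CHF.
#' @export
sv_generalized_hyperbolic <- function(reward, delay, k, s) {
  check_pos(reward, "reward"); check_nonneg(delay, "delay")
  if (any(k <= 0)) stop("parameter 'k' must be > 0")
  if (any(s <= 0)) stop("parameter 's' must be > 0")
  reward / (1 + k * delay)^s
}

#' Subjective value for a parameter set
#'
#' Dispatches to the model-specific discount function of a
#' [discount_params()] object.
#'
#' @param params A `discount_params` object.
#' @param reward,delay Vectors of LL rewards (CHF) and delays (days).
#' @return Subjective values in CHF.
#' @export
subjective_value <- function(params, reward, delay) {
  stopifnot(inherits(params, "discount_params"))
  switch(params$model,
    quasi_hyperbolic =
      sv_quasi_hyperbolic(reward, delay, params$beta, params$delta),
    hyperbolic = sv_hyperbolic(reward, delay, params$k),
    generalized_hyperbolic =
      sv_generalized_hyperbolic(reward, delay, params$k, params$s)
  )
}

#' Softmax probability of choosing the larger-later option
#'
#' P(LL) = 1 / (1 + exp(-beta_temp x (SV_LL - ss_amount))). The
#' smaller-sooner amount defaults to the 10 CHF immediate option of the
#' task design. Numerically stable over |argument| up to ~700 by using
#' `stats::plogis`.
#'
#' @param sv_ll Subjective value of the LL option (CHF). Vectorised.
#' @param beta_temp Inverse temperature per CHF (> 0).
#' @param ss_amount Immediate smaller-sooner amount in CHF (default 10).
#' @return Probability of choosing LL.
#' @export
choice_prob <- function(sv_ll, beta_temp, ss_amount = 10) {
  if (any(beta_temp <= 0)) stop("parameter 'beta_temp' must be > 0")
  stats::plogis(beta_temp * (sv_ll - ss_amount))
}

# Per-trial probabilities are clamped to [PROB_FLOOR, 1 - PROB_FLOOR] before
# log to keep the likelihood finite under extreme beta_temp during MCMC.
PROB_FLOOR <- 1e-12

#' Bernoulli choice log-likelihood for a discount model
#'
#' Sums log P(observed choice) over trials under the softmax rule, with the
#' per-trial probability clamped to `[1e-12, 1 - 1e-12]` before taking logs.
#' The pointwise vector is returned as well; it is the input that
#' [psis_loo()] needs.
#'
#' @param params A [discount_params()] object.
#' @param trials Data frame with columns `reward_ll`, `delay`, `choice`
#'   (`"LL"`/`"SS"`).
#' @param ss_amount Smaller-sooner amount (CHF), default 10.
#' @return List with `total` (scalar, nats) and `pointwise` (per-trial
#'   log-likelihood vector).
#' @export
choice_loglik <- function(params, trials, ss_amount = 10) {
  if (nrow(trials) == 0L) stop("trials must be non-empty")
  sv <- subjective_value(params, trials$reward_ll, trials$delay)
  p <- choice_prob(sv, params$beta_temp, ss_amount)
  p <- pmin(pmax(p, PROB_FLOOR), 1 - PROB_FLOOR)
  ll <- ifelse(trials$choice == "LL", log(p), log1p(-p))
  list(total = sum(ll), pointwise = ll)
}

#' Normalized area under the generalized hyperbolic discount curve
#'
#' Integrates the discount fraction SV(d)/reward over delay, with both axes
#' normalized (delay by `max_delay`, value by the reward), so the result
#' lies in (0, 1]: 1 means no discounting, smaller values steeper
#' discounting / more impulsive preferences (Myerson-Green convention).
#' Computed by adaptive quadrature; a closed form exists for any s and is
#' used by the test-suite oracle.
#'
#' @param params A [discount_params()] object with
#'   `model = "generalized_hyperbolic"`.
#' @param max_delay Upper delay bound in days (default 180, the longest
#'   delay of the task design).
#' @return Dimensionless AUC in (0, 1].
#' @export
auc_discount_curve <- function(params, max_delay = 180) {
  stopifnot(inherits(params, "discount_params"))
  if (params$model != "generalized_hyperbolic")
    stop("auc_discount_curve requires the generalized hyperbolic model")
  k <- params$k; s <- params$s
  val <- stats::integrate(function(d) (1 + k * d)^(-s), 0, max_delay,
                          rel.tol = 1e-10)$value
  val / max_delay
}

check_pos <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) stop(sprintf("'%s' must be > 0", name))
}
check_nonneg <- function(x, name) {
  if (any(!is.finite(x) | x < 0)) stop(sprintf("'%s' must be >= 0", name))
}
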