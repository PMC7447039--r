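# Per-participant Bayesian estimation of discount models, session-chained
# priors, LOO model comparison and the parameter-recovery harness.

default_init_theta <- function(model) {
  switch(model,
    quasi_hyperbolic = c(stats::qlogis(0.9), stats::qlogis(0.98), 0),
    hyperbolic = c(log(0.01), 0),
    generalized_hyperbolic = c(log(0.01), 0, 0))
}

# Fast closure computing the Bernoulli choice log-likelihood at an
# unconstrained parameter vector; used inside the MCMC loop.
make_loglik_fn <- function(model, trials, ss_amount = 10) {
  if (nrow(trials) == 0L) return(function(theta) 0)
  reward <- trials$reward_ll; delay <- trials$delay
  y <- as.numeric(trials$choice == "LL")
  clamp <- function(p) pmin(pmax(p, PROB_FLOOR), 1 - PROB_FLOOR)
  switch(model,
    generalized_hyperbolic = function(theta) {
      sv <- reward * (1 + exp(theta[1]) * delay)^(-exp(theta[2]))
      p <- clamp(stats::plogis(exp(theta[3]) * (sv - ss_amount)))
      sum(y * log(p) + (1 - y) * log1p(-p))
    },
    hyperbolic = function(theta) {
      sv <- reward / (1 + exp(theta[1]) * delay)
      p <- clamp(stats::plogis(exp(theta[2]) * (sv - ss_amount)))
      sum(y * log(p) + (1 - y) * log1p(-p))
    },
    quasi_hyperbolic = function(theta) {
      sv <- reward * stats::plogis(theta[1]) * stats::plogis(theta[2])^delay
      p <- clamp(stats::plogis(exp(theta[3]) * (sv - ss_amount)))
      sum(y * log(p) + (1 - y) * log1p(-p))
    })
}

# Vectorised pointwise log-likelihood over all retained draws:
# returns a draws x trials matrix.
pointwise_loglik_matrix <- function(model, draws, trials, ss_amount = 10) {
  if (nrow(trials) == 0L) return(matrix(0, nrow(draws), 0))
  reward <- trials$reward_ll; delay <- trials$delay
  y <- trials$choice == "LL"
  if (model == "generalized_hyperbolic") {
    k <- exp(draws[, 1]); s <- exp(draws[, 2]); bt <- exp(draws[, 3])
    sv <- exp(sweep(log1p(outer(k, delay)), 1, -s, `*`))
    sv <- sweep(sv, 2, reward, `*`)
  } else if (model == "hyperbolic") {
    k <- exp(draws[, 1]); bt <- exp(draws[, 2])
    sv <- sweep(1 / (1 + outer(k, delay)), 2, reward, `*`)
  } else {
    beta <- stats::plogis(draws[, 1]); delta <- stats::plogis(draws[, 2])
    bt <- exp(draws[, 3])
    sv <- beta * exp(outer(log(delta), delay))
    sv <- sweep(sv, 2, reward, `*`)
  }
  p <- stats::plogis(sweep(sv - ss_amount, 1, bt, `*`))
  p <- pmin(pmax(p, PROB_FLOOR), 1 - PROB_FLOOR)
  ll <- log(p)
  if (any(!y)) ll[, !y] <- log1p(-p[, !y, drop = FALSE])
  ll
}

#' Fit a discount model to one participant-session by MCMC
#'
#' Adaptive random-walk Metropolis on the unconstrained scale (log for
#' positive parameters, logit for the unit-interval parameters of the
#' quasi-hyperbolic model). Defaults are 2 chains of 4,000 samples with the
#' first 1,000 per chain discarded as burn-in, leaving 6,000 retained
#' draws. Non-convergence (any split-R-hat > 1.1) is flagged on the result,
#' never silent.
#'
#' @param trials Choice data frame (`reward_ll`, `delay`, `choice`).
#'   Fewer than 20 trials, or trials with only one choice type, produce a
#'   warn-and-fit flag (`weakly_identified`).
#' @param model Model name.
#' @param priors A `prior_spec`, e.g. [flat_priors()] or the output of
#'   [posterior_to_prior()] for session chaining.
#' @param control An [mcmc_control()].
#' @param seed Seed; fits are reproducible given (seed, data, control).
#' @param allow_empty Allow zero trials (prior-only fit, used in tests).
#' @param ss_amount Smaller-sooner amount (CHF).
#' @return Object of class `discount_fit` with elements `draws`
#'   (retained draws x parameters, unconstrained scale), `chain_id`,
#'   `pointwise_loglik`, `point_estimates` (posterior medians, natural
#'   scale), `rhat`, `accept_rate`, `converged`, `weakly_identified`.
#' @export
fit_discount_model <- function(trials, model, priors = flat_priors(model),
                               control = mcmc_control(), seed = 1L,
                               allow_empty = FALSE, ss_amount = 10) {
  stopifnot(inherits(priors, "prior_spec"), priors$model == model)
  weakly <- FALSE
  if (nrow(trials) == 0L) {
    if (!allow_empty) stop("trials must be non-empty (use allow_empty for prior-only fits)")
  } else {
    n_ll <- sum(trials$choice == "LL")
    if (nrow(trials) < 20L || n_ll == 0L || n_ll == nrow(trials)) {
      weakly <- TRUE
      warning("few trials or a single choice type: parameters weakly identified; fitting anyway")
    }
  }
  loglik_fn <- make_loglik_fn(model, trials, ss_amount)
  log_post <- function(theta) loglik_fn(theta) + log_prior(priors, theta)
  nm <- unconstrained_names(model)
  d <- length(nm)
  informative <- all(priors$sd < 5)
  base_init <- if (informative) priors$mean else default_init_theta(model)
  set.seed(seed)
  chains <- vector("list", control$chains)
  acc <- numeric(control$chains)
  for (c_i in seq_len(control$chains)) {
    init <- base_init + stats::rnorm(d, 0, 0.3)
    res <- run_rwm_chain(log_post, init, control)
    chains[[c_i]] <- res$draws
    acc[c_i] <- res$accept_rate
  }
  rhat <- if (control$chains >= 2) split_rhat(chains) else rep(NA_real_, d)
  draws <- do.call(rbind, chains)
  colnames(draws) <- nm
  chain_id <- rep(seq_len(control$chains), each = control$iter - control$burnin)
  converged <- all(is.na(rhat)) || all(rhat < 1.1, na.rm = TRUE)
  if (!converged)
    warning(sprintf("non-convergence: max split-R-hat = %.3f", max(rhat, na.rm = TRUE)))
  med <- apply(draws, 2, stats::median)
  point <- theta_to_params(model, med)
  ll <- pointwise_loglik_matrix(model, draws, trials, ss_amount)
  structure(list(model = model, draws = draws, chain_id = chain_id,
                 pointwise_loglik = ll,
                 point_estimates = point,
                 rhat = stats::setNames(rhat, nm),
                 accept_rate = mean(acc), converged = converged,
                 weakly_identified = weakly, priors = priors,
                 control = control, seed = seed, n_trials = nrow(trials)),
            class = "discount_fit")
}

#' @export
print.discount_fit <- function(x, ...) {
  cat(sprintf("<discount_fit> %s: %d trials, %d draws, accept %.2f, max R-hat %.3f%s\n",
              x$model, x$n_trials, nrow(x$draws), x$accept_rate,
              max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$point_estimates)
  invisible(x)
}

#' Turn a pre-session posterior into a post-session prior
#'
#' Moment-matches independent Gaussians on the unconstrained scale to the
#' posterior draws and inflates each scale by `inflate` (default 2) so the
#' chained prior informs without over-constraining; scales are floored at
#' `sd_floor` to guard against degenerate posteriors. Refuses
#' non-converged fits.
#'
#' @param fit A converged `discount_fit`.
#' @param inflate Multiplicative SD inflation factor.
#' @param sd_floor Lower bound on the prior SD.
#' @return A `prior_spec` usable by [fit_discount_model()].
#' @export
posterior_to_prior <- function(fit, inflate = 2, sd_floor = 0.1) {
  stopifnot(inherits(fit, "discount_fit"))
  if (!fit$converged) stop("refusing to chain a non-converged fit into a prior")
  m <- colMeans(fit$draws)
  s <- pmax(apply(fit$draws, 2, stats::sd) * inflate, sd_floor)
  structure(list(model = fit$model, names = colnames(fit$draws),
                 mean = m, sd = s), class = "prior_spec")
}

#' Mean-LOOIC model comparison table
#'
#' Runs [psis_loo()] on every fit and averages LOOIC per model across
#' participants — the group-level "mean LOOIC" used for model ranking
#' (lower is better).
#'
#' @param fits_by_model Named list (one element per model) of lists of
#'   `discount_fit` objects.
#' @return Data frame with `model`, `mean_looic`, `n_fits`, sorted best
#'   first.
#' @export
compare_models_looic <- function(fits_by_model) {
  rows <- lapply(names(fits_by_model), function(m) {
    loos <- vapply(fits_by_model[[m]],
                   function(f) suppressWarnings(psis_loo(f$pointwise_loglik))$looic,
                   0)
    data.frame(model = m, mean_looic = mean(loos),
               n_fits = length(loos), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mean_looic), , drop = FALSE]
}

#' Parameter-recovery harness
#'
#' For each row of `true_grid`: simulate choices under the true parameters
#' on the given design, fit the model, and record posterior medians.
#' Summaries are the Spearman rank correlation between true and recovered
#' values and the median absolute relative error, per parameter.
#'
#' @param true_grid Data frame of true parameter values (natural scale),
#'   columns matching the model's parameter fields.
#' @param design Choice design from [make_choice_design()].
#' @param model Model name.
#' @param control An [mcmc_control()].
#' @param seed Seed.
#' @return List of class `recovery_report` with `results` (true and
#'   recovered values) and `summary` (rank correlation, median absolute
#'   relative error per parameter).
#' @export
recover_parameters <- function(true_grid, design,
                               model = "generalized_hyperbolic",
                               control = mcmc_control(), seed = 1L) {
  stopifnot(nrow(true_grid) > 0)
  fields <- discount_model_fields(model)
  stopifnot(all(fields %in% names(true_grid)))
  res <- true_grid[, fields, drop = FALSE]
  for (f in fields) res[[paste0(f, "_hat")]] <- NA_real_
  for (i in seq_len(nrow(true_grid))) {
    par <- do.call(discount_params, c(list(model = model),
                                      as.list(true_grid[i, fields])))
    ch <- simulate_choices(par, design, seed = seed + i)
    fit <- suppressWarnings(fit_discount_model(ch, model, control = control,
                                               seed = seed + 10000L + i))
    for (f in fields) res[[paste0(f, "_hat")]][i] <- fit$point_estimates[[f]]
  }
  summ <- do.call(rbind, lapply(fields, function(f) {
    tr <- res[[f]]; est <- res[[paste0(f, "_hat")]]
    data.frame(parameter = f,
               rank_cor = if (stats::sd(tr) == 0) NA_real_ else
                 stats::cor(tr, est, method = "spearman"),
               median_abs_rel_err = stats::median(abs(est - tr) / abs(tr)),
               stringsAsFactors = FALSE)
  }))
  structure(list(results = res, summary = summ), class = "recovery_report")
}

#' Persist a fit as JSON (point estimates + diagnostics) and a long-format
#' draws CSV
#'
#' @param fit A `discount_fit`.
#' @param dir Output directory.
#' @param label File stem, e.g. `"P001_pre_generalized"`.
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir, label) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(model = fit$model,
               point_estimates = fit$point_estimates[
                 discount_model_fields(fit$model)],
               rhat = as.list(fit$rhat), accept_rate = fit$accept_rate,
               converged = fit$converged,
               weakly_identified = fit$weakly_identified,
               n_trials = fit$n_trials, seed = fit$seed)
  jpath <- file.path(dir, paste0(label, ".json"))
  jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  long <- data.frame(chain = rep(fit$chain_id, ncol(fit$draws)),
                     iteration = rep(seq_len(nrow(fit$draws)), ncol(fit$draws)),
                     parameter = rep(colnames(fit$draws), each = nrow(fit$draws)),
                     value = as.vector(fit$draws))
  cpath <- file.path(dir, paste0(label, "_draws.csv"))
  utils::write.csv(long, cpath, row.names = FALSE)
  invisible(c(json = jpath, draws = cpath))
}
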