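# End-to-end replication pipeline: simulate cohort -> fit three discount
# models per participant-session (post-session chained priors) -> LOOIC
# comparison -> stimulation group statistics -> RT contrast analysis ->
# cross-task correlation -> PPI recovery demo -> consolidated report.
# Every stage caches its outputs in the run directory and is skipped when
# they already exist, so runs are idempotent and resumable; all randomness
# flows from the master seed through named substreams.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()]; its `seed` is overwritten by the
#'   pipeline master seed.
#' @param mcmc An [mcmc_control()].
#' @param models Models to fit and compare.
#' @param bonferroni_m Number of comparisons for corrected p-values in the
#'   report (default 2, the two value-coding ROIs convention).
#' @param ppi Settings for the PPI demonstration: replicates, pre/post
#'   coupling, events and scans per session, noise SD.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            mcmc = mcmc_control(),
                            models = c("generalized_hyperbolic", "hyperbolic",
                                       "quasi_hyperbolic"),
                            bonferroni_m = 2,
                            ppi = list(replicates = 500, coupling_pre = 0.4,
                                       coupling_post = 0.1, n_events = 40,
                                       n_scans = 200, tr = 2.438,
                                       noise_sd = 1),
                            seed = 1L) {
  structure(list(cohort = cohort, mcmc = mcmc, models = models,
                 bonferroni_m = bonferroni_m, ppi = ppi,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Reduced-scale pipeline configuration for quick runs
#'
#' Same stated world, scaled down (fewer participants, shorter chains,
#' fewer PPI replicates) so a full run completes in well under a minute.
#' @param seed Master seed.
#' @export
pipeline_config_fast <- function(seed = 1L) {
  pipeline_config(
    cohort = cohort_config(n_per_group = 4, repeats_per_session = 1,
                           seed = seed),
    mcmc = mcmc_control(chains = 2, iter = 600, burnin = 200),
    ppi = list(replicates = 25, coupling_pre = 0.4, coupling_post = 0.1,
               n_events = 20, n_scans = 100, tr = 2.438, noise_sd = 1),
    seed = seed)
}

stage_cached <- function(path, compute, reader, writer) {
  if (file.exists(path)) return(reader(path))
  value <- compute()
  writer(value, path)
  value
}

#' Fit all discount models to every participant-session of a cohort
#'
#' Pre-session fits use flat priors; post-session fits use the same
#' participant's pre-session posterior, moment-matched and inflated, as
#' prior (session chaining). Returns per-fit posterior medians, the
#' normalized discount-curve AUC (generalized model), LOOIC, and
#' convergence flags.
#'
#' @param choices Cohort choice table.
#' @param models Character vector of models.
#' @param control An [mcmc_control()].
#' @param seed Seed.
#' @return Data frame, one row per participant x session x model.
#' @export
fit_cohort <- function(choices, models = c("generalized_hyperbolic",
                                           "hyperbolic", "quasi_hyperbolic"),
                       control = mcmc_control(), seed = 1L) {
  ids <- unique(choices$participant_id)
  rows <- list()
  for (id in ids) {
    sub <- choices[choices$participant_id == id, ]
    for (model in models) {
      pre_trials <- sub[sub$session == "pre", ]
      post_trials <- sub[sub$session == "post", ]
      fit_pre <- suppressWarnings(fit_discount_model(
        pre_trials, model, control = control,
        seed = substream_seed(seed, paste0("fit:", id, ":pre:", model))))
      prior_post <- if (fit_pre$converged) posterior_to_prior(fit_pre)
                    else flat_priors(model)
      fit_post <- suppressWarnings(fit_discount_model(
        post_trials, model, priors = prior_post, control = control,
        seed = substream_seed(seed, paste0("fit:", id, ":post:", model))))
      for (sess in c("pre", "post")) {
        fit <- if (sess == "pre") fit_pre else fit_post
        est <- fit$point_estimates
        loo <- suppressWarnings(psis_loo(fit$pointwise_loglik))
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = id, group = sub$group[1], session = sess,
          model = model,
          k = est$k %||% NA_real_, s = est$s %||% NA_real_,
          beta = est$beta %||% NA_real_, delta = est$delta %||% NA_real_,
          beta_temp = est$beta_temp,
          auc = if (model == "generalized_hyperbolic")
            auc_discount_curve(est) else NA_real_,
          looic = loo$looic, converged = fit$converged,
          weakly_identified = fit$weakly_identified,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory; intermediates and the report are written
#'   here. Existing intermediates are reused (delete a file to recompute
#'   it).
#' @return The report, invisibly (also written as `report.json` and
#'   `report.txt`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config$cohort$seed <- substream_seed(config$seed, "cohort")

  # stage 1: synthetic cohort ------------------------------------------------
  ch_path <- file.path(out_dir, "choices.csv")
  if (!file.exists(ch_path)) write_cohort(simulate_cohort(config$cohort), out_dir)
  choices <- read_choices(ch_path)
  rts <- utils::read.csv(file.path(out_dir, "rts.csv"), stringsAsFactors = FALSE)

  # stage 2: per-participant model fits --------------------------------------
  fits <- stage_cached(file.path(out_dir, "fits.csv"),
    function() fit_cohort(choices, config$models, config$mcmc,
                          seed = substream_seed(config$seed, "fits")),
    function(p) utils::read.csv(p, stringsAsFactors = FALSE),
    function(v, p) utils::write.csv(v, p, row.names = FALSE))

  # stage 3: model comparison ------------------------------------------------
  loo_tab <- stats::aggregate(looic ~ model, data = fits, FUN = mean)
  names(loo_tab)[2] <- "mean_looic"
  loo_tab <- loo_tab[order(loo_tab$mean_looic), ]

  # stage 4: stimulation group statistics on the generalized model -----------
  gen <- fits[fits$model == "generalized_hyperbolic", ]
  gtests <- list(
    delta_s = ctbs_group_test(gen, "s", tail = "one", direction = "greater"),
    delta_s_baseline = ctbs_group_test(gen, "s", normalize = "baseline",
                                       tail = "one", direction = "greater"),
    delta_k = ctbs_group_test(gen, "k", tail = "one", direction = "greater"),
    delta_auc = ctbs_group_test(gen, "auc", tail = "one", direction = "less"),
    delta_beta_temp = ctbs_group_test(gen, "beta_temp", tail = "two"))

  # stage 5: mental time-travel RT contrasts ---------------------------------
  contrasts <- suppressWarnings(rt_interaction_scores(rts))
  rt_test <- interaction_test(contrasts, tail = "one", direction = "greater")

  # stage 6: cross-task correlation (pooled groups, one-tailed) --------------
  delta_s_scores <- attr(gtests$delta_s, "scores")
  delta_s_scores$delta_s <- delta_s_scores$score
  xcor <- crosstask_correlation(contrasts, delta_s_scores,
                                tail = "one", direction = "greater")

  # stage 7: PPI coupling-reduction demo -------------------------------------
  pp <- config$ppi
  ppi_diff <- ppi_coupling_change(pp$replicates, pp$coupling_pre,
                                  pp$coupling_post, pp$n_events, pp$n_scans,
                                  pp$tr, pp$noise_sd,
                                  seed = substream_seed(config$seed, "ppi"))

  gt_json <- function(g) list(u = g$u, z = g$z, p = g$p, r = g$r,
                              n_total = g$n_total, tail = g$tail)
  report <- list(
    seed = config$seed,
    cohort = list(n_per_group = config$cohort$n_per_group,
                  ctbs_effect_s = config$cohort$ctbs_effect_s,
                  repeats_per_session = config$cohort$repeats_per_session),
    model_comparison = loo_tab,
    winning_model = loo_tab$model[1],
    group_tests = lapply(gtests, gt_json),
    rt_interaction = gt_json(rt_test),
    rt_median_score_rtpj =
      stats::median(contrasts$score[contrasts$group == "rTPJ"]),
    rt_median_score_vertex =
      stats::median(contrasts$score[contrasts$group == "vertex"]),
    crosstask = list(rho = xcor$rho, p = xcor$p, n = xcor$n),
    ppi = list(replicates = pp$replicates,
               mean_post_minus_pre = mean(ppi_diff),
               prop_negative = mean(ppi_diff < 0)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(format_report(report), file.path(out_dir, "report.txt"))
  invisible(report)
}

# Replicated two-session PPI simulation: returns per-replicate
# post-minus-pre interaction estimates under a coupling reduction.
#' @rdname run_pipeline
#' @param replicates Number of replicate session pairs.
#' @param coupling_pre,coupling_post Value-dependent coupling per session.
#' @param n_events,n_scans,tr,noise_sd Session geometry and noise.
#' @param seed Seed.
#' @export
ppi_coupling_change <- function(replicates, coupling_pre, coupling_post,
                                n_events = 40, n_scans = 200, tr = 2.438,
                                noise_sd = 1, seed = 1L) {
  one_session <- function(coupling, label) {
    s <- substream_seed(seed, label)
    ev <- make_event_table(n_events,
      modulator = stats::runif(n_events, 2, 20), seed = s)
    des <- build_design(ev, tr = tr, n_scans = n_scans)
    sim <- simulate_bold(des,
      seed_effects = c(decision = 1, decision_x_mod = 0.5),
      target_effects = c(decision = 1, decision_x_mod = 0.3),
      coupling = coupling, noise_sd = noise_sd, seed = s %% 2000000000L + 1L)
    ppi_estimate(sim$seed, sim$target, des)
  }
  vapply(seq_len(replicates), function(r) {
    one_session(coupling_post, paste0("ppi:", r, ":post")) -
      one_session(coupling_pre, paste0("ppi:", r, ":pre"))
  }, 0)
}

format_report <- function(rep) {
  g <- function(x) sprintf("U = %.1f, Z = %.2f, p = %.3f (%s-tailed), r = %.2f",
                           x$u, x$z, x$p, x$tail, x$r)
  c("== discountfit pipeline report ==",
    sprintf("seed: %d | n/group: %d | ctbs effect on s: %.2f",
            rep$seed, rep$cohort$n_per_group, rep$cohort$ctbs_effect_s),
    "",
    "Model comparison (mean LOOIC, lower = better):",
    sprintf("  %-24s %8.1f", rep$model_comparison$model,
            rep$model_comparison$mean_looic),
    sprintf("winning model: %s", rep$winning_model),
    "",
    "Stimulation group tests (rTPJ vs vertex, post - pre):",
    sprintf("  %-18s %s", names(rep$group_tests),
            vapply(rep$group_tests, g, "")),
    "",
    sprintf("RT interaction (group x session x event time): %s",
            g(rep$rt_interaction)),
    sprintf("  median interaction score rTPJ %.4f vs vertex %.4f",
            rep$rt_median_score_rtpj, rep$rt_median_score_vertex),
    sprintf("Cross-task Spearman rho = %.3f, p = %.3f (n = %d)",
            rep$crosstask$rho, rep$crosstask$p, rep$crosstask$n),
    sprintf("PPI post-minus-pre coupling estimate: mean %.3f (%.0f%% negative, %d replicates)",
            rep$ppi$mean_post_minus_pre, 100 * rep$ppi$prop_negative,
            rep$ppi$replicates))
}
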