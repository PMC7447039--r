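# ROI-level GLM and psychophysiological interaction (PPI) construction:
# canonical double-gamma HRF, event-table design matrices with mean-centered
# parametric modulators, discrete-cosine high-pass filtering, least-squares
# fitting, and a synthetic BOLD generator for recovery testing.

#' Canonical double-gamma haemodynamic response function
#'
#' Standard parameterization: response gamma with delay 6 s, undershoot
#' gamma with delay 16 s, dispersions 1, undershoot ratio 1/6. The kernel
#' is sampled on the given time step and normalized to unit peak; it peaks
#' near 5 s and is negative in the undershoot region.
#'
#' @param tr Sampling step in seconds (> 0); use the scan TR for a
#'   scan-grid kernel or a finer step for microtime convolution.
#' @param duration Kernel length in seconds (default 32).
#' @return Numeric kernel sampled at `seq(0, duration, by = tr)`.
#' @export
canonical_hrf <- function(tr, duration = 32) {
  stopifnot(tr > 0, duration > tr)
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Build an ROI-level design matrix from an event table
#'
#' Each condition contributes a boxcar regressor (onset + duration,
#' default 3 s events; zero-duration events become delta sticks, e.g.
#' motor responses), convolved with the canonical HRF on a microtime grid
#' (`tr/16`) and down-sampled to scan onsets. A `modulator` column adds,
#' per condition that carries non-missing values, a parametric regressor:
#' the modulator is mean-centered across that condition's events before
#' multiplying the boxcar (SPM convention; avoids collinearity with the
#' condition regressor). An intercept column is always included.
#' Overlapping duplicate events sum.
#'
#' @param events Data frame with columns `onset_s`, `condition`, and
#'   optionally `duration_s` (default 3) and `modulator`.
#' @param tr Repetition time in seconds.
#' @param n_scans Number of scans.
#' @param microtime_bins Microtime bins per TR (default 16).
#' @return Object of class `design_matrix`: list with `X` (n_scans x
#'   columns), `tr`, `n_scans`, `psych_cols` (names of modulator columns).
#' @export
build_design <- function(events, tr, n_scans, microtime_bins = 16) {
  stopifnot(tr > 0, n_scans > 0, nrow(events) > 0,
            all(c("onset_s", "condition") %in% names(events)))
  if (!"duration_s" %in% names(events)) events$duration_s <- 3
  if (any(events$onset_s < 0 | events$onset_s >= n_scans * tr))
    stop("event onsets must lie within the scan window")
  dt <- tr / microtime_bins
  n_fine <- n_scans * microtime_bins
  h <- canonical_hrf(dt)
  scan_idx <- (seq_len(n_scans) - 1L) * microtime_bins + 1L
  stick <- function(rows, amplitude) {
    g <- numeric(n_fine)
    for (r in rows) {
      a <- amplitude[match(r, rows)]
      i0 <- floor(events$onset_s[r] / dt) + 1L
      if (events$duration_s[r] <= 0) {
        g[i0] <- g[i0] + a
      } else {
        i1 <- min(n_fine, i0 + max(1L, round(events$duration_s[r] / dt)) - 1L)
        g[i0:i1] <- g[i0:i1] + a
      }
    }
    g
  }
  conv_sample <- function(g) {
    x <- stats::convolve(g, rev(h), type = "open")[seq_len(n_fine)]
    x[scan_idx]
  }
  cols <- list(intercept = rep(1, n_scans))
  psych_cols <- character(0)
  for (cond in unique(events$condition)) {
    rows <- which(events$condition == cond)
    cols[[cond]] <- conv_sample(stick(rows, rep(1, length(rows))))
    if ("modulator" %in% names(events) &&
        any(!is.na(events$modulator[rows]))) {
      mod <- events$modulator[rows]
      mod <- mod - mean(mod)                 # mean-center per condition
      nm <- paste0(cond, "_x_mod")
      cols[[nm]] <- conv_sample(stick(rows, mod))
      psych_cols <- c(psych_cols, nm)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(X = X, tr = tr, n_scans = n_scans, psych_cols = psych_cols),
            class = "design_matrix")
}

#' Discrete-cosine high-pass filter
#'
#' Removes slow drift by projecting out the DCT basis functions with
#' period longer than `cutoff` seconds (plus the constant), the standard
#' fMRI high-pass (default cutoff 128 s).
#'
#' @param series Numeric BOLD vector.
#' @param tr Repetition time in seconds.
#' @param cutoff Cutoff period in seconds (> 2 TR).
#' @return Filtered, zero-mean series.
#' @export
highpass_filter <- function(series, tr, cutoff = 128) {
  stopifnot(cutoff > 2 * tr)
  n <- length(series)
  k_max <- floor(2 * n * tr / cutoff)
  t <- seq_len(n) - 1
  B <- cbind(1, if (k_max >= 1)
    sapply(seq_len(k_max), function(k) cos(pi * (2 * t + 1) * k / (2 * n))))
  series - B %*% solve(crossprod(B), crossprod(B, series))
}

#' Least-squares GLM fit of an ROI time series
#'
#' @param y Numeric BOLD vector (or `RoiSeries`-like list with `values`).
#' @param design A `design_matrix` or plain numeric matrix with unique
#'   column names. Must have full column rank and fewer columns than
#'   scans; rank deficiency is an explicit error naming the collinear
#'   columns.
#' @return Object of class `roi_glm`: `coefficients`, `se`, `sigma2`,
#'   `df_residual`, `xtx_inv`.
#' @export
fit_glm <- function(y, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (is.list(y) && !is.null(y$values)) y <- y$values
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X))
  if (anyDuplicated(colnames(X))) stop("design matrix column names must be unique")
  if (nrow(X) <= ncol(X)) stop("need more scans than design columns")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, se = sqrt(sigma2 * diag(xtx_inv)),
                 sigma2 = sigma2, df_residual = df, xtx_inv = xtx_inv),
            class = "roi_glm")
}

#' Evaluate a contrast on a fitted ROI GLM
#'
#' @param fit A `roi_glm`.
#' @param weights Named (or positional) contrast weight vector.
#' @return List with `estimate`, `se`, `t`.
#' @export
glm_contrast <- function(fit, weights) {
  b <- fit$coefficients
  w <- numeric(length(b)); names(w) <- names(b)
  if (is.null(names(weights))) {
    stopifnot(length(weights) == length(b))
    w[] <- weights
  } else {
    stopifnot(all(names(weights) %in% names(b)))
    w[names(weights)] <- weights
  }
  est <- sum(w * b)
  se <- sqrt(fit$sigma2 * drop(t(w) %*% fit$xtx_inv %*% w))
  list(estimate = est, se = se, t = est / se)
}

#' Construct a PPI regressor
#'
#' Element-wise product of the (high-pass filtered, mean-centered)
#' physiological seed series with the psychological (value-modulated)
#' regressor — the direct multiplication construction, without a
#' deconvolution step. Returned together with both main effects, which
#' must accompany the interaction in the PPI GLM.
#'
#' @param seed Seed ROI series (already filtered); will be mean-centered.
#' @param psych Psychological regressor of equal length.
#' @return List with `ppi`, `phys` (centered seed), `psych`.
#' @export
ppi_regressor <- function(seed, psych) {
  if (is.list(seed) && !is.null(seed$values)) seed <- seed$values
  if (length(seed) != length(psych))
    stop("seed and psychological regressor lengths differ")
  phys <- seed - mean(seed)
  list(ppi = phys * psych, phys = phys, psych = psych)
}

#' Event table with Poisson-jittered inter-trial intervals
#'
#' Trials of `duration_s` seconds separated by ITIs drawn from a Poisson
#' distribution with mean 2 s, clamped to [1, 11] s, as in the scanner
#' task design.
#'
#' @param n_events Number of events.
#' @param modulator Optional per-event modulator values (e.g. subjective
#'   LL values).
#' @param duration_s Event duration (default 3 s).
#' @param seed Seed.
#' @return Event data frame for [build_design()].
#' @export
make_event_table <- function(n_events, modulator = NULL, duration_s = 3,
                             seed = 1L) {
  set.seed(seed)
  iti <- pmin(pmax(stats::rpois(n_events, 2), 1), 11)
  onsets <- cumsum(iti + duration_s) - duration_s
  ev <- data.frame(onset_s = onsets, duration_s = duration_s,
                   condition = "decision", stringsAsFactors = FALSE)
  if (!is.null(modulator)) {
    stopifnot(length(modulator) == n_events)
    ev$modulator <- modulator
  }
  ev
}

#' Simulate coupled seed and target BOLD series
#'
#' The seed responds to the design (`seed_effects`); the target responds
#' to the design (`target_effects`) plus `coupling` times the product of
#' the centered seed series with the psychological regressor — i.e.
#' value-dependent seed-target connectivity. Optional AR(1) noise.
#'
#' @param design A `design_matrix` with exactly one modulator column.
#' @param seed_effects,target_effects Named effect vectors over design
#'   columns (missing columns default to 0).
#' @param coupling Value-dependent coupling strength.
#' @param noise_sd Gaussian innovation SD.
#' @param ar1 AR(1) coefficient of the noise (default 0, white).
#' @param seed RNG seed.
#' @return List with `seed`, `target` (numeric series), `psych`.
#' @export
simulate_bold <- function(design, seed_effects, target_effects, coupling,
                          noise_sd = 1, ar1 = 0, seed = 1L) {
  stopifnot(inherits(design, "design_matrix"),
            length(design$psych_cols) == 1)
  set.seed(seed)
  X <- design$X
  expand <- function(eff) {
    b <- numeric(ncol(X)); names(b) <- colnames(X)
    b[names(eff)] <- eff
    b
  }
  noise <- function() {
    e <- stats::rnorm(nrow(X), 0, noise_sd)
    if (ar1 != 0) e <- as.numeric(stats::filter(e, ar1, method = "recursive"))
    e
  }
  psych <- X[, design$psych_cols]
  seed_series <- drop(X %*% expand(seed_effects)) + noise()
  phys <- seed_series - mean(seed_series)
  target <- drop(X %*% expand(target_effects)) + coupling * phys * psych +
    noise()
  list(seed = seed_series, target = target, psych = psych)
}

#' Estimate value-dependent coupling with a PPI GLM
#'
#' Builds the PPI regressor from the seed and the design's psychological
#' regressor, then regresses the target on intercept, task regressors,
#' physiological and psychological main effects, and the interaction.
#'
#' @param seed,target Numeric BOLD series.
#' @param design The `design_matrix` used to generate/model the session.
#' @return The PPI interaction estimate (scalar) with the full `roi_glm`
#'   fit as attribute `"fit"`.
#' @export
ppi_estimate <- function(seed, target, design) {
  stopifnot(length(design$psych_cols) == 1)
  pr <- ppi_regressor(seed, design$X[, design$psych_cols])
  X <- cbind(design$X, phys = pr$phys, ppi = pr$ppi)
  fit <- fit_glm(target, X)
  structure(fit$coefficients["ppi"], fit = fit)
}
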