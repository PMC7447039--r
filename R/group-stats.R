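# Nonparametric group-level statistics: Mann-Whitney U with normal
# approximation and tie-corrected variance, effect size r = |Z|/sqrt(N),
# baseline normalization, Bonferroni correction, Spearman correlation.

#' Mann-Whitney U test with normal approximation
#'
#' U is computed from pooled mid-ranks; Z uses the normal approximation
#' with tie-corrected variance and (by default) no continuity correction,
#' matching the Z-to-p mapping of common statistics packages (e.g.
#' Z = 1.97 gives a one-tailed p of 0.02). The effect size is
#' r = |Z|/sqrt(n1 + n2). An exact-enumeration oracle for small samples
#' lives in the test-suite; the documented maximum one-tailed
#' approximation error is 0.062/0.045/0.035 for n1 = n2 = 4/5/6.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param tail `"two"` or `"one"`.
#' @param direction For one-tailed tests, `"greater"` tests the
#'   alternative that `x` is stochastically larger than `y`; `"less"` the
#'   reverse. Never inferred from the data.
#' @param continuity Apply a 0.5 continuity correction to |U - mu|
#'   (default `FALSE`).
#' @return Object of class `group_test`: `u`, `z`, `p`, `r`, `n_total`,
#'   `tail`, `direction`.
#' @export
mann_whitney <- function(x, y, tail = c("two", "one"),
                         direction = c("greater", "less"),
                         continuity = FALSE) {
  tail <- match.arg(tail); direction <- match.arg(direction)
  stopifnot(length(x) >= 2, length(y) >= 2, all(is.finite(c(x, y))))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(c(x, y))                       # mid-ranks for ties
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) {
    z <- 0
  } else {
    num <- u - mu
    if (continuity) num <- sign(num) * max(0, abs(num) - 0.5)
    z <- num / sqrt(v)
  }
  p <- if (tail == "two") two_tailed_p(z)
       else if (direction == "greater") one_tailed_p(z) else one_tailed_p(-z)
  structure(list(u = u, z = z, p = p, r = effect_size_r(z, n),
                 n_total = n, tail = tail, direction = direction),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> U = %.1f, Z = %.2f, p = %.3f (%s-tailed), r = %.2f, N = %d\n",
              x$u, x$z, x$p, x$tail, x$r, x$n_total))
  invisible(x)
}

#' Effect size r = |Z|/sqrt(N) for nonparametric tests
#'
#' `N` is the total combined sample size (e.g. 60 for two groups of 30).
#'
#' @param z Standard-normal deviate.
#' @param n_total Combined sample size (>= 1).
#' @return Dimensionless effect size.
#' @export
effect_size_r <- function(z, n_total) {
  stopifnot(n_total >= 1)
  abs(z) / sqrt(n_total)
}

#' Standard-normal tail probabilities
#'
#' @param z Finite standard-normal deviate.
#' @return `one_tailed_p`: 1 - Phi(z); `two_tailed_p`: 2 (1 - Phi(|z|)).
#' @export
one_tailed_p <- function(z) {
  stopifnot(all(is.finite(z)))
  stats::pnorm(z, lower.tail = FALSE)
}

#' @rdname one_tailed_p
#' @export
two_tailed_p <- function(z) {
  stopifnot(all(is.finite(z)))
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Baseline-normalize difference scores
#'
#' Divides post-minus-pre difference scores element-wise by pre-session
#' baseline values. Zero baselines are an explicit error — nothing is
#' imputed.
#'
#' @param post_minus_pre,pre Equal-length numeric vectors.
#' @return Element-wise ratio.
#' @export
baseline_normalize <- function(post_minus_pre, pre) {
  stopifnot(length(post_minus_pre) == length(pre))
  if (any(pre == 0)) stop("baseline_normalize: zero pre-session baseline value")
  post_minus_pre / pre
}

#' Bonferroni correction
#'
#' @param p Probability (or vector).
#' @param m Number of comparisons (>= 1).
#' @return `bonferroni`: min(1, m p); `bonferroni_alpha`: alpha / m.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' @rdname bonferroni
#' @param alpha Nominal significance level.
#' @export
bonferroni_alpha <- function(alpha, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-rank-transformed data;
#' p from t = rho sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 5).
#' @param tail `"two"` or `"one"`.
#' @param direction For one-tailed tests: `"greater"` (rho > 0) or
#'   `"less"`.
#' @return List with `rho` and `p`.
#' @export
spearman_correlation <- function(x, y, tail = c("two", "one"),
                                 direction = c("greater", "less")) {
  tail <- match.arg(tail); direction <- match.arg(direction)
  stopifnot(length(x) == length(y), length(x) >= 5)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("spearman_correlation: zero rank variance")
  rho <- stats::cor(rx, ry)
  n <- length(x)
  tstat <- if (abs(rho) >= 1) sign(rho) * Inf
           else rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (tail == "two") 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
       else if (direction == "greater") stats::pt(tstat, n - 2, lower.tail = FALSE)
       else stats::pt(tstat, n - 2)
  list(rho = rho, p = p)
}

# Half-up rounding for report tables (matches printed 2-dp values).
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Group test on per-participant pre-to-post parameter changes
#'
#' Convenience wrapper for the stimulation contrast: computes post-minus-
#' pre difference scores per participant for one measure, optionally
#' baseline-normalized, and compares the rTPJ and vertex groups with a
#' one- or two-tailed Mann-Whitney test.
#'
#' @param values Data frame with columns `participant_id`, `group`,
#'   `session`, and the measure column.
#' @param measure Column name to analyse (e.g. `"s"`, `"k"`, `"auc"`).
#' @param normalize `"none"` or `"baseline"` (divide by pre values).
#' @param tail,direction Passed to [mann_whitney()]; direction refers to
#'   the rTPJ group relative to vertex.
#' @return A `group_test` with the per-participant scores attached as
#'   attribute `"scores"`.
#' @export
ctbs_group_test <- function(values, measure, normalize = c("none", "baseline"),
                            tail = c("one", "two"),
                            direction = c("greater", "less")) {
  normalize <- match.arg(normalize)
  tail <- match.arg(tail); direction <- match.arg(direction)
  pre <- values[values$session == "pre", ]
  post <- values[values$session == "post", ]
  m <- merge(pre[, c("participant_id", "group", measure)],
             post[, c("participant_id", measure)],
             by = "participant_id", suffixes = c("_pre", "_post"))
  diff <- m[[paste0(measure, "_post")]] - m[[paste0(measure, "_pre")]]
  if (normalize == "baseline")
    diff <- baseline_normalize(diff, m[[paste0(measure, "_pre")]])
  scores <- data.frame(participant_id = m$participant_id, group = m$group,
                       score = diff, stringsAsFactors = FALSE)
  res <- mann_whitney(scores$score[scores$group == "rTPJ"],
                      scores$score[scores$group == "vertex"],
                      tail = tail, direction = direction)
  attr(res, "scores") <- scores
  res
}
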