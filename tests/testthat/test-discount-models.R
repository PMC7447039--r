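# Discount functions, softmax choice rule, likelihood, AUC.
# High-precision expected values were computed once with an
# arbitrary-precision oracle (mpmath, 40 significant digits) and frozen.

test_that("quasi-hyperbolic subjective value matches frozen oracle and limits", {
  expect_equal(sv_quasi_hyperbolic(20, 0, beta = 0.8, delta = 0.95), 16.0)
  expect_equal(sv_quasi_hyperbolic(15, 10, beta = 1, delta = 1), 15.0)
  expect_equal(sv_quasi_hyperbolic(20, 30, beta = 0.9, delta = 0.98),
               9.818717748883869, tolerance = 1e-12)
})

test_that("hyperbolic subjective value matches frozen oracle and limits", {
  expect_equal(sv_hyperbolic(20, 0, k = 0.05), 20.0)
  expect_equal(sv_hyperbolic(20, 100, k = 0.01), 10.0)
  expect_equal(sv_hyperbolic(12, 180, k = 0.02), 2.608695652173913,
               tolerance = 1e-12)
})

test_that("generalized hyperbolic reduces to hyperbolic and powers correctly", {
  expect_equal(sv_generalized_hyperbolic(20, 100, k = 0.01, s = 1), 10.0)
  expect_equal(sv_generalized_hyperbolic(20, 100, k = 0.01, s = 2), 5.0)
  # s -> 0 limit removes discounting (s = 0 itself is rejected)
  expect_error(sv_generalized_hyperbolic(20, 100, k = 0.01, s = 0), "'s'")
  expect_equal(sv_generalized_hyperbolic(20, 100, k = 0.01, s = 1e-8), 20,
               tolerance = 1e-6)
})

test_that("parameter bounds raise domain errors naming the offending field", {
  expect_error(sv_quasi_hyperbolic(20, 1, beta = 1.2, delta = 0.9), "beta")
  expect_error(sv_quasi_hyperbolic(20, 1, beta = 0.9, delta = 0), "delta")
  expect_error(sv_hyperbolic(20, 1, k = -0.1), "'k'")
  expect_error(sv_hyperbolic(-5, 1, k = 0.1), "reward")
  expect_error(sv_generalized_hyperbolic(20, -1, k = 0.1, s = 1), "delay")
  expect_error(choice_prob(10, beta_temp = 0), "beta_temp")
  expect_error(discount_params("hyperbolic", k = 0.1, s = 2, beta_temp = 1),
               "does not belong")
  expect_error(discount_params("generalized_hyperbolic", k = 0.1,
                               beta_temp = 1), "requires parameter 's'")
})

test_that("softmax choice probability: indifference, limits, frozen value", {
  expect_equal(choice_prob(10, beta_temp = 2), 0.5)
  expect_equal(choice_prob(1e6, beta_temp = 1), 1.0)
  expect_equal(choice_prob(11, beta_temp = 1), 0.7310585786300049,
               tolerance = 1e-12)
  # numerically stable far into the tails
  expect_equal(choice_prob(710, beta_temp = 1), 1.0)
  expect_gt(choice_prob(-690, beta_temp = 1), 0)
})

test_that("softmax symmetry and monotonicity properties hold", {
  set.seed(41)
  for (rep in 1:25) {
    sv <- runif(1, 0, 25); bt <- rlnorm(1, 0, 1)
    expect_equal(choice_prob(sv, bt) + choice_prob(20 - sv, bt), 1,
                 tolerance = 1e-12)
  }
  sv <- seq(0, 20, by = 0.25)
  expect_true(all(diff(choice_prob(sv, beta_temp = 0.7)) > 0))
})

test_that("subjective value is non-increasing in delay for all models", {
  set.seed(42)
  d <- sort(runif(40, 0, 180))
  for (rep in 1:20) {
    r <- runif(1, 10, 20)
    expect_true(all(diff(sv_hyperbolic(r, d, k = rlnorm(1, -4, 1))) <= 0))
    expect_true(all(diff(sv_generalized_hyperbolic(r, d, k = rlnorm(1, -4, 1),
                                                   s = rlnorm(1, 0, 0.5))) <= 0))
    expect_true(all(diff(sv_quasi_hyperbolic(r, d, beta = runif(1, 0.2, 1),
                                             delta = runif(1, 0.8, 1))) <= 0))
    # generalized with s = 1 is the one-parameter model to machine precision
    k <- rlnorm(1, -4, 1)
    expect_identical(sv_generalized_hyperbolic(r, d, k, s = 1),
                     sv_hyperbolic(r, d, k))
  }
})

test_that("choice log-likelihood matches frozen 4-trial oracle and sums its pointwise vector", {
  par <- discount_params("generalized_hyperbolic", k = 0.02, s = 1.2,
                         beta_temp = 0.8)
  trials <- data.frame(reward_ll = c(20, 15, 12, 11),
                       delay = c(30, 10, 180, 1),
                       choice = c("LL", "SS", "LL", "SS"))
  ll <- choice_loglik(par, trials)
  expect_equal(ll$pointwise,
               c(-0.2866315503002754, -1.8189048401231824,
                 -6.4635410053580504, -1.0331989574061906),
               tolerance = 1e-12)
  expect_equal(ll$total, -9.602276353187699, tolerance = 1e-12)
  expect_identical(ll$total, sum(ll$pointwise))
})

test_that("likelihood degenerate regimes: uninformative and indifferent trials", {
  trials <- sim_trials(seed = 3)
  par0 <- discount_params("generalized_hyperbolic", k = 0.01, s = 1,
                          beta_temp = 1e-12)
  expect_equal(choice_loglik(par0, trials)$total, nrow(trials) * log(0.5),
               tolerance = 1e-9)
  one <- data.frame(reward_ll = 10, delay = 0, choice = "LL")
  par <- discount_params("hyperbolic", k = 0.3, beta_temp = 2)
  expect_equal(choice_loglik(par, one)$total, log(0.5))
  # probability floor keeps the log-likelihood finite under extreme noise
  wrong <- data.frame(reward_ll = 20, delay = 0, choice = "SS")
  par_hot <- discount_params("hyperbolic", k = 1e-6, beta_temp = 500)
  expect_equal(choice_loglik(par_hot, wrong)$total, log(1e-12),
               tolerance = 1e-5)
  expect_error(choice_loglik(par, one[0, ]), "non-empty")
})

test_that("discount-curve AUC: frozen closed form, limits, quadrature agreement", {
  gp <- function(k, s) discount_params("generalized_hyperbolic", k = k, s = s,
                                       beta_temp = 1)
  expect_equal(auc_discount_curve(gp(0.01, 1)), 0.5720107873228657,
               tolerance = 1e-10)
  expect_equal(auc_discount_curve(gp(1e-12, 1)), 1.0, tolerance = 1e-6)
  expect_lt(auc_discount_curve(gp(1e5, 1)), 1e-3)
  # adaptive quadrature vs analytic antiderivative for s = 1 and s = 2
  for (k in c(0.004, 0.01, 0.07, 0.3)) for (s in c(1, 2))
    expect_equal(auc_discount_curve(gp(k, s)), auc_closed_form(k, s),
                 tolerance = 1e-8)
  # strictly decreasing in k and in s
  expect_true(all(diff(sapply(c(0.005, 0.01, 0.05, 0.2),
                              function(k) auc_discount_curve(gp(k, 1.2)))) < 0))
  expect_true(all(diff(sapply(c(0.5, 1, 2, 4),
                              function(s) auc_discount_curve(gp(0.02, s)))) < 0))
  expect_error(auc_discount_curve(discount_params("hyperbolic", k = 0.1,
                                                  beta_temp = 1)),
               "generalized")
})
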