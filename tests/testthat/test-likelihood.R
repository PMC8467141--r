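test_that("hurdle log-likelihood matches hand-evaluated cases", {
  # single observation y = 1 with w = 0.5, mu = 1, alpha = 0
  d1 <- count_dataset(1, matrix(1, 1, 1), matrix(1, 1, 1))
  expect_equal(loglik_gphr(theta_pack(0, 0, 0), d1),
               log(0.5 * exp(-1) / (1 - exp(-1))), tolerance = 1e-12)
  # all-zero response, w = 0.5: only the zero branch contributes
  d0 <- count_dataset(rep(0, 8), matrix(1, 8, 1), matrix(1, 8, 1))
  expect_equal(loglik_gphr(theta_pack(0.2, 0.4, 0), d0), 8 * log(0.5),
               tolerance = 1e-12)
  expect_equal(loglik_ph(theta_pack(NULL, 0.4, 0), d0), 8 * log(0.5),
               tolerance = 1e-12)
})

test_that("alpha = 0 collapses the GP models onto their Poisson forms", {
  for (seed in 1:3) {
    d <- make_test_dataset(40, seed = seed)
    beta <- c(0.3, -0.4); delta <- c(0.2, 0.5)
    expect_equal(loglik_gphr(theta_pack(0, beta, delta), d),
                 loglik_ph(theta_pack(NULL, beta, delta), d),
                 tolerance = 1e-10)
    # GP regression at alpha = 0 is plain Poisson regression
    mu <- exp(drop(d$x %*% beta))
    expect_equal(loglik_gp(theta_pack(0, beta), d),
                 sum(dpois(d$y, mu, log = TRUE)), tolerance = 1e-10)
  }
  d1 <- count_dataset(0, cbind(1), cbind(1))
  expect_equal(loglik_gp(theta_pack(0, log(2)), d1), -2, tolerance = 1e-12)
  d2 <- count_dataset(1, cbind(1), cbind(1))
  expect_equal(loglik_gp(theta_pack(0.5, log(2)), d2), -1.5,
               tolerance = 1e-12)
})

test_that("infeasible parameters are penalized, not thrown", {
  d <- make_test_dataset(20)
  expect_equal(loglik_gphr(theta_pack(-2, c(1, 0), c(0, 0)), d), -1e10)
})

test_that("AIC follows its definition and ranks nested fits sensibly", {
  expect_equal(aic(0, 2), 4)
  expect_equal(aic(-315.95, 4), 639.90)
  d <- generate_counts(earlike_scenario(seed = 5))
  f_gphr <- fit_ml("gphr", d)
  f_ph <- fit_ml("ph", d)
  f_gp <- fit_ml("gp", d)
  for (f in list(f_gphr, f_ph, f_gp))
    expect_equal(f$aic, -2 * f$loglik + 2 * f$n_params)
  expect_identical(c(f_gphr$n_params, f_ph$n_params, f_gp$n_params),
                   c(7L, 6L, 4L))
  # nesting: GPHR contains PH (alpha = 0), so its optimum is no worse
  expect_gte(f_gphr$loglik, f_ph$loglik - 1e-6)
})

test_that("ML fitting recovers Poisson-hurdle truth when alpha is zero", {
  sc <- sim_scenario(
    n = 3000, beta = c(0.5, 0.4), delta = c(0.1, -0.6), alpha = 0,
    covariates = list(u = list(values = c(0, 1), prob = c(0.5, 0.5))),
    seed = 77)
  d <- generate_counts(sc)
  f_gphr <- fit_ml("gphr", d)
  f_ph <- fit_ml("ph", d)
  expect_lt(abs(f_gphr$theta[["alpha"]]), 0.05)
  # with the extra free dispersion parameter the AIC penalty is ~2
  expect_lt(abs(f_gphr$aic - (f_ph$aic + 2)), 2.5)
  expect_lt(max(abs(f_ph$theta - c(0.5, 0.4, 0.1, -0.6))), 0.15)
})

test_that("likelihood at the truth concentrates at the expected level", {
  # average per-observation log-likelihood at the truth ~ its expectation
  sc <- recovery_scenario(4000, seed = 31)
  d <- generate_counts(sc)
  th0 <- theta_pack(sc$alpha, sc$beta, sc$delta)
  ll_true <- loglik_gphr(th0, d)
  # perturbed parameters must not beat the truth by more than noise (KL >= 0)
  ll_pert <- loglik_gphr(th0 + c(0.05, 0.1, -0.1, 0.1, -0.1), d)
  expect_gt(ll_true, ll_pert)
})

test_that("observed-information standard errors are finite and positive", {
  d <- generate_counts(earlike_scenario(seed = 8, n = 400))
  f <- fit_ml("gphr", d)
  se <- ml_observed_info_se(f, d)
  expect_length(se, 7)
  expect_true(all(is.finite(se) & se > 0))
})
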