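test_that("GP pmf matches hand-evaluated and Poisson-limit values", {
  expect_equal(dgp(0, 2, 0), exp(-2), tolerance = 1e-12)
  expect_equal(dgp(1, 2, 0.5), exp(-1.5), tolerance = 1e-12)
  # P(Y = 0) = exp(-mu/(1+alpha*mu)) for any valid parameters
  for (mu in c(0.5, 2, 7)) for (alpha in c(-0.05, 0, 0.4))
    expect_equal(dgp(0, mu, alpha), exp(-mu / (1 + alpha * mu)),
                 tolerance = 1e-12)
  # alpha = 0 reduction to the Poisson pmf
  for (mu in c(0.3, 1, 4, 9))
    expect_equal(dgp(0:50, mu, 0), dpois(0:50, mu), tolerance = 1e-12)
})

test_that("GP pmf rejects invalid parameters and truncates under alpha < 0", {
  expect_error(dgp(1, -1, 0.2), "mu")
  expect_error(dgp(1, 10, -0.2), "alpha")
  # support cut-off: zero mass where 1 + alpha*y <= 0
  expect_equal(dgp(25, 2, -0.05), 0)
  expect_gt(gp_mass_deficit(2, -0.05), 0)
  expect_equal(gp_mass_deficit(2, 0.3), 0, tolerance = 1e-10)
})

test_that("GP pmf normalizes for alpha >= 0 and moments match summation", {
  grid <- gp_param_grid()
  for (i in seq_len(nrow(grid))) {
    mu <- grid$mu[i]; alpha <- grid$alpha[i]
    bf <- brute_gp_moments(mu, alpha)
    cf <- gp_moments(mu, alpha)
    if (alpha >= 0) {
      expect_equal(sum(dgp(0:3000, mu, alpha)), 1, tolerance = 1e-8)
      expect_equal(bf$mean, cf$mean, tolerance = 1e-6)
      expect_equal(bf$variance, cf$variance, tolerance = 1e-6)
    }
    # dispersion direction is set by the sign of alpha
    if (alpha > 0) expect_gt(cf$variance, cf$mean)
    if (alpha < 0) expect_lt(cf$variance, cf$mean)
    if (alpha == 0) expect_equal(cf$variance, cf$mean)
  }
})

test_that("GP1 parameterization converts and round-trips", {
  expect_equal(gp1_from_gp2(2, 0), list(lambda1 = 2, lambda2 = 0))
  expect_equal(gp1_from_gp2(2, 0.5), list(lambda1 = 1, lambda2 = 0.5))
  for (i in seq_len(nrow(gp_param_grid()))) {
    g <- gp_param_grid()[i, ]
    l <- gp1_from_gp2(g$mu, g$alpha)
    expect_equal(l$lambda1 / (1 - l$lambda2), g$mu, tolerance = 1e-12)
  }
})

test_that("hurdle pmf obeys its zero branch and collapses to plain GP", {
  expect_equal(dgphurdle(0, w = 0.3, mu = 2, alpha = 0.5), 0.3)
  # w = g(0): the hurdle is inactive and the mixture is the GP itself
  for (mu in c(1, 3)) for (alpha in c(0, 0.3)) {
    w0 <- exp(-mu / (1 + alpha * mu))
    expect_equal(dgphurdle(0:30, w0, mu, alpha), dgp(0:30, mu, alpha),
                 tolerance = 1e-12)
  }
  # total mass reaches 1 for alpha >= 0
  expect_equal(sum(dgphurdle(0:3000, 0.4, 5, 0.5)), 1, tolerance = 1e-8)
})

test_that("hurdle moments match brute-force summation on a grid", {
  expect_equal(gphurdle_moments(0.5, 1, 0)$mean, 0.5 / (1 - exp(-1)),
               tolerance = 1e-9)
  for (w in c(0.2, 0.48, 0.8)) for (i in seq_len(nrow(gp_param_grid()))) {
    g <- gp_param_grid()[i, ]
    if (g$alpha < 0) next # closed forms assume full mass
    bf <- brute_gphr_moments(w, g$mu, g$alpha)
    cf <- gphurdle_moments(w, g$mu, g$alpha)
    expect_equal(cf$mean, bf$mean, tolerance = 1e-6)
    expect_equal(cf$variance, bf$variance, tolerance = 1e-6)
  }
  # hurdle factor 1: mean reduces to mu
  mu <- 2; alpha <- 0.3
  expect_equal(gphurdle_moments(exp(-mu / (1 + alpha * mu)), mu, alpha)$mean,
               mu, tolerance = 1e-12)
})

test_that("samplers are seeded, respect support, and match their pmfs", {
  expect_identical(rgp(50, 2, 0.5, seed = 9), rgp(50, 2, 0.5, seed = 9))
  expect_identical(rtgp(50, 2, 0.5, seed = 9), rtgp(50, 2, 0.5, seed = 9))
  expect_gte(min(rtgp(2000, 0.5, 0.4, seed = 1)), 1)

  n <- 1e5
  s <- rgp(n, 2, 0, seed = 11)
  expect_lt(abs(mean(s) - 2), 4 * sqrt(2 / n))       # CLT bound, Poisson
  s2 <- rgp(n, 2, 0.5, seed = 12)
  expect_lt(abs(var(s2) - 8) / 8, 0.1)               # Var = mu(1+alpha*mu)^2
  st <- rtgp(n, 2, 0, seed = 13)
  expect_lt(abs(mean(st) - 2 / (1 - exp(-2))), 0.03) # zero-truncated Poisson

  # chi-square goodness of fit of the empirical law against the exact pmf
  tab <- tabulate(s2 + 1, nbins = max(s2) + 1)
  p <- dgp(0:max(s2), 2, 0.5)
  keep <- n * p >= 5
  chi <- sum((tab[keep] - n * p[keep])^2 / (n * p[keep]))
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.001)
})
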