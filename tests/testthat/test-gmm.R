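test_that("moment vectors have the stated structure and dimension", {
  d <- make_test_dataset(15, distinct = TRUE)
  th <- theta_pack(0.2, c(0.3, 0.1), c(0.2, -0.4))
  H <- moment_matrix(th, d)
  expect_equal(dim(H), c(15, 2 * (d$p + d$q + 2)))
  # rows rebuild from the R-side moment functions
  gm <- moment_g1_g2(th, d)
  for (i in c(1, 7, 15)) {
    Xi <- c(d$x[i, ], d$z[i, ])
    expect_equal(moment_vector(i, th, d),
                 c(Xi * (d$y[i] - gm$g1[i]), Xi * (d$y[i]^2 - gm$g2[i])),
                 tolerance = 1e-10)
  }
  # scalar design, w = 0.5, mu = 1, alpha = 0: both blocks repeat y - g
  d1 <- count_dataset(2, matrix(1, 1, 1), matrix(1, 1, 1))
  h <- moment_vector(1, theta_pack(0, 0, 0), d1)
  g1 <- 0.5 / (1 - exp(-1))
  g2 <- brute_gphr_moments(0.5, 1, 0)
  expect_equal(h, c(2 - g1, 2 - g1, 4 - (g2$variance + g2$mean^2),
                    4 - (g2$variance + g2$mean^2)), tolerance = 1e-6)
})

test_that("sample moments average correctly and shrink at the truth", {
  d <- make_test_dataset(10, distinct = TRUE)
  th <- theta_pack(0.1, c(0.2, 0.3), c(0.1, -0.2))
  expect_equal(sample_moments(th, d), colMeans(moment_matrix(th, d)))
  # duplication invariance of the average
  dd <- dataset_subset(d, rep(seq_len(d$n), 2))
  expect_equal(sample_moments(th, dd), sample_moments(th, d),
               tolerance = 1e-12)
  # LLN: ||h_n|| at the truth decreases roughly like n^(-1/2)
  th0 <- theta_pack(0.2, c(0.3, 0.5), c(0.4, -0.9))
  norms <- sapply(c(500, 8000), function(n)
    sqrt(sum(sample_moments(th0, generate_counts(
      recovery_scenario(n, seed = 99)))^2)))
  expect_lt(norms[2], norms[1])
})

test_that("GMM objective is the stated quadratic form", {
  d <- make_test_dataset(20, distinct = TRUE)
  spec <- gmm_spec()
  th <- theta_pack(0.15, c(0.2, 0.1), c(0.3, -0.5))
  h <- sample_moments(th, d, spec)
  expect_equal(gmm_objective(th, d, spec), sum(h^2), tolerance = 1e-10)
  W <- diag(length(h)) * 2
  expect_equal(gmm_objective(th, d, spec, W = W), 2 * sum(h^2),
               tolerance = 1e-10)
  expect_gte(gmm_objective(th, d, spec), 0)
  # infeasible theta gets the penalty, not an error
  expect_equal(gmm_objective(theta_pack(-2, c(1, 0), c(0, 0)), d, spec), 1e10)
  expect_error(gmm_objective(th, d, spec, W = diag(3)), "W must be")
})

test_that("weight matrices: identity dimension, singular two-step handled", {
  d <- make_test_dataset(60) # x = z: duplicated moment rows
  th <- theta_pack(0.1, c(0.2, 0.1), c(0.3, -0.5))
  expect_equal(make_weight(th, d, "identity"), diag(8))
  H <- moment_matrix(th, d)
  Sigma <- crossprod(H) / d$n
  expect_lte(qr(Sigma)$rank, 4) # rank at most half the dimension
  W2 <- make_weight(th, d, "two_step") # pseudo-inverse, no error
  expect_equal(W2, t(W2))
  # pseudo-inverse property on the singular covariance
  expect_equal(Sigma %*% W2 %*% Sigma, Sigma, tolerance = 1e-6)
})

test_that("GMM fitting descends from its start and is deterministic", {
  d <- generate_counts(recovery_scenario(400, seed = 12))
  spec <- gmm_spec()
  fml <- fit_ml("gphr", d)
  g <- fit_gmm(d, spec = spec)
  expect_lte(g$objective, gmm_objective(fml$theta, d, spec) + 1e-12)
  expect_identical(g$theta, fit_gmm(d, spec = spec)$theta)
  expect_identical(g$aic_type, "quasi")
  # two-step runs end to end
  g2 <- fit_gmm(d, init = fml$theta, spec = gmm_spec("two_step"))
  expect_true(is.finite(g2$objective))
})

test_that("sandwich variance surfaces identification failure under x = z", {
  d <- generate_counts(earlike_scenario(seed = 4, n = 300))
  g <- fit_gmm(d)
  dg <- gmm_asymptotic_variance(g$theta, d)
  expect_lt(dg$jacobian_rank, length(g$theta)) # under-identified as written
  expect_equal(dg$Gamma_hat, t(dg$Gamma_hat))
})

test_that("efficient weighting simplifies the sandwich to (G' W G)^-1", {
  # with W the (pseudo-)inverse of Sigma, the sandwich collapses to its bread
  spec <- gmm_spec(augment_zero_moment = TRUE)
  d <- generate_counts(recovery_scenario(500, seed = 21))
  f <- fit_gmm(d, spec = spec)
  W <- make_weight(f$theta, d, "two_step", spec)
  dg <- gmm_asymptotic_variance(f$theta, d, spec, W = W)
  direct <- solve(t(dg$G) %*% W %*% dg$G)
  expect_equal(dg$Gamma_hat, (direct + t(direct)) / 2, tolerance = 1e-8)
  # augmented moments restore full-rank identification
  expect_equal(dg$jacobian_rank, length(f$theta))
})
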