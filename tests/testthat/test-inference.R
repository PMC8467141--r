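test_that("bootstrap variance follows its defining formula", {
  d <- make_test_dataset(80)
  # constant estimator: zero variance
  bv0 <- bootstrap_variance(d, function(x) c(1, 2), B = 10, seed = 1)
  expect_equal(bv0$variances, c(0, 0))
  # B = 2: variance is the two-point formula (a - b)^2 / 2
  bv2 <- bootstrap_variance(d, function(x) mean(x$y), B = 2, seed = 2)
  expect_equal(bv2$variances,
               (bv2$replicates[1, ] - bv2$replicates[2, ])^2 / 2)
  expect_error(bootstrap_variance(d, mean, B = 1), "at least 2")
})

test_that("bootstrap variance of the sample mean matches s^2/n", {
  set.seed(5)
  n <- 200
  d <- count_dataset(rpois(n, 3), matrix(1, n, 1), matrix(1, n, 1))
  bv <- bootstrap_variance(d, function(x) mean(x$y), B = 2000, seed = 6)
  expect_lt(abs(bv$variances - var(d$y) / n) / (var(d$y) / n), 0.15)
})

test_that("failing replicates are redrawn and counted", {
  d <- make_test_dataset(30)
  flaky <- function(x) {
    if (mean(x$y) > mean(d$y)) stop("resample rejected") # ~half of draws
    mean(x$y)
  }
  bv <- bootstrap_variance(d, flaky, B = 3, seed = 3)
  expect_equal(nrow(bv$replicates), 3)
  expect_gt(bv$n_redrawn, 0)
})

test_that("Wald inference matches the normal reference", {
  wi <- wald_inference(0, 1, level = 0.05)
  expect_equal(wi$ci_low, -qnorm(0.975), tolerance = 1e-9)
  expect_equal(wi$p_values, 1)
  expect_equal(wald_inference(1.96, 1)$p_values, 0.05, tolerance = 1e-3)
  # published-style check: estimate 0.63, SE 0.26 -> p about 0.015
  expect_equal(wald_inference(0.63, 0.26)$p_values, 0.0154, tolerance = 2e-3)
  # sign-flip equivariance
  a <- wald_inference(c(0.4, -1.1), c(0.2, 0.5))
  b <- wald_inference(-c(0.4, -1.1), c(0.2, 0.5))
  expect_equal(a$p_values, b$p_values)
  expect_equal(a$ci_low, -b$ci_high)
  # degenerate SEs
  expect_equal(wald_inference(c(0.5, 0), c(0, 0))$p_values, c(0, 1))
})

test_that("model comparison sorts by AIC with stable ties", {
  mk <- function(model, ll, k) structure(
    list(model = model, estimator = "ml", loglik = ll, aic = aic(ll, k),
         n_params = k), class = "gphr_fit")
  tab <- compare_models(mk("gphr", -315.95, 4), mk("ph", -366.82, 3),
                        mk("gp", -317.655, 4))
  expect_equal(tab$model, c("gphr", "gp", "ph"))
  expect_equal(tab$delta_aic[1], 0)
  expect_true(all(diff(tab$aic) >= 0))
  single <- compare_models(mk("gp", -100, 2))
  expect_equal(single$delta_aic, 0)
  ties <- compare_models(mk("ph", -100, 2), mk("gp", -100, 2))
  expect_equal(ties$model, c("ph", "gp")) # input order preserved
})

test_that("bootstrap inference attaches coherent fields to a fit", {
  d <- generate_counts(earlike_scenario(seed = 10, n = 250))
  f <- add_bootstrap_inference(fit_ml("gphr", d), d, B = 8, seed = 11)
  expect_length(f$se, length(f$theta))
  expect_true(all(f$ci_low <= f$theta & f$theta <= f$ci_high))
  expect_true(all(f$p_values >= 0 & f$p_values <= 1))
})
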