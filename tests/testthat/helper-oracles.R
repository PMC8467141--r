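# Brute-force oracles and small fixture builders shared across the suite.

# support large enough to exhaust the mass for the parameter grids used here
.oracle_support <- function(mu, alpha, J = 3000) {
  if (alpha < 0) 0:floor(-1 / alpha - 1e-12) else 0:J
}

# moments by direct summation of the pmf (checks closed forms against mass)
brute_gp_moments <- function(mu, alpha) {
  ys <- .oracle_support(mu, alpha)
  p <- dgp(ys, mu, alpha)
  m1 <- sum(ys * p)
  list(mean = m1, variance = sum(ys^2 * p) - m1^2)
}

brute_gphr_moments <- function(w, mu, alpha) {
  ys <- .oracle_support(mu, alpha)
  p <- dgphurdle(ys, w, mu, alpha)
  m1 <- sum(ys * p)
  list(mean = m1, variance = sum(ys^2 * p) - m1^2, total = sum(p))
}

# parameter grid covering over-, equi- and under-dispersion (20 points)
gp_param_grid <- function() {
  expand.grid(mu = c(0.5, 1, 2, 5, 10),
              alpha = c(-0.05, 0, 0.2, 0.5))
}

# small dataset with continuous covariates, optionally distinct x and z
make_test_dataset <- function(n = 50, seed = 42, distinct = FALSE) {
  set.seed(seed)
  x <- cbind(1, runif(n, -1, 1))
  z <- if (distinct) cbind(1, rbinom(n, 1, 0.5)) else x
  y <- rpois(n, 1.5)
  count_dataset(y, x, z)
}

# scenario with distinct count/zero covariates, used for GMM identification
recovery_scenario <- function(n, seed) {
  sim_scenario(
    n = n,
    beta = c(0.3, 0.5), delta = c(0.4, -0.9), alpha = 0.2,
    covariates = list(a = list(values = c(0, 1), prob = c(0.5, 0.5)),
                      b = list(values = c(0, 1), prob = c(0.5, 0.5))),
    x_vars = "a", z_vars = "b", seed = seed)
}

recovery_truth <- c(0.2, 0.3, 0.5, 0.4, -0.9)
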