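# Log-likelihoods and maximum-likelihood fitting for the three competing
# models: GP hurdle (GPHR), Poisson hurdle (PH, the alpha = 0 special case)
# and one-part GP regression.

.MODEL_CODE <- c(gphr = 0L, ph = 1L, gp = 2L)

#' Log-likelihood of the generalized Poisson hurdle regression model
#'
#' \deqn{\ell(\theta) = \sum_{y_i = 0} \log w_i + \sum_{y_i > 0}
#'   [\log(1-w_i) + \log g(y_i;\mu_i,\alpha) - \log(1 - g(0;\mu_i,\alpha))]}
#' with \eqn{\mu_i, w_i} from [linpred_to_params()]. Infeasible parameter
#' values return the penalized value `-1e10` rather than an error, so that
#' the simplex search remains unconstrained.
#'
#' @param theta packed \eqn{(\alpha, \beta^\top, \delta^\top)^\top}.
#' @param dataset a [count_dataset()].
#' @return scalar log-likelihood.
#' @export
loglik_gphr <- function(theta, dataset) {
  .check_theta_len(theta, 1L + dataset$p + 1L + dataset$q + 1L)
  -cpp_nll(0L, as.numeric(theta), dataset$y, dataset$x, dataset$z)
}

#' Log-likelihood of the Poisson hurdle regression model
#'
#' Identical to [loglik_gphr()] with the dispersion fixed at zero; `theta`
#' therefore has no alpha slot.
#'
#' @param theta packed \eqn{(\beta^\top, \delta^\top)^\top}.
#' @inheritParams loglik_gphr
#' @export
loglik_ph <- function(theta, dataset) {
  .check_theta_len(theta, dataset$p + 1L + dataset$q + 1L)
  -cpp_nll(1L, as.numeric(theta), dataset$y, dataset$x, dataset$z)
}

#' Log-likelihood of the generalized Poisson regression model
#'
#' One-part model: \eqn{\sum_i \log g(y_i; \mu_i, \alpha)} with
#' \eqn{\log\mu_i = x_i^\top\beta}; there is no zero process.
#'
#' @param theta packed \eqn{(\alpha, \beta^\top)^\top}.
#' @inheritParams loglik_gphr
#' @export
loglik_gp <- function(theta, dataset) {
  .check_theta_len(theta, 1L + dataset$p + 1L)
  -cpp_nll(2L, as.numeric(theta), dataset$y, dataset$x, dataset$z)
}

.check_theta_len <- function(theta, expected) {
  if (length(theta) != expected)
    stop(sprintf("theta has length %d, expected %d", length(theta), expected),
         call. = FALSE)
}

#' Akaike information criterion
#'
#' `-2 * loglik + 2 * n_params`; smaller values indicate a better fit.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters.
#' @export
aic <- function(loglik, n_params) -2 * loglik + 2 * n_params

# free-parameter counts: GPHR = (p+1)+(q+1)+1, PH = (p+1)+(q+1), GP = (p+1)+1
.n_params <- function(model, dataset) {
  switch(model,
         gphr = dataset$p + dataset$q + 3L,
         ph   = dataset$p + dataset$q + 2L,
         gp   = dataset$p + 2L)
}

# moment-based default start: count part from the mean of positive counts,
# zero part from the empirical logit of the zero fraction, small positive
# dispersion
.default_init <- function(model, dataset) {
  ybar_pos <- mean(dataset$y[dataset$y > 0])
  if (!is.finite(ybar_pos) || ybar_pos <= 0) ybar_pos <- 0.5
  beta0 <- c(log(ybar_pos), rep(0, dataset$p))
  z0 <- min(max(mean(dataset$y == 0), 1 / (dataset$n + 1)),
            dataset$n / (dataset$n + 1))
  delta0 <- c(qlogis(z0), rep(0, dataset$q))
  switch(model,
         gphr = theta_pack(0.01, beta0, delta0),
         ph   = theta_pack(NULL, beta0, delta0),
         gp   = theta_pack(0.01, beta0))
}

#' Maximum-likelihood fit of a count model
#'
#' Minimizes the (penalized) negative log-likelihood with the simplex
#' optimizer. If the first run hits the iteration cap, one restart is made
#' from a deterministically jittered start (each coordinate displaced by 10%
#' of its scale) and the better of the two solutions is kept.
#'
#' @param model `"gphr"`, `"ph"` or `"gp"`.
#' @param dataset a [count_dataset()].
#' @param init optional packed starting vector; defaults to a moment-based
#'   start (log mean of positive counts for the count intercept, empirical
#'   logit of the zero share for the zero intercept, alpha = 0.01).
#' @param nm an [nm_config()].
#' @return a `gphr_fit` object: `model`, `estimator = "ml"`, named `theta`,
#'   `loglik`, `aic`, `n_params`, `converged`, `n_iter`.
#' @export
#' @examples
#' sc <- earlike_scenario(seed = 1)
#' fit <- fit_ml("gphr", generate_counts(sc))
#' fit$aic
fit_ml <- function(model = c("gphr", "ph", "gp"), dataset, init = NULL,
                   nm = nm_config()) {
  model <- match.arg(model)
  if (is.null(init)) init <- .default_init(model, dataset)
  run <- function(th0)
    cpp_fit_nll(.MODEL_CODE[[model]], dataset$y, dataset$x, dataset$z,
                as.numeric(th0), nm$eta, nm$gamma, nm$xi, nm$kappa,
                nm$eps, nm$max_iter, nm$init_step)
  res <- run(init)
  if (!res$converged) {
    res2 <- run(init + 0.1 * pmax(abs(init), 0.1))
    if (res2$value < res$value) res <- res2
  }
  theta <- stats::setNames(res$par, names(init))
  ll <- -res$value
  k <- .n_params(model, dataset)
  structure(list(model = model, estimator = "ml", theta = theta,
                 loglik = ll, aic = aic(ll, k), n_params = k,
                 converged = res$converged, n_iter = res$n_iter,
                 se = NULL, ci_low = NULL, ci_high = NULL, p_values = NULL),
            class = "gphr_fit")
}

#' @export
print.gphr_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): loglik = %.4f, AIC = %.4f, %s in %d iterations\n",
              toupper(x$model), toupper(x$estimator), x$loglik, x$aic,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  est <- data.frame(estimate = x$theta)
  if (!is.null(x$se)) {
    est$se <- x$se
    est$ci_low <- x$ci_low
    est$ci_high <- x$ci_high
    est$p_value <- x$p_values
  }
  print(round(est, 4))
  invisible(x)
}

# log-likelihood of a fit object evaluated at an arbitrary theta
.loglik_for <- function(model, theta, dataset) {
  switch(model,
         gphr = loglik_gphr(theta, dataset),
         ph   = loglik_ph(theta, dataset),
         gp   = loglik_gp(theta, dataset))
}

#' Standard errors from the numerically differenced observed information
#'
#' Central-difference Hessian of the negative log-likelihood at the ML
#' estimate; standard errors are square roots of the diagonal of its inverse.
#' Non-invertible information matrices yield `NA` entries rather than an
#' error.
#'
#' @param fit a `gphr_fit` from [fit_ml()].
#' @param dataset the dataset the fit was computed on.
#' @param rel_step relative finite-difference step.
#' @return numeric vector of standard errors.
#' @export
ml_observed_info_se <- function(fit, dataset, rel_step = 1e-4) {
  th <- fit$theta
  nll <- function(t) -.loglik_for(fit$model, t, dataset)
  m <- length(th)
  h <- rel_step * pmax(abs(th), 1)
  H <- matrix(NA_real_, m, m)
  f0 <- nll(th)
  for (i in seq_len(m)) {
    for (j in i:m) {
      ei <- ej <- rep(0, m); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (nll(th + ei) - 2 * f0 + nll(th - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (nll(th + ei + ej) - nll(th + ei - ej) -
           nll(th - ei + ej) + nll(th - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(rep(NA_real_, m))
  d <- diag(V)
  ifelse(d > 0, sqrt(d), NA_real_)
}
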