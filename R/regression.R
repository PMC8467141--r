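# Link functions mapping covariates and packed parameters to per-observation
# hurdle parameters, and the model-implied raw moments used by GMM.

#' Per-observation hurdle parameters from the linear predictors
#'
#' Applies the model links \eqn{\log \mu_i = x_i^\top\beta} and
#' \eqn{\mathrm{logit}\, w_i = z_i^\top\delta}. Parameter values that leave
#' the generalized Poisson family (any \eqn{1+\alpha\mu_i \le 0}, or a
#' non-finite \eqn{\mu_i}) are not an error: they are reported through
#' `feasible = FALSE` so that the unconstrained optimizer can penalize them.
#'
#' @param theta packed parameter vector \eqn{(\alpha, \beta^\top,
#'   \delta^\top)^\top}.
#' @param dataset a [count_dataset()].
#' @return list with elements `w`, `mu` (length-n vectors), `alpha` and
#'   `feasible`.
#' @export
linpred_to_params <- function(theta, dataset) {
  pp <- theta_unpack(theta, dataset$p, dataset$q)
  mu <- exp(drop(dataset$x %*% pp$beta))
  w <- plogis(drop(dataset$z %*% pp$delta))
  feasible <- all(is.finite(mu)) && all(1 + pp$alpha * mu > 0)
  list(w = w, mu = mu, alpha = pp$alpha, feasible = feasible)
}

#' Model-implied first and second raw moments
#'
#' For each observation, the hurdle mean \eqn{g_{1i} = r_i \mu_i} and second
#' raw moment \eqn{g_{2i} = r_i [\mu_i(1+\alpha\mu_i)^2 + \mu_i^2]}, where
#' \eqn{r_i = (1-w_i)/(1-e^{-\mu_i/(1+\alpha\mu_i)})} is the hurdle factor.
#' These are the expectations matched by the GMM moment conditions.
#'
#' @inheritParams linpred_to_params
#' @param g2_form `"squared"` (default) uses the variance-consistent bracket
#'   \eqn{\mu(1+\alpha\mu)^2+\mu^2}; `"linear"` switches to
#'   \eqn{\mu(1+\alpha\mu)+\mu^2}, a variant retained for sensitivity
#'   analysis.
#' @return list with vectors `g1`, `g2` and flag `feasible`.
#' @export
moment_g1_g2 <- function(theta, dataset, g2_form = c("squared", "linear")) {
  g2_form <- match.arg(g2_form)
  lp <- linpred_to_params(theta, dataset)
  if (!lp$feasible)
    return(list(g1 = rep(NA_real_, dataset$n), g2 = rep(NA_real_, dataset$n),
                feasible = FALSE))
  am <- 1 + lp$alpha * lp$mu
  r <- (1 - lp$w) / (-expm1(-lp$mu / am))
  g1 <- r * lp$mu
  g2 <- if (g2_form == "linear") r * (lp$mu * am + lp$mu^2)
        else r * (lp$mu * am^2 + lp$mu^2)
  list(g1 = g1, g2 = g2, feasible = TRUE)
}
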