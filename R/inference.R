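# Bootstrap variance estimation, Wald intervals/p-values, and AIC-based
# model comparison.

#' Bootstrap variance of an estimator
#'
#' Draws `B` with-replacement resamples of the dataset rows, applies
#' `estimator` to each, and returns the componentwise variance
#' \deqn{\widehat{Var} = \frac{1}{B-1}\sum_{b=1}^B
#'   [\hat\theta(Z^{*b}) - \bar S^*]^2,
#'   \qquad \bar S^* = \frac{1}{B}\sum_b \hat\theta(Z^{*b}).}
#' A replicate on which the estimator throws an error is redrawn, up to
#' `5 * B` total attempts.
#'
#' @param dataset a [count_dataset()].
#' @param estimator function mapping a `count_dataset` to a fixed-length
#'   numeric vector (e.g. `function(d) fit_ml("gphr", d)$theta`).
#' @param B number of bootstrap datasets (default 50).
#' @param resample_size rows per resample; defaults to `n` (the bootstrap
#'   datasets may in principle differ in size from the original, but equal
#'   size is the standard and default choice).
#' @param seed integer seed for the resampling.
#' @return list with `variances`, `se`, the `B` x k `replicates` matrix, and
#'   `n_redrawn`.
#' @export
bootstrap_variance <- function(dataset, estimator, B = 50,
                               resample_size = NULL, seed = NULL) {
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  if (is.null(resample_size)) resample_size <- dataset$n
  if (!is.null(seed)) set.seed(seed)
  reps <- NULL
  n_redrawn <- 0L
  attempts <- 0L
  b <- 0L
  while (b < B) {
    if (attempts >= 5L * B)
      stop("bootstrap estimator failed too often (", n_redrawn, " redraws)",
           call. = FALSE)
    attempts <- attempts + 1L
    idx <- sample.int(dataset$n, resample_size, replace = TRUE)
    est <- tryCatch(estimator(dataset_subset(dataset, idx)),
                    error = function(e) NULL)
    if (is.null(est) || any(!is.finite(est))) {
      n_redrawn <- n_redrawn + 1L
      next
    }
    if (is.null(reps)) reps <- matrix(NA_real_, B, length(est))
    b <- b + 1L
    reps[b, ] <- est
  }
  v <- apply(reps, 2, var) # 1/(B-1) sum (theta_b - mean)^2
  list(variances = v, se = sqrt(v), replicates = reps, n_redrawn = n_redrawn)
}

#' Wald confidence intervals and p-values
#'
#' Normal-reference inference: `est +/- z_{1-level/2} * se` and two-sided
#' p-values `2 * (1 - Phi(|est/se|))`. Degenerate standard errors are handled
#' explicitly: `se = 0` gives p = 0 for a nonzero estimate and p = 1 for a
#' zero one.
#'
#' @param est estimate vector.
#' @param se standard-error vector (non-negative).
#' @param level significance level (default 0.05 for 95% intervals).
#' @return list with `ci_low`, `ci_high`, `p_values`.
#' @export
wald_inference <- function(est, se, level = 0.05) {
  stopifnot(length(est) == length(se), all(se >= 0 | is.na(se)),
            level > 0, level < 1)
  zq <- qnorm(1 - level / 2)
  p <- ifelse(se > 0, 2 * (1 - pnorm(abs(est / se))),
              ifelse(est == 0, 1, 0))
  list(ci_low = est - zq * se, ci_high = est + zq * se, p_values = p)
}

#' Attach bootstrap standard errors and Wald inference to a fit
#'
#' Refits the model on `B` bootstrap resamples, stores the resulting
#' standard errors, intervals and p-values on the fit object.
#'
#' @param fit a `gphr_fit` from [fit_ml()] or [fit_gmm()].
#' @param dataset the dataset the fit was computed on.
#' @param B,seed bootstrap settings, see [bootstrap_variance()].
#' @param level Wald significance level.
#' @return the fit with `se`, `ci_low`, `ci_high`, `p_values` filled in.
#' @export
add_bootstrap_inference <- function(fit, dataset, B = 50, seed = NULL,
                                    level = 0.05) {
  est_fun <- if (fit$estimator == "gmm") {
    spec <- fit$spec
    function(d) fit_gmm(d, init = fit$theta, spec = spec)$theta
  } else {
    function(d) fit_ml(fit$model, d, init = fit$theta)$theta
  }
  bv <- bootstrap_variance(dataset, est_fun, B = B, seed = seed)
  wi <- wald_inference(unname(fit$theta), bv$se, level)
  fit$se <- bv$se
  fit$ci_low <- wi$ci_low
  fit$ci_high <- wi$ci_high
  fit$p_values <- wi$p_values
  fit
}

#' Compare fitted models by AIC
#'
#' @param ... `gphr_fit` objects (or a single list of them).
#' @return data.frame sorted by ascending AIC with a `delta_aic` column;
#'   ties keep their input order.
#' @export
#' @examples
#' sc <- earlike_scenario(seed = 1)
#' d <- generate_counts(sc)
#' compare_models(fit_ml("gphr", d), fit_ml("ph", d), fit_ml("gp", d))
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "gphr_fit"))
    fits <- fits[[1]]
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, TRUE, "gphr_fit")))
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    estimator = vapply(fits, `[[`, "", "estimator"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    n_params = vapply(fits, function(f) as.numeric(f$n_params), 0),
    aic = vapply(fits, `[[`, 0, "aic"))
  ord <- order(tab$aic) # stable: ties preserve input order
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  tab
}
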