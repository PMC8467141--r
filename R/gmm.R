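# Generalized method of moments for the GP hurdle regression: moment
# conditions built from the model-implied first two raw moments, the
# quadratic-form objective, weight matrices, fitting, and the sandwich
# variance diagnostic.

#' GMM specification
#'
#' @param weight_strategy `"identity"` (default), `"two_step"` (weight is the
#'   pseudo-inverse of the estimated moment covariance at a first-stage
#'   identity-weight estimate), or `"fixed"` (use `W` as given).
#' @param W fixed weight matrix (symmetric positive semi-definite); required
#'   when `weight_strategy = "fixed"`.
#' @param augment_zero_moment if `TRUE`, append the zero-indicator moments
#'   \eqn{z_i(1\{y_i=0\} - w_i)} to the moment vector. With shared covariates
#'   (`x = z`) the mean/second-moment conditions are duplicated and the model
#'   is under-identified; the augmented block restores identification. Off by
#'   default.
#' @param g2_form second-raw-moment convention, see [moment_g1_g2()].
#' @return a list of class `gmm_spec`.
#' @export
gmm_spec <- function(weight_strategy = c("identity", "two_step", "fixed"),
                     W = NULL, augment_zero_moment = FALSE,
                     g2_form = c("squared", "linear")) {
  weight_strategy <- match.arg(weight_strategy)
  g2_form <- match.arg(g2_form)
  if (weight_strategy == "fixed") {
    if (is.null(W)) stop("fixed strategy requires W", call. = FALSE)
    W <- as.matrix(W)
    if (max(abs(W - t(W))) > 1e-8 * max(1, max(abs(W))))
      stop("W must be symmetric", call. = FALSE)
    if (min(eigen(W, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("W must be positive semi-definite", call. = FALSE)
  }
  structure(list(weight_strategy = weight_strategy, W = W,
                 augment_zero_moment = augment_zero_moment,
                 g2_form = g2_form),
            class = "gmm_spec")
}

.g2_code <- function(spec) if (spec$g2_form == "linear") 1L else 0L

.moment_dim <- function(dataset, spec) {
  d <- 2L * (dataset$p + dataset$q + 2L)
  if (spec$augment_zero_moment) d <- d + dataset$q + 1L
  d
}

#' Per-observation GMM moment vector
#'
#' For stacked covariates \eqn{X_i = (x_i^\top, z_i^\top)^\top}, the moment
#' condition is
#' \deqn{h(y_i, X_i, \theta) = \begin{pmatrix}
#'   X_i (y_i - g_{1i}) \\ X_i (y_i^2 - g_{2i}) \end{pmatrix},}
#' which has expectation zero at the true parameter. Dimension
#' \eqn{2(p+q+2)}, plus \eqn{q+1} when the zero-indicator augmentation is on.
#'
#' @param i observation index.
#' @param theta packed parameter vector.
#' @param dataset a [count_dataset()].
#' @param spec a [gmm_spec()].
#' @return numeric moment vector for observation `i`.
#' @export
moment_vector <- function(i, theta, dataset, spec = gmm_spec()) {
  drop(moment_matrix(theta, dataset, spec)[i, ])
}

#' Matrix of per-observation moment vectors
#'
#' @inheritParams moment_vector
#' @return n x d matrix with row i equal to `moment_vector(i, ...)`.
#' @export
moment_matrix <- function(theta, dataset, spec = gmm_spec()) {
  cpp_moment_matrix(as.numeric(theta), dataset$y, dataset$x, dataset$z,
                    .g2_code(spec), spec$augment_zero_moment)
}

#' Sample moment conditions
#'
#' The average \eqn{h_n(\theta) = n^{-1}\sum_i h(y_i, X_i, \theta)}.
#'
#' @inheritParams moment_vector
#' @return numeric vector of length d.
#' @export
sample_moments <- function(theta, dataset, spec = gmm_spec()) {
  colMeans(moment_matrix(theta, dataset, spec))
}

#' GMM objective
#'
#' The quadratic form \eqn{Q_n(\theta) = h_n(\theta)^\top W h_n(\theta)},
#' non-negative for positive semi-definite `W`. Infeasible `theta` values
#' receive the penalty value `1e10`.
#'
#' @inheritParams moment_vector
#' @param W weight matrix; defaults to the one implied by `spec` (identity
#'   unless fixed).
#' @return non-negative scalar.
#' @export
gmm_objective <- function(theta, dataset, spec = gmm_spec(), W = NULL) {
  d <- .moment_dim(dataset, spec)
  if (is.null(W))
    W <- if (spec$weight_strategy == "fixed") spec$W else diag(d)
  W <- as.matrix(W)
  if (!all(dim(W) == d))
    stop(sprintf("W must be %d x %d", d, d), call. = FALSE)
  cpp_qn(as.numeric(theta), dataset$y, dataset$x, dataset$z, W,
         .g2_code(spec), spec$augment_zero_moment)
}

# Moore-Penrose pseudo-inverse via SVD; singular values below
# tol * max(singular value) are treated as zero.
.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Build a GMM weight matrix
#'
#' `"identity"` returns the identity. `"two_step"` returns the pseudo-inverse
#' of the moment covariance estimate
#' \eqn{\hat\Sigma = n^{-1}\sum_i h_i h_i^\top} evaluated at `theta`
#' (pseudo-inverse because shared covariates duplicate moment rows and make
#' \eqn{\hat\Sigma} singular).
#'
#' @inheritParams moment_vector
#' @param strategy `"identity"` or `"two_step"`.
#' @return d x d weight matrix.
#' @export
make_weight <- function(theta, dataset, strategy = c("identity", "two_step"),
                        spec = gmm_spec()) {
  strategy <- match.arg(strategy)
  d <- .moment_dim(dataset, spec)
  if (strategy == "identity") return(diag(d))
  H <- moment_matrix(theta, dataset, spec)
  Sigma <- crossprod(H) / dataset$n
  W <- .pinv(Sigma)
  (W + t(W)) / 2
}

#' GMM fit of the generalized Poisson hurdle model
#'
#' Minimizes \eqn{Q_n(\theta)} with the simplex optimizer. The default start
#' is the maximum-likelihood estimate (computed on the fly when `init` is
#' `NULL`). Under `"two_step"` weighting, a first stage uses the identity
#' weight, the covariance-based weight is rebuilt at the first-stage
#' solution, and \eqn{Q_n} is minimized once more.
#'
#' The reported `loglik`/`aic` are quasi-values: the GPHR log-likelihood
#' evaluated at the GMM estimate, labelled by `aic_type = "quasi"`.
#'
#' @param dataset a [count_dataset()].
#' @param init packed start; `NULL` (default) uses [fit_ml()].
#' @param spec a [gmm_spec()].
#' @param nm an [nm_config()].
#' @return a `gphr_fit` object with `estimator = "gmm"` and extra fields
#'   `objective` (minimized \eqn{Q_n}), `W` and `spec`.
#' @export
fit_gmm <- function(dataset, init = NULL, spec = gmm_spec(),
                    nm = nm_config()) {
  if (is.null(init)) init <- fit_ml("gphr", dataset, nm = nm)$theta
  d <- .moment_dim(dataset, spec)
  W <- switch(spec$weight_strategy,
              identity = diag(d),
              fixed = spec$W,
              two_step = diag(d))
  run <- function(th0, W)
    cpp_fit_gmm(dataset$y, dataset$x, dataset$z, W, as.numeric(th0),
                .g2_code(spec), spec$augment_zero_moment,
                nm$eta, nm$gamma, nm$xi, nm$kappa, nm$eps, nm$max_iter,
                nm$init_step)
  res <- run(init, W)
  if (spec$weight_strategy == "two_step") {
    W <- make_weight(res$par, dataset, "two_step", spec)
    res <- run(res$par, W)
  }
  theta <- stats::setNames(res$par, names(init))
  ll <- loglik_gphr(theta, dataset)
  k <- .n_params("gphr", dataset)
  structure(list(model = "gphr", estimator = "gmm", theta = theta,
                 loglik = ll, aic = aic(ll, k), aic_type = "quasi",
                 n_params = k, converged = res$converged,
                 n_iter = res$n_iter, objective = res$value, W = W,
                 spec = spec,
                 se = NULL, ci_low = NULL, ci_high = NULL, p_values = NULL),
            class = "gphr_fit")
}

#' Sandwich variance diagnostic for the GMM estimator
#'
#' Estimates the asymptotic covariance
#' \deqn{\Gamma = (G^\top W G)^{-1} G^\top W \Sigma W G (G^\top W G)^{-1}}
#' of \eqn{\sqrt{n}(\hat\theta - \theta_0)}, with the moment Jacobian `G`
#' obtained by central finite differences on [sample_moments()] and
#' \eqn{\hat\Sigma = n^{-1}\sum_i h_i h_i^\top}. Pseudo-inverses replace
#' inverses wherever \eqn{G^\top W G} is singular, and the numerical rank of
#' `G` is reported so identification failures (notably under shared
#' covariates `x = z`) are visible rather than silent.
#'
#' @param theta_hat GMM estimate (packed).
#' @param dataset a [count_dataset()].
#' @param spec a [gmm_spec()].
#' @param W the weight matrix used in fitting; defaults per `spec`.
#' @param rel_step relative finite-difference step.
#' @return list with `G`, `Sigma_hat`, `Gamma_hat`, `jacobian_rank`, and
#'   per-parameter asymptotic standard errors `se` (already divided by
#'   \eqn{\sqrt{n}}).
#' @export
gmm_asymptotic_variance <- function(theta_hat, dataset, spec = gmm_spec(),
                                    W = NULL, rel_step = 1e-5) {
  d <- .moment_dim(dataset, spec)
  if (is.null(W))
    W <- if (spec$weight_strategy == "fixed") spec$W else diag(d)
  m <- length(theta_hat)
  G <- matrix(0, d, m)
  for (j in seq_len(m)) {
    h <- rel_step * max(abs(theta_hat[j]), 1)
    tp <- tm <- as.numeric(theta_hat)
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    G[, j] <- (sample_moments(tp, dataset, spec) -
               sample_moments(tm, dataset, spec)) / (2 * h)
  }
  H <- moment_matrix(theta_hat, dataset, spec)
  Sigma <- crossprod(H) / dataset$n
  A <- t(G) %*% W %*% G
  Ainv <- .pinv(A)
  Gamma <- Ainv %*% t(G) %*% W %*% Sigma %*% W %*% G %*% Ainv
  Gamma <- (Gamma + t(Gamma)) / 2
  rank_G <- qr(G, tol = 1e-10)$rank
  dg <- diag(Gamma)
  list(G = G, Sigma_hat = Sigma, Gamma_hat = Gamma,
       jacobian_rank = rank_G,
       se = ifelse(dg > 0, sqrt(dg / dataset$n), NA_real_))
}
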