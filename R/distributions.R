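# Generalized Poisson (GP2) distribution, its zero-truncated form, and the
# hurdle mixture built from them: exact pmfs, closed-form moments, and
# inverse-CDF samplers.

.check_gp <- function(mu, alpha) {
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("invalid GP parameters: mu must be positive and finite", call. = FALSE)
  if (any(!is.finite(alpha)) || any(1 + alpha * mu <= 0))
    stop("invalid GP parameters: 1 + alpha*mu must be positive", call. = FALSE)
  invisible(TRUE)
}

.check_w <- function(w) {
  if (any(!is.finite(w)) || any(w <= 0) || any(w >= 1))
    stop("invalid hurdle parameter: w must lie strictly in (0, 1)",
         call. = FALSE)
  invisible(TRUE)
}

#' Generalized Poisson probability mass function
#'
#' Evaluates the two-parameter generalized Poisson (GP2) pmf
#' \deqn{P(Y=y) = \left[\frac{\mu}{1+\alpha\mu}\right]^y
#'   \frac{(1+\alpha y)^{y-1}}{y!}
#'   \exp\left[-\frac{\mu(1+\alpha y)}{1+\alpha\mu}\right],}
#' which has mean \eqn{\mu} and variance \eqn{\mu(1+\alpha\mu)^2}. The
#' dispersion parameter \eqn{\alpha} controls the variance-to-mean ratio:
#' positive values give over-dispersion, negative values under-dispersion,
#' and \eqn{\alpha = 0} recovers the Poisson distribution. For
#' \eqn{\alpha < 0} the support is truncated at the largest integer with
#' \eqn{1 + \alpha y > 0}; mass beyond that point is zero and the pmf is not
#' renormalized (see [gp_mass_deficit()]).
#'
#' Evaluation is done in log space with `lgamma` so that large counts do not
#' overflow.
#'
#' @param y vector of non-negative integers.
#' @param mu positive mean parameter (recycled against `y`).
#' @param alpha dispersion parameter; must satisfy `1 + alpha*mu > 0`.
#' @param log if `TRUE`, return log-probabilities.
#' @return numeric vector of (log-)probabilities.
#' @seealso [gp_moments()], [rgp()], [dgphurdle()]
#' @export
#' @examples
#' dgp(0:5, mu = 2, alpha = 0.5)
#' all.equal(dgp(0:10, 2, 0), dpois(0:10, 2))
dgp <- function(y, mu, alpha, log = FALSE) {
  .check_gp(mu, alpha)
  if (any(y < 0) || any(y != floor(y)))
    stop("y must contain non-negative integers", call. = FALSE)
  n <- max(length(y), length(mu), length(alpha))
  y <- rep_len(y, n); mu <- rep_len(mu, n); alpha <- rep_len(alpha, n)
  am <- 1 + alpha * mu
  ay <- 1 + alpha * y
  lp <- ifelse(ay > 0,
               y * base::log(mu / am) + (y - 1) * base::log(pmax(ay, .Machine$double.xmin)) -
                 lgamma(y + 1) - mu * ay / am,
               -Inf)
  if (log) lp else exp(lp)
}

#' Mean and variance of the generalized Poisson distribution
#'
#' @inheritParams dgp
#' @return a list with elements `mean` (\eqn{\mu}) and `variance`
#'   (\eqn{\mu(1+\alpha\mu)^2}).
#' @export
#' @examples
#' gp_moments(2, 0.5)  # variance 8: over-dispersed
gp_moments <- function(mu, alpha) {
  .check_gp(mu, alpha)
  list(mean = mu, variance = mu * (1 + alpha * mu)^2)
}

#' Convert GP2 parameters to the GP1 parameterization
#'
#' The two common parameterizations of the generalized Poisson distribution
#' coincide under \eqn{\lambda_1 = \mu/(1+\alpha\mu)},
#' \eqn{\lambda_2 = \alpha\mu/(1+\alpha\mu)}; the inverse map satisfies
#' \eqn{\mu = \lambda_1/(1-\lambda_2)}.
#'
#' @inheritParams dgp
#' @return a list with elements `lambda1` and `lambda2`.
#' @export
gp1_from_gp2 <- function(mu, alpha) {
  .check_gp(mu, alpha)
  am <- 1 + alpha * mu
  list(lambda1 = mu / am, lambda2 = alpha * mu / am)
}

# Cumulative pmf table up to the support cap: the smallest y whose cumulative
# mass exceeds 1 - tol (hard ceiling 1e6), or the truncation point for
# alpha < 0. Returns the vector of pmf values for y = 0, 1, ..., cap.
.gp_pmf_table <- function(mu, alpha, tol = 1e-12, ceiling_y = 1e6) {
  .check_gp(mu, alpha)
  upper <- if (alpha < 0) floor(-1 / alpha - 1e-12) else ceiling_y
  # grow in blocks; typical mu keeps this small
  block <- max(64L, ceiling(4 * mu * (1 + abs(alpha) * mu)^2))
  ys <- 0:min(block, upper)
  p <- dgp(ys, mu, alpha)
  while (sum(p) < 1 - tol && max(ys) < upper) {
    nxt <- (max(ys) + 1):min(max(ys) + block, upper)
    p <- c(p, dgp(nxt, mu, alpha))
    ys <- c(ys, nxt)
  }
  cum <- cumsum(p)
  keep <- if (any(cum >= 1 - tol)) seq_len(which(cum >= 1 - tol)[1]) else seq_along(p)
  p[keep]
}

#' Total mass deficit of the generalized Poisson pmf
#'
#' For \eqn{\alpha < 0} the pmf assigns zero mass beyond the support
#' truncation point and consequently sums to slightly less than one. This
#' diagnostic reports \eqn{1 - \sum_y P(Y=y)} over the full (capped) support;
#' it is numerically zero for \eqn{\alpha \ge 0}.
#'
#' @inheritParams dgp
#' @return non-negative scalar mass deficit.
#' @export
gp_mass_deficit <- function(mu, alpha) {
  max(0, 1 - sum(.gp_pmf_table(mu, alpha)))
}

#' Sample from the generalized Poisson distribution
#'
#' Inverse-CDF sampling over the sequentially accumulated pmf, capped at the
#' smallest count whose cumulative mass exceeds \eqn{1-10^{-12}}. For
#' \eqn{\alpha < 0} draws are conditioned on the truncated support (the tiny
#' mass deficit is renormalized away).
#'
#' @param n number of draws.
#' @param mu,alpha GP2 parameters, scalars.
#' @param seed optional integer seed (calls `set.seed`).
#' @return integer vector of length `n`.
#' @export
#' @examples
#' mean(rgp(1e4, mu = 2, alpha = 0.5, seed = 1))
rgp <- function(n, mu, alpha, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- .gp_pmf_table(mu, alpha)
  cum <- cumsum(p) / sum(p)
  findInterval(runif(n), cum) # counts 0..cap
}

#' Sample from the zero-truncated generalized Poisson distribution
#'
#' Inverse-CDF draws from \eqn{P(Y=j \mid Y \ge 1) = g(j)/(1-g(0))}; never
#' returns zero.
#'
#' @inheritParams rgp
#' @return integer vector of positive counts.
#' @export
rtgp <- function(n, mu, alpha, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- .gp_pmf_table(mu, alpha)
  if (length(p) < 2)
    stop("degenerate truncated distribution: no mass above zero", call. = FALSE)
  p <- p[-1]
  cum <- cumsum(p) / sum(p)
  1L + findInterval(runif(n), cum)
}

#' Generalized Poisson hurdle probability mass function
#'
#' Two-part mixture: zeros occur with probability `w`; positive counts follow
#' the zero-truncated GP2 distribution,
#' \deqn{P(Y=j) = w \; (j=0), \qquad
#'   P(Y=j) = (1-w)\,\frac{g(j)}{1-g(0)} \; (j \ge 1),}
#' where \eqn{g} is the GP2 pmf and \eqn{g(0) = \exp[-\mu/(1+\alpha\mu)]}.
#' The model captures both excess zeros (\eqn{w > g(0)}) and a shortage of
#' zeros (\eqn{w < g(0)}); it collapses to the plain GP2 distribution when
#' \eqn{w = g(0)}.
#'
#' @param j vector of non-negative integers.
#' @param w zero-process probability in (0, 1).
#' @param mu,alpha GP2 parameters of the positive process.
#' @param log if `TRUE`, return log-probabilities.
#' @return numeric vector of (log-)probabilities.
#' @export
#' @examples
#' dgphurdle(0:5, w = 0.3, mu = 2, alpha = 0.5)
dgphurdle <- function(j, w, mu, alpha, log = FALSE) {
  .check_gp(mu, alpha); .check_w(w)
  n <- max(length(j), length(w), length(mu), length(alpha))
  j <- rep_len(j, n); w <- rep_len(w, n)
  mu <- rep_len(mu, n); alpha <- rep_len(alpha, n)
  c0 <- mu / (1 + alpha * mu)
  lp <- ifelse(j == 0,
               base::log(w),
               base::log1p(-w) + dgp(pmax(j, 1), mu, alpha, log = TRUE) -
                 base::log(-expm1(-c0)))
  if (log) lp else exp(lp)
}

#' Mean and variance of the generalized Poisson hurdle distribution
#'
#' Closed-form moments of the hurdle mixture: with hurdle factor
#' \eqn{r = (1-w)/(1 - e^{-\mu/(1+\alpha\mu)})},
#' \deqn{E[Y] = r\mu, \qquad
#'   Var[Y] = r\,[\mu(1+\alpha\mu)^2 + \mu^2] - (r\mu)^2.}
#' The bracket is the untruncated GP2 second raw moment (variance plus
#' squared mean).
#'
#' @inheritParams dgphurdle
#' @return a list with elements `mean` and `variance`.
#' @export
gphurdle_moments <- function(w, mu, alpha) {
  .check_gp(mu, alpha); .check_w(w)
  c0 <- mu / (1 + alpha * mu)
  r <- (1 - w) / (-expm1(-c0))
  m <- r * mu
  list(mean = m, variance = r * (mu * (1 + alpha * mu)^2 + mu^2) - m^2)
}
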