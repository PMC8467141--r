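# Count-data container and the packed parameter vector used by all fitters.

#' Construct a count-regression dataset
#'
#' Bundles a non-negative integer response with the two design matrices of a
#' hurdle regression: `x_design` drives the count (positive-part) mean via a
#' log link, `z_design` drives the zero-process probability via a logit link.
#' Both matrices must carry an intercept as their first column and have full
#' column rank. The same object serves the one-part GP regression, which
#' simply ignores `z_design`.
#'
#' @param y non-negative integer response vector.
#' @param x_design numeric matrix, n x (p+1), first column all ones.
#' @param z_design numeric matrix, n x (q+1), first column all ones; defaults
#'   to `x_design` (the common case where both parts share covariates).
#' @return an object of class `count_dataset` with elements `y`, `x`, `z`,
#'   `n`, `p`, `q`.
#' @export
#' @examples
#' x <- cbind(1, runif(20))
#' count_dataset(rpois(20, 2), x)
count_dataset <- function(y, x_design, z_design = x_design) {
  y <- as.numeric(y)
  x_design <- as.matrix(x_design)
  z_design <- as.matrix(z_design)
  n <- length(y)
  if (n < 1) stop("empty response", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y)))
    stop("response must be finite non-negative integers", call. = FALSE)
  if (nrow(x_design) != n || nrow(z_design) != n)
    stop("design matrices must have one row per observation", call. = FALSE)
  for (nm in c("x_design", "z_design")) {
    m <- if (nm == "x_design") x_design else z_design
    if (any(m[, 1] != 1))
      stop(nm, ": first column must be an all-ones intercept", call. = FALSE)
    if (qr(m)$rank < ncol(m))
      stop(nm, " is column-rank deficient", call. = FALSE)
  }
  structure(
    list(y = y, x = x_design, z = z_design,
         n = n, p = ncol(x_design) - 1L, q = ncol(z_design) - 1L),
    class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf(
    "count_dataset: n = %d, zeros = %d (%.1f%%), mean = %.3f, var = %.3f\n",
    x$n, sum(x$y == 0), 100 * mean(x$y == 0), mean(x$y), var(x$y)))
  cat(sprintf("  count part: %d covariate(s); zero part: %d covariate(s)\n",
              x$p, x$q))
  invisible(x)
}

#' Row-subset a count dataset
#'
#' @param dataset a [count_dataset()].
#' @param idx integer row indices (with repeats allowed, as in bootstrap
#'   resampling).
#' @return a new `count_dataset`. Rank revalidation is skipped: resamples of
#'   a valid design are accepted even if a particular draw is degenerate (the
#'   fitter flags such cases through non-convergence instead).
#' @export
dataset_subset <- function(dataset, idx) {
  structure(
    list(y = dataset$y[idx],
         x = dataset$x[idx, , drop = FALSE],
         z = dataset$z[idx, , drop = FALSE],
         n = length(idx), p = dataset$p, q = dataset$q),
    class = "count_dataset")
}

#' Pack hurdle-model parameters into a single vector
#'
#' The fitters work on the packed vector
#' \eqn{\theta = (\alpha, \beta^\top, \delta^\top)^\top}: dispersion first,
#' then the count-part coefficients, then the zero-part coefficients.
#' `theta_pack()` and `theta_unpack()` are exact inverses.
#'
#' @param alpha scalar dispersion, or `NULL` for models without one.
#' @param beta count-part coefficient vector (length p+1).
#' @param delta zero-part coefficient vector (length q+1), or `NULL` for the
#'   one-part GP regression.
#' @return named numeric vector.
#' @export
#' @examples
#' th <- theta_pack(0.2, c(0.1, -0.5), c(1, 0.3))
#' theta_unpack(th, p = 1, q = 1)
theta_pack <- function(alpha = NULL, beta, delta = NULL) {
  out <- c(if (!is.null(alpha)) c(alpha = unname(alpha)),
           stats::setNames(beta, paste0("beta", seq_along(beta) - 1L)),
           if (!is.null(delta))
             stats::setNames(delta, paste0("delta", seq_along(delta) - 1L)))
  out
}

#' @rdname theta_pack
#' @param theta packed parameter vector.
#' @param p,q numbers of non-intercept covariates in the count and zero parts;
#'   use `q = NULL` for GP regression and `has_alpha = FALSE` for the Poisson
#'   hurdle.
#' @param has_alpha whether `theta` carries a leading dispersion parameter.
#' @export
theta_unpack <- function(theta, p, q = NULL, has_alpha = TRUE) {
  expected <- (if (has_alpha) 1L else 0L) + (p + 1L) +
    (if (is.null(q)) 0L else q + 1L)
  if (length(theta) != expected)
    stop(sprintf("theta has length %d, expected %d", length(theta), expected),
         call. = FALSE)
  i <- 1L
  alpha <- NULL
  if (has_alpha) { alpha <- unname(theta[1L]); i <- 2L }
  beta <- unname(theta[i:(i + p)])
  delta <- if (!is.null(q)) unname(theta[(i + p + 1L):length(theta)])
  list(alpha = alpha, beta = beta, delta = delta)
}
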