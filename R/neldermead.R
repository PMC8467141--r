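# Derivative-free simplex minimizer. All model fitting in this package goes
# through the same compiled routine; this file exposes it for arbitrary R
# objectives and holds the configuration container.

#' Nelder-Mead configuration
#'
#' Coefficients of the simplex moves and the stopping rule. Defaults are the
#' standard settings: reflection \eqn{\eta = 1}, expansion \eqn{\gamma = 2},
#' contraction \eqn{\xi = 1/2}, shrink \eqn{\kappa = 1/2}. Iteration stops
#' when the root-mean-square spread of the objective over the m best vertices
#' drops below `eps`, when the simplex diameter collapses below
#' `eps * (1 + ||best||)` (guards flat objectives), or at `max_iter`.
#'
#' @param eta reflection coefficient, > 0.
#' @param gamma expansion coefficient, > 1.
#' @param xi contraction coefficient, in (0, 1).
#' @param kappa shrink coefficient, in (0, 1).
#' @param eps stopping tolerance on the objective spread. The default
#'   `1e-10` is tight enough that the returned vertex, not just its objective
#'   value, is resolved to roughly the square root of `eps`.
#' @param max_iter iteration cap.
#' @param init_step relative edge length of the initial simplex: coordinate i
#'   of vertex i is displaced by `init_step * max(|x0_i|, 1)`.
#' @return a list of class `nm_config`.
#' @export
nm_config <- function(eta = 1, gamma = 2, xi = 0.5, kappa = 0.5,
                      eps = 1e-10, max_iter = 5000L, init_step = 0.05) {
  stopifnot(eta > 0, gamma > 1, xi > 0, xi < 1, kappa > 0, kappa < 1,
            eps > 0, max_iter >= 1)
  structure(list(eta = eta, gamma = gamma, xi = xi, kappa = kappa,
                 eps = eps, max_iter = as.integer(max_iter),
                 init_step = init_step),
            class = "nm_config")
}

#' Initial simplex construction
#'
#' Vertex 0 is the starting point; vertex i displaces coordinate i by
#' `step * max(|x0_i|, 1)`, giving m+1 affinely independent vertices.
#'
#' @param x0 numeric starting vector of length m.
#' @param step relative edge length.
#' @return (m+1) x m matrix, one vertex per row.
#' @export
initial_simplex <- function(x0, step = 0.05) {
  m <- length(x0)
  v <- matrix(rep(x0, each = m + 1), nrow = m + 1)
  for (i in seq_len(m))
    v[i + 1, i] <- x0[i] + step * max(abs(x0[i]), 1)
  v
}

#' Minimize a function by the Nelder-Mead simplex method
#'
#' Iterates ordering, reflection, expansion, outside/inside contraction and
#' shrink steps of an (m+1)-vertex simplex. Deterministic: identical inputs
#' produce identical iterate sequences (ties in the vertex ordering are
#' broken by insertion order).
#'
#' @param f objective, a function of a numeric vector returning a finite
#'   scalar (penalize infeasible regions inside `f`).
#' @param x0 numeric starting vector.
#' @param config an [nm_config()].
#' @return list with `par`, `value`, `n_iter`, `converged`.
#' @export
#' @examples
#' nelder_mead(function(x) sum((x - c(1, 2))^2), c(0, 0))$par
nelder_mead <- function(f, x0, config = nm_config()) {
  stopifnot(inherits(config, "nm_config"), length(x0) >= 1)
  cpp_nelder_mead(function(x) as.numeric(f(x)), as.numeric(x0),
                  config$eta, config$gamma, config$xi, config$kappa,
                  config$eps, config$max_iter, config$init_step)
}
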