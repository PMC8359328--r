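#' Gauss-Hermite quadrature specification
#'
#' Integration over the latent distribution uses a Gauss-Hermite product grid
#' for the standard normal in each dimension. A nonzero latent correlation is
#' handled by reweighting the fixed grid with the bivariate-normal density
#' ratio `phi2(theta; rho) / (phi(theta1) phi(theta2))`, so the item trace
#' lines never depend on `rho` and the EM update for `rho` reduces to a
#' one-dimensional maximization over the prior weights. Weights are normalized
#' to sum to one.
#'
#' @param nodes_per_dim number of nodes per dimension (>= 11; default 21).
#' @param ndim number of latent dimensions (1 or 2).
#' @return An object of class `dsrt_quad`: node matrix `theta` (Q x ndim),
#'   base log-weights `logw0`, and metadata.
#' @export
quad_spec <- function(nodes_per_dim = 21L, ndim = 1L) {
  if (nodes_per_dim < 11L) abort("`nodes_per_dim` must be at least 11.")
  gh <- pracma::gaussHermite(as.integer(nodes_per_dim))
  x <- gh$x * sqrt(2)          # standard-normal nodes
  lw <- log(gh$w) - 0.5 * log(pi)
  if (ndim == 1L) {
    theta <- cbind(theta1 = x)
    logw0 <- lw
  } else if (ndim == 2L) {
    g <- expand.grid(q1 = seq_along(x), q2 = seq_along(x))
    theta <- cbind(theta1 = x[g$q1], theta2 = x[g$q2])
    logw0 <- lw[g$q1] + lw[g$q2]
  } else {
    abort("Only 1- or 2-dimensional quadrature is supported.")
  }
  structure(list(theta = theta, logw0 = logw0 - logsumexp(logw0),
                 nodes_per_dim = as.integer(nodes_per_dim), ndim = as.integer(ndim)),
            class = "dsrt_quad")
}

# Normalized log prior weights at correlation rho.
quad_logw <- function(quad, rho = 0) {
  lw <- quad$logw0
  if (quad$ndim == 2L && rho != 0) {
    if (abs(rho) >= 1) abort("`rho` must lie in (-1, 1).")
    t1 <- quad$theta[, 1L]; t2 <- quad$theta[, 2L]
    lw <- lw - 0.5 * log(1 - rho^2) -
      (rho^2 * (t1^2 + t2^2) - 2 * rho * t1 * t2) / (2 * (1 - rho^2))
    lw <- lw - logsumexp(lw)
  }
  lw
}

#' @export
print.dsrt_quad <- function(x, ...) {
  cat(sprintf("<dsrt_quad> %d-D Gauss-Hermite grid, %d nodes/dim (%d total)\n",
              x$ndim, x$nodes_per_dim, nrow(x$theta)))
  invisible(x)
}
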