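# Independent brute-force oracles used to validate the quadrature machinery.
# These deliberately re-derive the category probabilities with plain R code
# and integrate on dense grids instead of reusing the package's internals.

# softmax category probabilities, written out directly
oracle_probs_1d <- function(theta, alpha, beta) {
  l <- (0:3) * alpha * theta + c(0, beta)
  exp(l) / sum(exp(l))
}

oracle_probs_2d <- function(theta1, theta2, alpha1, alpha2, beta,
                            c1 = 0:3, c2 = c(1, 0, 0, 1)) {
  l <- c1 * alpha1 * theta1 + c2 * alpha2 * theta2 + c(0, beta)
  exp(l) / sum(exp(l))
}

# grid x category probability matrix for one item (plain matrix algebra)
oracle_pmat <- function(t1, t2, alpha1, alpha2, beta,
                        c1 = 0:3, c2 = c(1, 0, 0, 1)) {
  l <- outer(alpha1 * t1, c1) + outer(alpha2 * t2, c2) +
    matrix(c(0, beta), length(t1), 4, byrow = TRUE)
  e <- exp(l)
  e / rowSums(e)
}

# dense-grid marginal log-likelihood, unidimensional
oracle_loglik_1d <- function(scores, alphas, betas, n_grid = 4001, lim = 9) {
  th <- seq(-lim, lim, length.out = n_grid)
  w <- dnorm(th); w <- w / sum(w)
  K <- ncol(scores)
  P <- lapply(seq_len(K), function(k) {
    oracle_pmat(th, rep(0, n_grid), alphas[k], 0, betas[k, ])
  })
  sum(apply(scores, 1L, function(row) {
    lik <- rep(1, n_grid)
    for (k in seq_len(K)) {
      if (is.na(row[k])) next
      lik <- lik * P[[k]][, row[k] + 1L]
    }
    log(sum(w * lik))
  }))
}

# dense-grid marginal log-likelihood, two-dimensional with correlation rho
oracle_loglik_2d <- function(scores, alpha1, alpha2, betas, rho,
                             n_grid = 201, lim = 6) {
  th <- seq(-lim, lim, length.out = n_grid)
  g <- expand.grid(t1 = th, t2 = th)
  w <- exp(-(g$t1^2 - 2 * rho * g$t1 * g$t2 + g$t2^2) / (2 * (1 - rho^2)))
  w <- w / sum(w)
  K <- ncol(scores)
  P <- lapply(seq_len(K), function(k) {
    oracle_pmat(g$t1, g$t2, alpha1[k], alpha2[k], betas[k, ])
  })
  sum(apply(scores, 1L, function(row) {
    lik <- rep(1, nrow(g))
    for (k in seq_len(K)) {
      if (is.na(row[k])) next
      lik <- lik * P[[k]][, row[k] + 1L]
    }
    log(sum(w * lik))
  }))
}
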