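#' Category probabilities of the discretized SRT model family
#'
#' All members of the family are adjacent-category / nominal softmax models on
#' the polytomous SRT score `s = 0..C-1`:
#' * `prob_coomans()`: single item parameter, `P(S = s) softmax s(theta - delta)`.
#' * `prob_gpcm1d()`: generalized partial-credit form,
#'   `softmax(s * alpha * theta + beta_s)` with `beta_0 = 0`.
#' * `prob_2d()`: two-dimensional model with an ability dimension scored by
#'   `c1` (default `0:3`) and a speed dimension scored by `c2`
#'   (default `c(1, 0, 0, 1)`, the fast-response indicator):
#'   `softmax(c1_s alpha1 theta1 + c2_s alpha2 theta2 + beta_s)`.
#' * `prob_nominal()`: the general multidimensional nominal form with arbitrary
#'   per-dimension scoring vectors.
#'
#' All functions are vectorized over `theta` and return a matrix with one row
#' per theta value and `C` columns (a plain probability vector for scalar
#' input). Rows sum to one; computation subtracts the maximum logit before
#' exponentiation.
#'
#' @param theta,theta1,theta2 latent variable value(s).
#' @param delta item difficulty (single-parameter model).
#' @param alpha,alpha1,alpha2 positive item slope(s).
#' @param beta category intercepts `beta_1..beta_{C-1}` (`beta_0` fixed at 0).
#' @param c1,c2 scoring vectors of length `C` for the ability and speed
#'   dimensions.
#' @return Probability vector (scalar theta) or matrix (vector theta).
#' @examples
#' prob_gpcm1d(0, 0.5, c(1.5, 1.5, 0)) # approx .1 .4 .4 .1
#' prob_2d(0, 1, alpha1 = 0.5, alpha2 = 1, beta = c(0, 0, 0))
#' @name srt-probabilities
NULL

#' @rdname srt-probabilities
#' @export
prob_coomans <- function(theta, delta) {
  prob_nominal(cbind(theta), list(0:3), alpha = cbind(1),
               beta = -(1:3) * delta)
}

#' @rdname srt-probabilities
#' @export
prob_gpcm1d <- function(theta, alpha, beta) {
  if (alpha <= 0) abort("`alpha` must be strictly positive.")
  C <- length(beta) + 1L
  prob_nominal(cbind(theta), list(seq_len(C) - 1L), alpha = cbind(alpha), beta = beta)
}

#' @rdname srt-probabilities
#' @export
prob_2d <- function(theta1, theta2, alpha1, alpha2, beta,
                    c1 = seq_along(c(0, beta)) - 1, c2 = NULL) {
  if (alpha1 <= 0 || alpha2 <= 0) abort("Slopes must be strictly positive.")
  C <- length(beta) + 1L
  if (is.null(c2)) {
    if (C != 4L) abort("Supply `c2` explicitly when the number of categories is not 4.")
    c2 <- c(1, 0, 0, 1)
  }
  prob_nominal(cbind(theta1, theta2), list(c1, c2),
               alpha = cbind(alpha1, alpha2), beta = beta)
}

#' @rdname srt-probabilities
#' @param scoring list of scoring vectors, one per dimension, each length `C`.
#' @export
prob_nominal <- function(theta, scoring, alpha, beta) {
  theta <- as.matrix(theta)
  alpha <- matrix(alpha, nrow = 1L)
  M <- length(scoring)
  if (ncol(theta) != M || ncol(alpha) != M) {
    abort("`theta` columns, `scoring` vectors and `alpha` entries must match in number.")
  }
  C <- length(beta) + 1L
  if (any(vapply(scoring, length, 1L) != C)) {
    abort(sprintf("Every scoring vector must have length %d.", C))
  }
  b <- c(0, beta)
  logits <- matrix(b, nrow(theta), C, byrow = TRUE)
  for (m in seq_len(M)) {
    logits <- logits + outer(alpha[, m] * theta[, m], scoring[[m]])
  }
  p <- softmax_rows(logits)
  colnames(p) <- paste0("s", seq_len(C) - 1L)
  if (nrow(p) == 1L) drop(p) else p
}

#' Conditional probability of a fast response given accuracy
#'
#' Under the discretized SRT models the probability that a response is fast,
#' conditional on it being correct, is the ratio `P(S=3) / (P(S=2) + P(S=3))`;
#' conditional on incorrect it is `P(S=0) / (P(S=0) + P(S=1))`. Under the
#' unidimensional model the former increases and the latter decreases in theta,
#' which is why these models predict negatively correlated speed indicators
#' across items that differ in accuracy.
#'
#' @inheritParams srt-probabilities
#' @param x binary accuracy the probability conditions on.
#' @param theta2 speed latent value; omit (`NULL`) for the unidimensional model.
#' @param alpha2 speed slope (two-dimensional model only).
#' @return Conditional probability(ies) of `T* = 1`.
#' @export
p_fast_given_accuracy <- function(theta1, alpha1, beta, x,
                                  theta2 = NULL, alpha2 = NULL) {
  stopifnot(length(beta) == 3L)
  if (is.null(theta2)) {
    p <- prob_gpcm1d_rows(theta1, alpha1, beta)
  } else {
    n <- max(length(theta1), length(theta2))
    p <- t(vapply(seq_len(n), function(i) {
      prob_2d(rep_len(theta1, n)[i], rep_len(theta2, n)[i], alpha1, alpha2, beta)
    }, numeric(4L)))
  }
  ifelse(rep_len(x, nrow(p)) == 1,
         p[, 4L] / (p[, 3L] + p[, 4L]),
         p[, 1L] / (p[, 1L] + p[, 2L]))
}

prob_gpcm1d_rows <- function(theta, alpha, beta) {
  p <- prob_gpcm1d(theta, alpha, beta)
  if (is.null(dim(p))) matrix(p, 1L) else p
}

#' Convert between intercept and step parameterizations
#'
#' The adjacent-category intercepts `beta_s` and the step ("threshold")
#' parameters `beta*_r` of the partial credit model are related by
#' `beta_s = -sum_{r <= s} beta*_r`. The two parameterizations give identical
#' category probabilities.
#'
#' @param beta_star step parameters (length `C - 1`).
#' @param beta category intercepts (length `C - 1`).
#' @return The converted parameter vector.
#' @export
masters_to_intercepts <- function(beta_star) -cumsum(beta_star)

#' @rdname masters_to_intercepts
#' @export
intercepts_to_masters <- function(beta) -diff(c(0, beta))
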