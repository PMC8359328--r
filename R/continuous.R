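#' Continuous SRT joint density of accuracy and response time
#'
#' Joint density of the binary accuracy `x` and the response time `t` under the
#' continuous SRT model with discrimination. Writing `a = alpha * (theta -
#' delta)` and the signed residual time `s = (2x - 1)(deadline - t)`, the
#' density is the truncated exponential family
#' `f(x, t | theta) = a * exp(s * a) / (exp(deadline * a) - exp(-deadline * a))`,
#' which integrates to one over `x` in `{0, 1}` and `t` in `[0, deadline]`
#' for any deadline. At `theta = delta` the analytic limit is the uniform
#' density `1 / (2 * deadline)`. The implied marginal probability of a correct
#' response is `plogis(deadline * alpha * (theta - delta))`, a two-parameter
#' logistic model.
#'
#' @param x binary accuracy (0/1).
#' @param t response time, `0 <= t <= deadline` (values outside error).
#' @param theta ability.
#' @param delta item difficulty.
#' @param alpha positive discrimination.
#' @param deadline item time limit.
#' @return Density value(s).
#' @export
srt_density <- function(x, t, theta, delta, alpha = 1, deadline) {
  check_rt(t, deadline)
  if (alpha <= 0) abort("`alpha` must be strictly positive.")
  if (deadline <= 0) abort("`deadline` must be positive.")
  s <- (2 * x - 1) * (deadline - t)
  a <- rep_len(alpha * (theta - delta), length(s))
  out <- ifelse(abs(a) < 1e-10,
                1 / (2 * deadline),
                # kernel / normalizer, computed on the log scale for stability
                exp(log(abs(a)) + s * a -
                      (abs(a) * deadline + log1p(-exp(-2 * abs(a) * deadline)))))
  unname(out)
}

#' @rdname srt_density
#' @details `srt_p_correct()` gives the closed-form marginal accuracy
#'   probability `plogis(deadline * alpha * (theta - delta))`.
#' @export
srt_p_correct <- function(theta, delta, alpha = 1, deadline) {
  stats::plogis(deadline * alpha * (theta - delta))
}
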