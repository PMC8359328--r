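#' Signed residual time score
#'
#' The continuous SRT scoring rule: the time remaining before the deadline is
#' credited for a correct response and subtracted for an incorrect one,
#' `(2x - 1) * (d - t)`. Fast correct responses therefore earn the most and
#' fast incorrect responses the least; a response at the deadline scores 0
#' regardless of accuracy.
#'
#' @param x binary accuracy (0/1), vectorized.
#' @param t response time in seconds, `0 <= t <= deadline`.
#' @param deadline item time limit in seconds (scalar, shared by all items).
#' @return Numeric score(s) in `[-deadline, deadline]`.
#' @examples
#' srt_score(1, 5, 20) # 15
#' srt_score(0, 5, 20) # -15
#' @export
srt_score <- function(x, t, deadline) {
  check_rt(t, deadline)
  if (!all(x %in% c(0, 1))) abort("`x` must be binary (0/1).")
  (2 * x - 1) * (deadline - t)
}

check_rt <- function(t, deadline) {
  if (!is.numeric(deadline) || length(deadline) != 1L || deadline <= 0) {
    abort("`deadline` must be a single positive number.")
  }
  bad <- !is.na(t) & (t < 0 | t > deadline)
  if (any(bad)) {
    abort(sprintf("Response times must lie in [0, %g]; %d value(s) outside.",
                  deadline, sum(bad)))
  }
  invisible(TRUE)
}

#' Discretize response time into speed categories
#'
#' Splits the available time `[0, deadline)` into `n_bins` equal half-open
#' intervals and returns a speed code with the fastest bin coded highest.
#' For `n_bins = 2` this is the fast indicator `T* = 1` iff `t < deadline / 2`;
#' a response at exactly half the deadline is slow (bins are `[lower, upper)`).
#'
#' @inheritParams srt_score
#' @param n_bins number of speed categories (>= 2), default 2.
#' @return Integer speed code(s) in `0..n_bins-1`; `n_bins - 1` is fastest.
#' @examples
#' discretize_rt(9.99, 20) # 1 (fast)
#' discretize_rt(10, 20)   # 0 (slow: boundary goes to the slow side)
#' discretize_rt(7, 20, n_bins = 3) # 1 (middle third)
#' @export
discretize_rt <- function(t, deadline, n_bins = 2L) {
  check_rt(t, deadline)
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 2 || n_bins %% 1 != 0) {
    abort("`n_bins` must be a single integer >= 2.")
  }
  n_bins <- as.integer(n_bins)
  bin <- pmin(floor(t / (deadline / n_bins)), n_bins - 1L) # t == deadline -> slowest
  as.integer(n_bins - 1L - bin)
}

#' Combine accuracy and speed into a polytomous item score
#'
#' The discretized SRT scoring rule. With a fast/slow split the four outcomes
#' are ordered fast-incorrect (0), slow-incorrect (1), slow-correct (2),
#' fast-correct (3). With `n_bins` speed categories the analogous
#' `0 .. 2*n_bins - 1` coding is used: incorrect responses are ordered from
#' fastest to slowest, then correct responses from slowest to fastest, so that
#' score order follows the continuous scoring rule.
#'
#' @param x binary accuracy (0/1).
#' @param t_star speed code from [discretize_rt()] (`0..n_bins-1`, fastest high).
#' @param n_bins number of speed categories the codes come from.
#' @return Integer score(s) in `0..2*n_bins-1`. `NA` propagates.
#' @examples
#' assign_scores(c(0, 0, 1, 1), c(1, 0, 0, 1)) # 0 1 2 3
#' @export
assign_scores <- function(x, t_star, n_bins = 2L) {
  n_bins <- as.integer(n_bins)
  ok <- is.na(x) | (x %in% c(0, 1))
  if (!all(ok)) abort("`x` must be binary (0/1).")
  if (any(!is.na(t_star) & (t_star < 0 | t_star >= n_bins))) {
    abort(sprintf("`t_star` must lie in 0..%d.", n_bins - 1L))
  }
  as.integer(ifelse(x == 1, n_bins + t_star, n_bins - 1L - t_star))
}

#' Score a response dataset
#'
#' Applies [discretize_rt()] and [assign_scores()] columnwise to accuracy and
#' response-time matrices, producing the polytomous score matrix the
#' discretized SRT models are fitted to. Missingness must coincide between
#' accuracy and response time.
#'
#' @param accuracy persons x items binary matrix (NA = not administered).
#' @param rt persons x items response-time matrix, same shape and missingness.
#' @param deadline shared item time limit, seconds.
#' @param n_bins speed categories (default 2: fast/slow at half deadline).
#' @return Integer score matrix with `2 * n_bins` categories and a
#'   `"provenance"` attribute recording the discretization rule.
#' @export
score_responses <- function(accuracy, rt, deadline, n_bins = 2L) {
  accuracy <- as.matrix(accuracy); rt <- as.matrix(rt)
  if (!identical(dim(accuracy), dim(rt))) abort("accuracy and rt must have the same shape.")
  if (!identical(is.na(accuracy), is.na(rt))) {
    abort("Missingness patterns of accuracy and rt must coincide.")
  }
  ts <- discretize_rt(rt, deadline, n_bins)
  s <- assign_scores(as.integer(accuracy), ts, n_bins)
  s <- matrix(s, nrow(accuracy), ncol(accuracy), dimnames = dimnames(accuracy))
  attr(s, "provenance") <- list(
    deadline = deadline, n_bins = as.integer(n_bins),
    boundary = "half-open [lower, upper); boundary response is slow",
    n_categories = 2L * as.integer(n_bins)
  )
  s
}

# decode a 4-category (or 2*n_bins) score back into accuracy / fast indicator
decode_scores <- function(s, n_bins = 2L) {
  x <- ifelse(is.na(s), NA_integer_, as.integer(s >= n_bins))
  t_star <- ifelse(is.na(s), NA_integer_,
                   as.integer(ifelse(s >= n_bins, s - n_bins, n_bins - 1L - s)))
  list(accuracy = x, t_star = t_star,
       fast = ifelse(is.na(t_star), NA_integer_, as.integer(t_star == n_bins - 1L)))
}
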