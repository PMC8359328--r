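#' Draw latent ability and speed values
#'
#' Samples person parameters from a bivariate standard-normal distribution
#' with correlation `rho` (means 0, variances 1, matching the model's
#' identification constraints).
#'
#' @details With `standardize = TRUE` the drawn sample is linearly transformed
#'   so its empirical mean, variances and correlation match the population
#'   values exactly. This matters when one fixed person sample is reused
#'   across many replications: the fitted models are identified by
#'   constraining the latent mean to 0 and variance to 1, so the estimated
#'   scale aligns itself with the *realized* sample moments; if those wobble
#'   around the nominal values (sampling SD of the sample variance is
#'   `sqrt(2/(n-1))`, about 4.5% at n = 1000), every bias/variance summary is
#'   coherently distorted by that one random scale factor. Standardizing the
#'   fixed truth sample to the identification constraints removes it.
#'
#' @param n number of persons.
#' @param rho latent correlation in (-1, 1).
#' @param seed optional integer seed for reproducibility.
#' @param standardize force the sample moments to the population values
#'   exactly (default `FALSE`; used by the study harness for fixed-person
#'   designs).
#' @return An `n` x 2 matrix with columns `theta1` (ability), `theta2` (speed).
#' @export
draw_latents <- function(n, rho = 0, seed = NULL, standardize = FALSE) {
  if (abs(rho) >= 1) abort("`rho` must lie in (-1, 1).")
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(2 * n), n, 2L)
  if (standardize && n > 2L) {
    z <- scale(z, center = TRUE, scale = FALSE)
    z <- z %*% backsolve(chol(stats::cov(z)), diag(2L))   # exact whitening
  }
  theta <- cbind(theta1 = z[, 1L],
                 theta2 = rho * z[, 1L] + sqrt(1 - rho^2) * z[, 2L])
  theta
}

#' Reference item intercept sets
#'
#' The five category-intercept sets used throughout the package's simulation
#' design. For a person at the population mean they imply item-score
#' probability vectors of approximately (.25,.25,.25,.25), (.1,.4,.4,.1),
#' (.4,.1,.1,.4), (.1,.1,.4,.4) and (.4,.4,.1,.1): items differing both in
#' overall difficulty and in the expected share of fast responses.
#'
#' @return A 5 x 3 matrix of intercepts (columns `beta1..beta3`).
#' @export
reference_beta_sets <- function() {
  m <- rbind(c(0, 0, 0),
             c(1.5, 1.5, 0),
             c(-1.5, -1.5, 0),
             c(0, 1.5, 1.5),
             c(0, -1.5, -1.5))
  colnames(m) <- paste0("beta", 1:3)
  m
}

#' Item bank for the simulation design
#'
#' Tiles the five [reference_beta_sets()] `n_items / 5` times with ability
#' slope 0.5 and the given speed slope (0 for the null design without person
#' speed differences, 1 otherwise), in the layout [fit_dsrt()] uses for the
#' two-dimensional model.
#'
#' @param n_items number of items (multiple of 5).
#' @param speed_slope common speed-dimension slope `alpha2` (0 or 1).
#' @param ability_slope common ability slope `alpha1` (default 0.5).
#' @return Tibble with columns `item`, `alpha1`, `alpha2`, `beta1..beta3`.
#' @export
study_item_bank <- function(n_items, speed_slope = 1, ability_slope = 0.5) {
  if (n_items %% 5L != 0L) abort("`n_items` must be a multiple of 5.")
  b <- reference_beta_sets()[rep(1:5, n_items / 5L), , drop = FALSE]
  tibble::tibble(item = paste0("item", seq_len(n_items)),
                 alpha1 = ability_slope, alpha2 = speed_slope,
                 beta1 = b[, 1L], beta2 = b[, 2L], beta3 = b[, 3L])
}

#' Simulate polytomous SRT scores
#'
#' Draws a persons x items score matrix from any model variant at the given
#' item parameters and person latents. Each entry is a categorical draw from
#' the model-implied category probabilities at that person's latent values.
#'
#' @param items natural-scale item parameter tibble in the layout of
#'   [fit_dsrt()] for `model` (e.g. [study_item_bank()] for `"srt2d"`).
#'   A zero `alpha2` column is accepted for the null design: categories are
#'   then generated by the unidimensional model.
#' @param theta person latents: an `N` x 2 matrix from [draw_latents()] (or a
#'   vector for one-dimensional models).
#' @param model generating model tag (see [fit_dsrt()]).
#' @param n_categories number of categories `C` (default 4).
#' @param c1,c2 scoring vectors for `"srt2d"`.
#' @param seed optional integer seed.
#' @return Integer score matrix `N` x `K` with column names from `items$item`.
#' @export
simulate_scores <- function(items, theta, model = "srt2d", n_categories = 4L,
                            c1 = NULL, c2 = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- as.integer(n_categories)
  fam <- make_family(model, C, c1 = c1 %||% (seq_len(C) - 1), c2 = c2)
  theta <- as.matrix(theta)
  if (ncol(theta) < fam$ndim) abort("`theta` has fewer columns than the model needs.")
  # log(0) = -Inf is harmless here: exp(-Inf) * theta = 0, i.e. a dead loading,
  # so alpha2 = 0 null designs generate exactly the unidimensional model
  par <- fam$from_natural(items)
  N <- nrow(theta); K <- nrow(par)
  out <- matrix(NA_integer_, N, K,
                dimnames = list(NULL, items$item %||% paste0("item", seq_len(K))))
  for (k in seq_len(K)) {
    lp <- fam$logprob(par[k, ], theta)          # C x N
    cp <- apply(exp(lp), 2L, cumsum)
    u <- stats::runif(N)
    out[, k] <- colSums(cp < matrix(u, C, N, byrow = TRUE))
  }
  out
}

#' Simulate accuracy and response time from the continuous SRT model
#'
#' Uses the fact that the signed residual time `S = (2X - 1)(deadline - T)`
#' has density proportional to `exp(s * alpha * (theta - delta))` on
#' `[-deadline, deadline]`: `S` is drawn by inverse CDF, then `X = 1` iff
#' `S >= 0` and `T = deadline - |S|`.
#'
#' @param theta vector of person abilities.
#' @param delta vector of item difficulties (length `K`).
#' @param alpha item discriminations (scalar or length `K`).
#' @param deadline shared item time limit.
#' @param seed optional integer seed.
#' @return List with `accuracy` and `rt` matrices (`N` x `K`) and `deadline`.
#' @export
simulate_continuous_srt <- function(theta, delta, alpha = 1, deadline, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- length(theta); K <- length(delta)
  alpha <- rep_len(alpha, K)
  if (any(alpha <= 0)) abort("`alpha` must be strictly positive.")
  acc <- rt <- matrix(NA_real_, N, K, dimnames = list(NULL, paste0("item", seq_len(K))))
  d <- deadline
  for (k in seq_len(K)) {
    a <- alpha[k] * (theta - delta[k])
    u <- stats::runif(N)
    s <- ifelse(abs(a) < 1e-10,
                -d + 2 * d * u,
                # inverse CDF of the exp(s a) kernel truncated to [-d, d],
                # evaluated stably: s = -d + log(1 - u + u e^{2da}) / a
                -d + log1p(u * expm1(2 * d * a)) / a)
    s <- pmin(pmax(s, -d), d)
    acc[, k] <- as.numeric(s >= 0)
    rt[, k] <- d - abs(s)
  }
  list(accuracy = acc, rt = rt, deadline = deadline)
}

#' Remove entries completely at random
#'
#' Missing-completely-at-random masking for simulated matrices, preserving the
#' marginal category frequencies among the observed entries.
#'
#' @param scores matrix to mask.
#' @param prop proportion of entries to set missing.
#' @param seed optional integer seed.
#' @export
inject_missing <- function(scores, prop, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(prop >= 0, prop < 1)
  idx <- which(stats::runif(length(scores)) < prop)
  scores[idx] <- NA
  scores
}
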