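#' First eigenvalue of the inter-item response-time correlation matrix
#'
#' A positive manifold across response times (persons who are fast on one item
#' tend to be fast on all) concentrates variance on the first eigenvalue of
#' the item-by-item RT correlation matrix. Unidimensional SRT-type models
#' cannot produce a strong manifold, so a large observed first eigenvalue
#' relative to its model-implied distribution signals unmodelled person speed
#' differences. Correlations are pairwise-complete to accommodate incomplete
#' designs.
#'
#' @param x persons x items matrix of response times or fast/slow indicators
#'   (missing allowed).
#' @param min_overlap minimum number of jointly observed persons per item
#'   pair below which a warning is issued (default 30).
#' @return Largest eigenvalue (numeric). Attribute `"psd"` is `FALSE` when the
#'   pairwise-complete matrix has negative eigenvalues beyond tolerance, in
#'   which case trace conservation (eigenvalues summing to K) still holds but
#'   the matrix is not a proper correlation matrix.
#' @export
rt_eigen_stat <- function(x, min_overlap = 30L) {
  x <- as.matrix(x)
  K <- ncol(x)
  if (K < 2L) abort("Need at least two items.")
  obs <- !is.na(x)
  overlap <- crossprod(obs)
  diag(overlap) <- NA
  if (any(overlap == 0L, na.rm = TRUE)) {
    idx <- which(overlap == 0L, arr.ind = TRUE)[1L, ]
    nm <- colnames(x) %||% paste0("item", seq_len(K))
    abort(sprintf("Item pair with no overlapping observations: %s and %s.",
                  nm[idx[1L]], nm[idx[2L]]))
  }
  if (any(overlap < min_overlap, na.rm = TRUE)) {
    warn(sprintf("Some item pairs have fewer than %d overlapping observations.",
                 min_overlap))
  }
  cm <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  if (any(is.na(cm))) abort("Correlation undefined for some item pair (constant column?).")
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  out <- ev[1L]
  attr(out, "psd") <- ev[K] > -1e-8
  out
}

#' Parametric-bootstrap predictive check of the RT positive manifold
#'
#' Simulates `n_rep` datasets from a fitted model at its parameter estimates
#' (same numbers of persons and items, same missingness pattern, latents drawn
#' from the fitted population distribution), computes [rt_eigen_stat()] on the
#' fast/slow indicator matrix of each, and compares the observed statistic to
#' the 2.5th-97.5th percentile interval of the replicates. An observed value
#' above the interval means the data carry stronger inter-item RT associations
#' than the model can produce.
#'
#' @param fit a [fit_dsrt()] result for a model that can simulate scores
#'   (any of the family's variants).
#' @param data the observed score matrix the fit was based on (used for the
#'   observed statistic and the missingness template).
#' @param n_rep number of bootstrap replicates (default 500).
#' @param seed optional integer seed.
#' @param statistic `"indicator"` (default) computes the eigenvalue on the
#'   fast/slow indicator; `"scores"` uses the raw polytomous scores.
#' @param min_overlap passed to [rt_eigen_stat()].
#' @return A `dsrt_ppc` object: `observed`, `replicates`, `interval`, `flag`.
#' @export
ppc_eigen <- function(fit, data, n_rep = 500L, seed = NULL,
                      statistic = c("indicator", "scores"), min_overlap = 30L) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  sm <- as_score_matrix(data, fit$n_categories)
  template <- is.na(sm$scores)
  stat_of <- function(s) {
    m <- if (statistic == "indicator") {
      matrix(decode_scores(s, fit$n_categories / 2L)$fast, nrow(s), ncol(s))
    } else s
    suppressWarnings(rt_eigen_stat(m, min_overlap))
  }
  observed <- stat_of(sm$scores)
  N <- nrow(sm$scores)
  reps <- vapply(seq_len(n_rep), function(r) {
    theta <- draw_latents(N, rho = if (is.na(fit$rho)) 0 else fit$rho)
    s <- simulate_scores(fit$items, theta, model = fit$model,
                         n_categories = fit$n_categories,
                         c1 = fit$c1, c2 = fit$c2)
    s[template] <- NA
    stat_of(s)
  }, numeric(1L))
  interval <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  structure(list(observed = as.numeric(observed), replicates = reps,
                 interval = interval,
                 flag = observed < interval[1L] | observed > interval[2L],
                 statistic = statistic, n_rep = n_rep, model = fit$model),
            class = "dsrt_ppc")
}

#' @export
print.dsrt_ppc <- function(x, ...) {
  cat(sprintf("<dsrt_ppc> first-eigenvalue predictive check (%s, %d replicates)\n",
              x$statistic, x$n_rep))
  cat(sprintf("  observed %.3f | 95%% predictive interval [%.3f, %.3f] -> %s\n",
              x$observed, x$interval[1L], x$interval[2L],
              if (x$flag) "OUTSIDE (misfit flagged)" else "inside"))
  invisible(x)
}
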