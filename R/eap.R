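#' EAP person estimates and posterior standard deviations
#'
#' Expected a posteriori (posterior mean) estimates of the latent variable(s)
#' for each person, given the item parameter estimates of a fitted model. The
#' posterior is evaluated on the fit's quadrature grid under the fitted
#' population distribution (including the estimated latent correlation for
#' two-dimensional models). Persons with no observed responses get the prior
#' mean and standard deviation and are flagged, not silently scored.
#'
#' @param data persons x items score matrix/data frame (same category coding
#'   as the fit). Defaults to scoring new data; pass the fitting data to score
#'   the calibration sample.
#' @param fit a [fit_dsrt()] result.
#' @param quad optional alternative [quad_spec()] for scoring.
#' @return A tibble with one row per person: `person`, `eap_theta1`,
#'   `psd_theta1` (and `eap_theta2`, `psd_theta2` for two-dimensional models),
#'   `loglik`, `n_items`, `flagged`.
#' @export
eap_scores <- function(data, fit, quad = NULL) {
  sm <- as_score_matrix(data, fit$n_categories)
  fam <- make_family(fit$model, fit$n_categories, c1 = fit$c1, c2 = fit$c2)
  quad <- quad %||% fit$quad
  if (quad$ndim != fam$ndim) abort("Quadrature dimension does not match the model.")
  logP <- build_logP(fam, fit$par, quad$theta)
  logw <- quad_logw(quad, if (fam$uses_rho) fit$rho else 0)
  mom <- eap_moments_cpp(scores_for_cpp(sm$scores), logP, logw, quad$theta)
  n_items <- rowSums(!is.na(sm$scores))
  out <- tibble::tibble(person = sm$person_id,
                        eap_theta1 = mom$eap[, 1L],
                        psd_theta1 = sqrt(mom$pvar[, 1L]))
  if (fam$ndim == 2L) {
    out$eap_theta2 <- mom$eap[, 2L]
    out$psd_theta2 <- sqrt(mom$pvar[, 2L])
  }
  out$loglik <- as.numeric(mom$loglik)
  out$n_items <- as.integer(n_items)
  out$flagged <- n_items == 0L
  out
}

#' Model-based EAP reliability
#'
#' The variance of the EAP estimates divided by that variance plus the mean
#' posterior variance: `var(eap) / (var(eap) + mean(psd^2))`. Lies in `[0, 1]`;
#' a degenerate set of identical estimates gives 0.
#'
#' @param estimates a tibble from [eap_scores()] (or any data frame with the
#'   chosen `eap` and `psd` columns).
#' @param dimension which latent dimension, `"theta1"` (default) or `"theta2"`.
#' @return Scalar reliability in `[0, 1]`.
#' @export
eap_reliability <- function(estimates, dimension = "theta1") {
  eap <- estimates[[paste0("eap_", dimension)]]
  psd <- estimates[[paste0("psd_", dimension)]]
  if (length(eap) < 2L) abort("EAP reliability needs at least two persons.")
  v <- stats::var(eap)
  if (v == 0) return(0)
  v / (v + mean(psd^2))
}

#' Bias, variance, and MSE of estimates over replications
#'
#' Given a replications x persons matrix of estimates for a fixed set of true
#' person parameters, computes the Monte Carlo summaries used to judge
#' recovery: per person, bias is the mean estimation error across
#' replications; reported are the average absolute per-person bias, the
#' average across persons of the across-replication variance, and the mean
#' squared error across persons and replications. Per person the decomposition
#' `mse = bias^2 + variance` holds (variance taken with denominator R).
#' Monte Carlo standard errors for the three aggregates are obtained by
#' jackknifing replications.
#'
#' @details With a finite number of replications the raw average absolute bias
#'   is inflated: the per-person bias is estimated with Monte Carlo noise of
#'   variance `var_p / R`, and taking absolute values folds that noise upward.
#'   `bias_corrected` removes the expected inflation before averaging,
#'   `sqrt(max(bias_p^2 - var_p / R, 0))` per person, and is the quantity to
#'   compare against references computed from many more replications.
#'   Monte Carlo standard errors are standard errors of the person-level
#'   summaries across persons, so they cover both the finite replication count
#'   and the finite person sample.
#'
#' @param estimates replications x persons numeric matrix.
#' @param truth numeric vector of true values, one per person.
#' @return A list: `bias`, `bias_corrected`, `variance`, `mse`, matching
#'   `mc_se_*` values, and a `per_person` tibble (`truth`, `mean_estimate`,
#'   `bias`, `bias_corrected`, `variance`, `mse`).
#' @export
bias_var_mse <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  R <- nrow(estimates)
  if (ncol(estimates) != length(truth)) {
    abort("`estimates` columns must match `truth` length.")
  }
  err <- sweep(estimates, 2L, truth)
  bias_p <- colMeans(err)
  var_p <- colMeans(err^2) - bias_p^2      # denominator R: makes mse = bias^2 + var exact
  mse_p <- colMeans(err^2)
  # unbiased (denominator R - 1) sampling variance of the per-person bias
  samp_var <- if (R > 1L) var_p * R / (R - 1L) / R else rep(0, length(bias_p))
  bias_c_p <- sqrt(pmax(bias_p^2 - samp_var, 0))
  se <- function(x) stats::sd(x) / sqrt(length(x))
  list(bias = mean(abs(bias_p)), bias_corrected = mean(bias_c_p),
       variance = mean(var_p), mse = mean(mse_p),
       mc_se_bias = se(abs(bias_p)), mc_se_bias_corrected = se(bias_c_p),
       mc_se_variance = se(var_p), mc_se_mse = se(mse_p),
       per_person = tibble::tibble(truth = truth, mean_estimate = bias_p + truth,
                                   bias = bias_p, bias_corrected = bias_c_p,
                                   variance = var_p, mse = mse_p))
}
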