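#' Fit a discretized SRT family model by marginal maximum likelihood
#'
#' Fits one of the model variants to a persons x items matrix of polytomous
#' SRT scores by marginal maximum likelihood: the latent variables are
#' integrated out over a Gauss-Hermite grid and the likelihood is maximized
#' with an EM algorithm (expected category counts on the grid in the E-step;
#' damped Newton updates per item and, for two-dimensional models, an exact
#' update of the latent correlation in the M-step). The latent means are fixed
#' at 0 and variances at 1 for identification; slopes are kept positive through
#' a log parameterization.
#'
#' Available models: `"coomans"` (one difficulty parameter per item), `"pcm"`
#' (partial credit: free category intercepts, common unit slope), `"srt1d"`
#' (adds an item slope), `"nrm"` (free category slopes, one dimension),
#' `"srt2d"` (ability plus speed dimension with scoring vectors `c1`, `c2` and
#' free latent correlation), `"hm"` (hierarchical model: accuracy 2PL on
#' ability, fast-indicator 2PL on speed), and `"irtree"` (fast/slow branch on
#' speed, branch-specific accuracy 2PLs on ability).
#'
#' @param data persons x items score matrix or data frame (categories
#'   `0..C-1`, `NA` = not administered; an optional `person`/`person_id`/`id`
#'   column is used for labels).
#' @param model model tag, see Details.
#' @param n_categories number of score categories `C` (default: inferred).
#' @param quad a [quad_spec()]; default 21 nodes per dimension.
#' @param c1,c2 scoring vectors for `"srt2d"` (defaults `0:3` and the fast
#'   indicator `c(1,0,0,1)`; for six categories the symmetric speed loading
#'   `c(2,1,0,0,1,2)` is used).
#' @param start optional warm start: a previous `dsrt_fit` or a list with
#'   elements `par` (working-scale item matrix) and `rho`.
#' @param control list: `tol` (relative log-likelihood change, default `1e-6`),
#'   `max_iter` (default 500), `mstep_iter` (Newton steps per item per EM
#'   cycle, default 2).
#' @return A `dsrt_fit` object: item estimates (tibble `items`), `rho`,
#'   `loglik`, `aic`, `bic`, `n_params`, `converged`, `n_iter`, and the
#'   quadrature used.
#' @seealso [eap_scores()], [marginal_loglik()], [simulate_scores()]
#' @export
fit_dsrt <- function(data, model = c("srt1d", "srt2d", "coomans", "pcm", "nrm",
                                     "hm", "irtree"),
                     n_categories = NULL, quad = NULL, c1 = NULL, c2 = NULL,
                     start = NULL, control = list()) {
  model <- match.arg(model)
  ctl <- utils::modifyList(list(tol = 1e-6, max_iter = 500L, mstep_iter = 2L),
                           control)
  sm <- as_score_matrix(data, n_categories)
  validate_observed(sm, require_items = TRUE, require_persons = TRUE)
  C <- sm$n_categories
  if (model %in% c("hm", "irtree") && C != 4L) {
    abort("`hm` and `irtree` operate on the 4-category accuracy-by-speed score.")
  }
  fam <- make_family(model, C, c1 = c1 %||% (seq_len(C) - 1), c2 = c2)
  check_category_coverage(sm, fam)
  if (is.null(quad)) quad <- quad_spec(21L, fam$ndim)
  if (quad$ndim != fam$ndim) abort("Quadrature dimension does not match the model.")

  K <- ncol(sm$scores)
  N <- nrow(sm$scores)
  sc <- scores_for_cpp(sm$scores)

  if (!is.null(start)) {
    if (inherits(start, "dsrt_fit")) start <- list(par = start$par, rho = start$rho)
    par <- start$par
    rho <- start$rho %||% 0
    stopifnot(is.matrix(par), nrow(par) == K, ncol(par) == fam$npar)
  } else {
    par <- vapply(seq_len(K), function(k) {
      freq <- tabulate(sm$scores[, k] + 1L, C) + 0.5
      fam$init(freq / sum(freq))
    }, numeric(fam$npar))
    par <- if (fam$npar == 1L) cbind(par) else t(par)
    rho <- 0
  }

  Theta <- quad$theta

  # one EM sweep; returns the updated parameters and the log-likelihood
  # evaluated at the *input* parameters (a free by-product of the E-step)
  em_step <- function(state) {
    logP <- build_logP(fam, state$par, Theta)
    es <- estep_counts_cpp(sc, logP, quad_logw(quad, state$rho))
    par_new <- state$par
    for (k in seq_len(K)) {
      par_new[k, ] <- fam$mstep(state$par[k, ], es$counts[, , k], Theta,
                                ctl$mstep_iter)
    }
    rho_new <- if (fam$uses_rho) update_rho(quad, es$nbar, state$rho) else 0
    list(state = list(par = par_new, rho = rho_new), ll = es$loglik)
  }
  clamp_state <- function(state) {
    state$par <- matrix(pmin(pmax(state$par,
                                  ifelse(rep(fam$curv, each = K), WORK_LO, -30)),
                             ifelse(rep(fam$curv, each = K), WORK_HI, 30)),
                        K, fam$npar)
    if (fam$uses_rho) state$rho <- min(max(state$rho, -0.98), 0.98)
    state
  }

  state <- list(par = par, rho = if (fam$uses_rho) rho else 0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  # SQUAREM-accelerated EM: extrapolate through two EM sweeps, fall back to
  # plain EM whenever the extrapolated likelihood regresses
  while (iter < ctl$max_iter) {
    e1 <- em_step(state); iter <- iter + 1L
    ll <- e1$ll
    if (is.finite(ll_old) && abs(ll - ll_old) / (abs(ll) + 0.1) < ctl$tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    e2 <- em_step(e1$state); iter <- iter + 1L
    th0 <- c(state$par, state$rho)
    th1 <- c(e1$state$par, e1$state$rho)
    th2 <- c(e2$state$par, e2$state$rho)
    r <- th1 - th0
    v <- (th2 - th1) - r
    vv <- sum(v * v)
    if (!is.finite(vv) || vv < 1e-14) { state <- e2$state; next }
    alpha <- max(-16, min(-1, -sqrt(sum(r * r) / vv)))
    th_s <- th0 - 2 * alpha * r + alpha^2 * v
    cand <- clamp_state(list(par = matrix(th_s[seq_len(K * fam$npar)], K, fam$npar),
                             rho = th_s[length(th_s)]))
    e3 <- em_step(cand); iter <- iter + 1L
    state <- if (is.finite(e3$ll) && e3$ll >= e2$ll - 1e-8) e3$state else e2$state
  }
  par <- state$par
  rho <- state$rho
  loglik <- marginal_loglik_cpp(sc, build_logP(fam, par, Theta),
                                quad_logw(quad, rho))
  n_params <- fam$n_params(K)
  items <- dplyr::bind_cols(tibble::tibble(item = sm$item_id), fam$to_natural(par))
  structure(list(
    model = model, items = items, rho = if (fam$uses_rho) rho else NA_real_,
    loglik = loglik, n_params = n_params,
    aic = -2 * loglik + 2 * n_params,
    bic = -2 * loglik + log(N) * n_params,
    converged = converged, n_iter = iter,
    n_persons = N, n_items = K, n_categories = C,
    c1 = fam$c1, c2 = fam$c2,
    quad = quad, par = par, person_id = sm$person_id
  ), class = "dsrt_fit")
}

build_logP <- function(fam, par, Theta) {
  K <- nrow(par)
  logP <- array(0, c(fam$C, nrow(Theta), K))
  for (k in seq_len(K)) logP[, , k] <- fam$logprob(par[k, ], Theta)
  logP
}

update_rho <- function(quad, nbar, rho_now) {
  f <- function(r) sum(nbar * quad_logw(quad, r))
  opt <- stats::optimize(f, c(-0.98, 0.98), maximum = TRUE, tol = 1e-5)
  if (opt$objective >= f(rho_now)) opt$maximum else rho_now
}

validate_observed <- function(sm, require_items = TRUE, require_persons = TRUE) {
  obs <- !is.na(sm$scores)
  if (require_persons && any(rowSums(obs) == 0L)) {
    abort(sprintf("Person(s) with no observed responses: %s",
                  paste(sm$person_id[rowSums(obs) == 0L], collapse = ", ")))
  }
  if (require_items && any(colSums(obs) == 0L)) {
    abort(sprintf("Item(s) with no observed responses: %s",
                  paste(sm$item_id[colSums(obs) == 0L], collapse = ", ")))
  }
  invisible(TRUE)
}

check_category_coverage <- function(sm, fam) {
  C <- fam$C
  tab <- apply(sm$scores, 2L, function(s) tabulate(s + 1L, C))
  if (fam$model == "hm") {
    x <- colSums(tab[3:4, , drop = FALSE]); f <- colSums(tab[c(1L, 4L), , drop = FALSE])
    n <- colSums(tab)
    bad <- which(x == 0 | x == n | f == 0 | f == n)
    if (length(bad)) {
      abort(sprintf("Item(s) without both accuracy and both speed outcomes observed: %s",
                    paste(sm$item_id[bad], collapse = ", ")))
    }
  } else if (fam$model == "irtree") {
    bad <- which(apply(tab, 2L, function(x) any(x == 0)))
    if (length(bad)) {
      abort(sprintf("IRTree branch with no observations for item(s): %s",
                    paste(sm$item_id[bad], collapse = ", ")))
    }
  } else {
    bad <- which(apply(tab, 2L, function(x) any(x == 0)))
    if (length(bad)) {
      abort(sprintf("Empty score categories for item(s): %s. Merge categories or drop the item.",
                    paste(sm$item_id[bad], collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Marginal log-likelihood of item parameters on a score matrix
#'
#' Evaluates the quadrature-approximated marginal log-likelihood of a set of
#' (natural-scale) item parameters. Missing entries are skipped in the
#' within-person product, so an unanswered item leaves the value unchanged.
#'
#' @inheritParams fit_dsrt
#' @param items tibble of natural-scale item parameters in the layout produced
#'   by [fit_dsrt()] for the given model.
#' @param rho latent correlation (two-dimensional models).
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(data, items, model, rho = 0, quad = NULL,
                            n_categories = NULL, c1 = NULL, c2 = NULL) {
  if (is.null(n_categories)) {
    # infer the category count from the item table, not just the observed codes
    nb <- sum(grepl("^beta[0-9]+$", names(items)))
    n_categories <- if (nb > 0L) nb + 1L else 4L
  }
  sm <- as_score_matrix(data, n_categories)
  validate_observed(sm)
  C <- sm$n_categories
  fam <- make_family(model, C, c1 = c1 %||% (seq_len(C) - 1), c2 = c2)
  if (is.null(quad)) quad <- quad_spec(21L, fam$ndim)
  par <- fam$from_natural(items)
  if (nrow(par) != ncol(sm$scores)) abort("`items` rows must match the item columns.")
  logP <- build_logP(fam, par, quad$theta)
  marginal_loglik_cpp(scores_for_cpp(sm$scores), logP,
                      quad_logw(quad, if (fam$uses_rho) rho else 0))
}

#' @export
print.dsrt_fit <- function(x, ...) {
  cat(sprintf("<dsrt_fit> %s model: %d persons x %d items, %d categories\n",
              x$model, x$n_persons, x$n_items, x$n_categories))
  cat(sprintf("  logLik %.2f | AIC %.2f | BIC %.2f | %d parameters\n",
              x$loglik, x$aic, x$bic, x$n_params))
  if (!is.na(x$rho)) cat(sprintf("  latent correlation rho = %.3f\n", x$rho))
  cat(sprintf("  EM %s in %d iterations\n",
              if (x$converged) "converged" else "did NOT converge", x$n_iter))
  invisible(x)
}

#' @export
logLik.dsrt_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params,
            nobs = object$n_persons, class = "logLik")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy item-parameter estimates
#'
#' @param x a `dsrt_fit`.
#' @param ... unused.
#' @return A long tibble with one row per item parameter.
#' @export
tidy.dsrt_fit <- function(x, ...) {
  tidyr::pivot_longer(x$items, -"item", names_to = "term", values_to = "estimate")
}

#' One-row model summary
#'
#' @param x a `dsrt_fit`.
#' @param ... unused.
#' @export
glance.dsrt_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_persons = x$n_persons, n_items = x$n_items,
                 n_params = x$n_params, loglik = x$loglik, aic = x$aic,
                 bic = x$bic, rho = x$rho, converged = x$converged,
                 n_iter = x$n_iter)
}

#' Fit the hierarchical accuracy/speed model
#'
#' Convenience wrapper: combines a binary accuracy matrix and a fast-response
#' indicator matrix into the joint 4-category score and fits the hierarchical
#' model (`model = "hm"`), i.e. a 2PL for accuracy on the ability dimension and
#' a 2PL for the fast indicator on the speed dimension, with bivariate-normal
#' latents and free correlation.
#'
#' @param accuracy persons x items binary matrix.
#' @param fast_indicator persons x items binary matrix (1 = fast), same
#'   missingness as `accuracy`.
#' @param ... passed to [fit_dsrt()].
#' @export
fit_hm <- function(accuracy, fast_indicator, ...) {
  fit_dsrt(combine_binary(accuracy, fast_indicator), model = "hm", ...)
}

#' Fit the IRTree model for fast and slow responses
#'
#' The first branch models the fast/slow indicator with a 2PL on the speed
#' dimension; accuracy is then modelled with separate 2PL parameters for fast
#' and for slow responses on the ability dimension.
#'
#' @inheritParams fit_hm
#' @export
fit_irtree <- function(accuracy, fast_indicator, ...) {
  fit_dsrt(combine_binary(accuracy, fast_indicator), model = "irtree", ...)
}

combine_binary <- function(accuracy, fast_indicator) {
  accuracy <- as.matrix(accuracy); fast_indicator <- as.matrix(fast_indicator)
  if (!identical(dim(accuracy), dim(fast_indicator))) {
    abort("accuracy and fast_indicator must have the same shape.")
  }
  if (!identical(is.na(accuracy), is.na(fast_indicator))) {
    abort("Missingness of accuracy and fast_indicator must coincide.")
  }
  s <- assign_scores(as.integer(accuracy), as.integer(fast_indicator), n_bins = 2L)
  matrix(s, nrow(accuracy), ncol(accuracy), dimnames = dimnames(accuracy))
}
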