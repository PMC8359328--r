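#' Default Monte Carlo study conditions
#'
#' The crossed design used to assess recovery of ability when person speed
#' differences are present or absent: a null design (`speed_slope = 0`, no
#' latent correlation involved) and a speed design (`speed_slope = 1`) with
#' latent correlation in `{0, .2, .5}`, each at 20 and 40 items.
#'
#' @return Tibble with columns `speed_slope`, `n_items`, `rho`.
#' @export
study_conditions <- function() {
  dplyr::bind_rows(
    tidyr::expand_grid(speed_slope = 0, n_items = c(20L, 40L), rho = NA_real_),
    tidyr::expand_grid(speed_slope = 1, n_items = c(20L, 40L), rho = c(0, .2, .5))
  )
}

#' Run one Monte Carlo condition
#'
#' Generates `n_reps` datasets under the two-dimensional discretized SRT model
#' (the null design uses `speed_slope = 0`, which is exactly the
#' unidimensional model), fits the requested models to every replication,
#' computes EAP ability estimates, and aggregates bias/variance/MSE of the
#' ability estimates and EAP reliability per model.
#'
#' Person latents are drawn once per condition and held fixed across
#' replications (`person_mode = "fixed"`), so that per-person bias across
#' replications is well defined; `"redraw"` draws new persons each
#' replication. Within a worker chunk, each fit is warm-started from the
#' previous replication's estimates, which shortens the optimization path
#' without changing the maximum.
#'
#' @param n_items test length (multiple of 5).
#' @param speed_slope common speed slope of the generating model (0 or 1).
#' @param rho generating latent correlation (ignored, treated as 0, in the
#'   null design).
#' @param n_reps number of replications (default 100).
#' @param n_persons sample size per replication (default 1000).
#' @param models which models to fit: subset of
#'   `c("srt1d", "srt2d", "hm", "irtree")`.
#' @param seed master seed; per-replication child seeds are derived with
#'   [child_seed()].
#' @param person_mode `"fixed"` (default) or `"redraw"`.
#' @param nodes_1d,nodes_2d quadrature nodes per dimension for one- and
#'   two-dimensional fits.
#' @param score_nodes_1d,score_nodes_2d finer quadrature used only for the EAP
#'   scoring pass (a single sweep, so the cost is negligible).
#' @param workers number of parallel workers (forked; replications are split
#'   into contiguous chunks so results are identical for any worker count).
#' @param warm_start logical; warm-start fits across replications.
#' @return A `dsrt_condition` list: `summary` (one row per model with the
#'   aggregate metrics and Monte Carlo standard errors), `per_person`
#'   (per-person average estimate vs truth, for shrinkage plots), `n_fail`,
#'   and the condition metadata.
#' @export
run_condition <- function(n_items, speed_slope, rho = 0, n_reps = 100L,
                          n_persons = 1000L,
                          models = c("srt1d", "srt2d", "hm", "irtree"),
                          seed = 1L, person_mode = c("fixed", "redraw"),
                          nodes_1d = 21L, nodes_2d = 15L,
                          score_nodes_1d = 41L, score_nodes_2d = 31L,
                          workers = 1L, warm_start = TRUE) {
  person_mode <- match.arg(person_mode)
  models <- match.arg(models, c("srt1d", "srt2d", "hm", "irtree"),
                      several.ok = TRUE)
  rho_gen <- if (speed_slope == 0 || is.na(rho)) 0 else rho
  items <- study_item_bank(n_items, speed_slope)
  # fixed-person designs pin the truth sample to the identification
  # constraints (see ?draw_latents); redrawn persons are left as sampled
  theta0 <- draw_latents(n_persons, rho_gen, seed = child_seed(seed, 0L, 0L),
                         standardize = person_mode == "fixed")
  fit_quad <- list(quad_spec(nodes_1d, 1L), quad_spec(nodes_2d, 2L))
  # EAP scoring reuses the fitted parameters on a finer grid: one cheap pass
  # that removes most of the quadrature footprint from the person estimates
  score_quad <- list(quad_spec(score_nodes_1d, 1L), quad_spec(score_nodes_2d, 2L))

  run_chunk <- function(rep_ids) {
    starts <- stats::setNames(vector("list", length(models)), models)
    est <- lapply(models, function(m) matrix(NA_real_, length(rep_ids), n_persons))
    names(est) <- models
    rel <- matrix(NA_real_, length(rep_ids), length(models),
                  dimnames = list(NULL, models))
    fails <- stats::setNames(integer(length(models)), models)
    for (i in seq_along(rep_ids)) {
      r <- rep_ids[i]
      theta <- if (person_mode == "fixed") theta0 else
        draw_latents(n_persons, rho_gen, seed = child_seed(seed, 2L, r))
      scores <- simulate_scores(items, theta, model = "srt2d",
                                seed = child_seed(seed, 1L, r))
      for (m in models) {
        d <- if (m == "srt1d") 1L else 2L
        fit <- tryCatch(
          fit_dsrt(scores, model = m, quad = fit_quad[[d]],
                   start = if (warm_start) starts[[m]] else NULL),
          error = function(e) NULL)
        if (is.null(fit)) { fails[m] <- fails[m] + 1L; next }
        if (warm_start) starts[[m]] <- fit
        sc <- eap_scores(scores, fit, quad = score_quad[[d]])
        est[[m]][i, ] <- sc$eap_theta1
        rel[i, m] <- eap_reliability(sc, "theta1")
      }
    }
    list(est = est, rel = rel, fails = fails, theta = theta0)
  }

  chunks <- split(seq_len(n_reps),
                  ceiling(seq_len(n_reps) / (n_reps / max(1L, workers))))
  res <- if (workers > 1L) {
    parallel::mclapply(chunks, run_chunk, mc.cores = workers)
  } else {
    lapply(chunks, run_chunk)
  }

  est <- lapply(models, function(m) do.call(rbind, lapply(res, function(x) x$est[[m]])))
  names(est) <- models
  rel <- do.call(rbind, lapply(res, function(x) x$rel))
  n_fail <- Reduce(`+`, lapply(res, function(x) x$fails))

  truth <- theta0[, 1L]
  summ <- purrr::map_dfr(models, function(m) {
    keep <- stats::complete.cases(est[[m]])
    bvm <- bias_var_mse(est[[m]][keep, , drop = FALSE], truth)
    rl <- rel[keep, m]
    rel_bar <- mean(rl)
    # reliability SE: replication noise plus the person-sampling component of
    # var(EAP), delta method: rel * (1 - rel) * sqrt(2 / (N - 1))
    rel_se <- sqrt(stats::var(rl) / length(rl) +
                     (rel_bar * (1 - rel_bar))^2 * 2 / (n_persons - 1))
    tibble::tibble(
      speed_slope = speed_slope, n_items = n_items,
      rho = if (speed_slope == 0) NA_real_ else rho, model = m,
      n_reps = sum(keep), n_fail = n_fail[[m]],
      bias = bvm$bias, bias_corrected = bvm$bias_corrected,
      variance = bvm$variance, mse = bvm$mse,
      mc_se_bias = bvm$mc_se_bias,
      mc_se_bias_corrected = bvm$mc_se_bias_corrected,
      mc_se_variance = bvm$mc_se_variance, mc_se_mse = bvm$mc_se_mse,
      reliability = rel_bar, mc_se_reliability = rel_se
    )
  })
  per_person <- purrr::map_dfr(models, function(m) {
    keep <- stats::complete.cases(est[[m]])
    tibble::tibble(model = m, person = seq_len(n_persons), truth = truth,
                   mean_estimate = colMeans(est[[m]][keep, , drop = FALSE]))
  })
  structure(list(summary = summ, per_person = per_person, n_fail = n_fail,
                 estimates = est, reliability = rel,
                 condition = list(speed_slope = speed_slope, n_items = n_items,
                                  rho = rho, n_reps = n_reps,
                                  n_persons = n_persons, seed = seed,
                                  person_mode = person_mode)),
            class = "dsrt_condition")
}

#' @export
print.dsrt_condition <- function(x, ...) {
  cn <- x$condition
  cat(sprintf("<dsrt_condition> speed_slope=%g, K=%d, rho=%s, %d reps x %d persons\n",
              cn$speed_slope, cn$n_items,
              if (is.na(cn$rho)) "-" else format(cn$rho), cn$n_reps, cn$n_persons))
  print(as.data.frame(dplyr::select(
    x$summary, "model", "bias", "variance", "mse", "reliability")), digits = 3)
  invisible(x)
}

#' Run a full Monte Carlo study
#'
#' Runs [run_condition()] for every row of a condition tibble and binds the
#' summaries.
#'
#' @param conditions tibble as from [study_conditions()].
#' @param ... passed to [run_condition()].
#' @param seed master seed; condition `i` uses stream `i` child seeds.
#' @return A `dsrt_study` list with `summary` (all conditions x models) and
#'   `per_person` tables.
#' @export
run_study <- function(conditions = study_conditions(), seed = 1L, ...) {
  out <- purrr::imap(split(conditions, seq_len(nrow(conditions))), function(cond, i) {
    run_condition(n_items = cond$n_items, speed_slope = cond$speed_slope,
                  rho = cond$rho, seed = child_seed(seed, 100L + as.integer(i), 0L),
                  ...)
  })
  structure(list(
    summary = purrr::map_dfr(out, "summary"),
    per_person = purrr::map_dfr(out, function(x) {
      dplyr::mutate(x$per_person,
                    speed_slope = x$condition$speed_slope,
                    n_items = x$condition$n_items, rho = x$condition$rho,
                    .before = 1L)
    }),
    conditions = conditions
  ), class = "dsrt_study")
}

#' Lay out study results as recovery and reliability tables
#'
#' Reshapes a study summary into the two standard report tables: recovery
#' (average absolute bias, variance, MSE of the ability estimates per
#' condition and model) and reliability (average EAP reliability per condition
#' and model), each with Monte Carlo standard errors retained in long form.
#'
#' @param results a `dsrt_study`, `dsrt_condition`, or their `summary` tibble.
#' @param dir optional directory; when given, writes `recovery.csv`,
#'   `reliability.csv` and the long-form `summary.csv` there.
#' @return List of tibbles `recovery`, `reliability`, `long`.
#' @export
emit_tables <- function(results, dir = NULL) {
  summ <- if (is.data.frame(results)) results else results$summary
  if (nrow(summ) == 0L) {
    out <- list(recovery = tibble::tibble(), reliability = tibble::tibble(),
                long = summ)
  } else {
    recovery <- tidyr::pivot_wider(
      dplyr::select(summ, "speed_slope", "n_items", "rho", "model",
                    "bias", "variance", "mse"),
      names_from = "model", values_from = c("bias", "variance", "mse"),
      names_vary = "slowest")
    reliability <- tidyr::pivot_wider(
      dplyr::select(summ, "speed_slope", "n_items", "rho", "model", "reliability"),
      names_from = "model", values_from = "reliability")
    out <- list(recovery = recovery, reliability = reliability, long = summ)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(out$recovery, file.path(dir, "recovery.csv"))
    readr::write_csv(out$reliability, file.path(dir, "reliability.csv"))
    readr::write_csv(out$long, file.path(dir, "summary.csv"))
  }
  out
}

#' Percent MSE reduction between two fitted models in a condition
#'
#' The headline comparison of the study: how much the two-dimensional model
#' reduces the MSE of the ability estimates relative to the unidimensional
#' one, `100 * (MSE_from - MSE_to) / MSE_from`. The Monte Carlo standard
#' error treats persons as the sampling unit and uses the paired per-person
#' MSEs (delta method for the ratio), so it covers replication noise and the
#' person draw.
#'
#' @param condition a `dsrt_condition` with both models fitted.
#' @param from,to model tags (defaults `"srt1d"` vs `"srt2d"`).
#' @return Tibble with `reduction` (percent) and `mc_se`.
#' @export
mse_reduction <- function(condition, from = "srt1d", to = "srt2d") {
  stopifnot(inherits(condition, "dsrt_condition"))
  truth <- condition$per_person$truth[condition$per_person$model == from]
  msep <- function(m) {
    est <- condition$estimates[[m]]
    if (is.null(est)) abort(sprintf("Model `%s` was not fitted in this condition.", m))
    colMeans(sweep(est[stats::complete.cases(est), , drop = FALSE], 2L, truth)^2)
  }
  m1 <- msep(from); m2 <- msep(to)
  N <- length(m1)
  M1 <- mean(m1); M2 <- mean(m2)
  S <- stats::cov(cbind(m1, m2)) / N
  grad <- c(M2 / M1^2, -1 / M1)           # d(1 - M2/M1)/d(M1, M2)
  se <- sqrt(drop(t(grad) %*% S %*% grad))
  tibble::tibble(from = from, to = to,
                 reduction = 100 * (M1 - M2) / M1, mc_se = 100 * se)
}
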