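make_small_scores <- function(n = 120, K = 3, seed = 2) {
  items <- study_item_bank(5, 0)[1:K, ]
  theta <- draw_latents(n, 0, seed = seed)
  simulate_scores(items, theta, "srt2d", seed = seed + 1)
}

test_that("quadrature marginal likelihood matches dense-grid integration", {
  s <- make_small_scores()
  items1 <- tibble::tibble(item = colnames(s), alpha = c(.5, .8, 1.2),
                           beta1 = c(0, 1, -1), beta2 = c(.5, -.5, 0),
                           beta3 = c(0, .3, -.3))
  ll_quad <- marginal_loglik(s, items1, "srt1d", quad = quad_spec(41, 1))
  ll_dense <- oracle_loglik_1d(s, items1$alpha,
                               as.matrix(items1[, c("beta1", "beta2", "beta3")]))
  expect_equal(ll_quad, ll_dense, tolerance = 1e-6)

  items2 <- tibble::tibble(item = colnames(s), alpha1 = c(.5, .8, 1.2),
                           alpha2 = c(1, .6, 1.4),
                           beta1 = c(0, 1, -1), beta2 = c(.5, -.5, 0),
                           beta3 = c(0, .3, -.3))
  for (rho in c(0, 0.4)) {
    ll2 <- marginal_loglik(s, items2, "srt2d", rho = rho, quad = quad_spec(41, 2))
    ll2_dense <- oracle_loglik_2d(s, items2$alpha1, items2$alpha2,
                                  as.matrix(items2[, c("beta1", "beta2", "beta3")]),
                                  rho)
    expect_equal(ll2, ll2_dense, tolerance = 1e-6)
  }
})

test_that("single-person, single-item likelihood agrees with brute force to 1e-8", {
  s <- matrix(2L, 1, 1, dimnames = list(NULL, "item1"))
  items <- tibble::tibble(item = "item1", alpha = 0.9,
                          beta1 = 0.4, beta2 = -0.2, beta3 = 0.1)
  ll <- marginal_loglik(s, items, "srt1d", quad = quad_spec(41, 1))
  f <- function(t) oracle_probs_1d(t, 0.9, c(0.4, -0.2, 0.1))[3] * dnorm(t)
  ll_int <- log(integrate(Vectorize(f), -9, 9, rel.tol = 1e-13)$value)
  expect_equal(ll, ll_int, tolerance = 1e-8)
})

test_that("missing responses drop out of the likelihood", {
  s <- make_small_scores()
  s[1, 2] <- NA   # person 1 never saw item 2
  items <- tibble::tibble(item = colnames(s), alpha = c(.5, .8, 1.2),
                          beta1 = 0, beta2 = 0, beta3 = 0)
  items_b <- items
  items_b[2, c("beta1", "beta2", "beta3")] <- list(2, -1, 3)  # perturb item 2 only
  fit_shell <- function(it) {
    f <- fit_dsrt(s, "srt1d", control = list(max_iter = 1))
    f$par <- dsrt:::make_family("srt1d", 4L)$from_natural(it)
    f
  }
  ll_a <- eap_scores(s, fit_shell(items))$loglik
  ll_b <- eap_scores(s, fit_shell(items_b))$loglik
  expect_equal(ll_a[1], ll_b[1])           # unanswered item leaves person 1 unchanged
  expect_false(isTRUE(all.equal(ll_a[2], ll_b[2])))
  # an item (or person) with no observations at all is refused by name
  s4 <- cbind(s, item_extra = NA_integer_)
  items4 <- dplyr::bind_rows(items, tibble::tibble(item = "item_extra", alpha = 1,
                                                   beta1 = 0, beta2 = 0, beta3 = 0))
  expect_error(marginal_loglik(s4, items4, "srt1d"), "item_extra")
})

test_that("degenerate inputs produce informative errors", {
  s <- make_small_scores()
  s[3, ] <- NA
  expect_error(fit_dsrt(s, "srt1d"), "Person.*3")
  s2 <- make_small_scores()
  s2[, 2] <- 0L
  expect_error(fit_dsrt(s2, "srt1d"), "Empty score categories.*item2")
  expect_error(fit_dsrt(matrix(c(0, 1, 2, 5), 2), "srt1d",
                        n_categories = 4), "0..3")
})

test_that("intercept and step parameterizations give identical fits", {
  s <- make_small_scores(n = 300)
  fit <- fit_dsrt(s, "pcm")
  b <- as.matrix(fit$items[, c("beta1", "beta2", "beta3")])
  bs <- t(apply(b, 1, intercepts_to_masters))
  b_back <- t(apply(bs, 1, masters_to_intercepts))
  expect_equal(b, b_back, tolerance = 1e-12)
  ll_direct <- marginal_loglik(s, fit$items, "pcm")
  items_back <- fit$items
  items_back[, c("beta1", "beta2", "beta3")] <- b_back
  expect_equal(marginal_loglik(s, items_back, "pcm"), ll_direct)
  expect_equal(ll_direct, fit$loglik, tolerance = 1e-8)
})

test_that("EM improves on the starting values and is deterministic", {
  set.seed(60)
  items <- study_item_bank(10, 0)
  theta <- draw_latents(400, 0, seed = 61)
  s <- simulate_scores(items, theta, "srt2d", seed = 62)
  fit <- fit_dsrt(s, "srt1d")
  start_items <- tibble::tibble(item = colnames(s), alpha = 1,
                                beta1 = 0, beta2 = 0, beta3 = 0)
  expect_gt(fit$loglik, marginal_loglik(s, start_items, "srt1d", quad = fit$quad))
  fit2 <- fit_dsrt(s, "srt1d")
  expect_identical(fit$items, fit2$items)
  expect_true(fit$converged)
  # information criteria bookkeeping
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  expect_equal(fit$bic, -2 * fit$loglik + log(400) * fit$n_params)
  expect_equal(fit$n_params, 40L)
})

test_that("parameter counts per variant are as documented", {
  set.seed(70)
  items <- study_item_bank(10, 1)
  theta <- draw_latents(500, 0.3, seed = 71)
  s <- simulate_scores(items, theta, "srt2d", seed = 72)
  q1 <- quad_spec(15, 1); q2 <- quad_spec(11, 2)
  counts <- c(coomans = 10, pcm = 30, srt1d = 40, nrm = 60,
              srt2d = 51, hm = 41, irtree = 61)
  for (m in names(counts)) {
    f <- fit_dsrt(s, m, quad = if (m %in% c("srt2d", "hm", "irtree")) q2 else q1,
                  control = list(max_iter = 30))
    expect_equal(f$n_params, unname(counts[m]), info = m)
  }
})

test_that("the IRTree model nests the hierarchical model", {
  set.seed(80)
  items <- study_item_bank(10, 1)
  theta <- draw_latents(600, 0.2, seed = 81)
  s <- simulate_scores(items, theta, "srt2d", seed = 82)
  dec <- dsrt:::decode_scores(s)
  acc <- matrix(dec$accuracy, nrow(s)); fast <- matrix(dec$fast, nrow(s))
  q2 <- quad_spec(11, 2)
  f_hm <- fit_hm(acc, fast, quad = q2)
  f_tr <- fit_irtree(acc, fast, quad = q2)
  expect_gte(f_tr$loglik, f_hm$loglik)
  expect_equal(f_tr$n_params - f_hm$n_params, 20L)
})

test_that("moderate-size fits recover the generating parameters", {
  items <- study_item_bank(10, 0)
  theta <- draw_latents(2500, 0, seed = 91)
  s <- simulate_scores(items, theta, "srt2d", seed = 92)
  fit <- fit_dsrt(s, "srt1d")
  expect_lt(mean(abs(fit$items$alpha - 0.5)), 0.06)
  b_hat <- as.matrix(fit$items[, c("beta1", "beta2", "beta3")])
  b_true <- as.matrix(study_item_bank(10, 0)[, c("beta1", "beta2", "beta3")])
  expect_lt(max(abs(b_hat - b_true)), 0.35)
  expect_lt(mean(abs(b_hat - b_true)), 0.12)
})
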