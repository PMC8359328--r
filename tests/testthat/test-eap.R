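fit_null_fixture <- function() {
  items <- study_item_bank(10, 0)
  theta <- draw_latents(800, 0, seed = 101)
  s <- simulate_scores(items, theta, "srt2d", seed = 102)
  list(fit = fit_dsrt(s, "srt1d"), scores = s, theta = theta)
}

test_that("persons without responses get the prior and are flagged", {
  fx <- fit_null_fixture()
  s <- fx$scores
  s[1, ] <- NA
  est <- eap_scores(s, fx$fit)
  expect_true(est$flagged[1])
  expect_equal(est$eap_theta1[1], 0, tolerance = 1e-10)
  expect_equal(est$psd_theta1[1], 1, tolerance = 1e-6)
  expect_false(any(est$flagged[-1]))
  expect_true(all(est$psd_theta1 > 0))
})

test_that("mirror-symmetric response patterns yield sign-flipped abilities", {
  # all-zero intercepts make the category probabilities symmetric in theta
  items <- tibble::tibble(item = paste0("item", 1:6), alpha = 0.8,
                          beta1 = 0, beta2 = 0, beta3 = 0)
  s <- rbind(c(3L, 2L, 3L, 1L, 3L, 2L),
             c(0L, 1L, 0L, 2L, 0L, 1L))  # category-reversed mirror (s -> 3 - s)
  colnames(s) <- items$item
  shell <- simulate_scores(items, draw_latents(300, 0, seed = 33), "srt1d", seed = 34)
  fit <- fit_dsrt(shell, "srt1d", control = list(max_iter = 1))
  fit$par <- dsrt:::make_family("srt1d", 4L)$from_natural(items)
  est <- eap_scores(s, fit)
  expect_equal(est$eap_theta1[1], -est$eap_theta1[2], tolerance = 1e-10)
  expect_gt(est$eap_theta1[1], 0)
})

test_that("EAP estimates shrink toward zero relative to per-person ML", {
  fx <- fit_null_fixture()
  est <- eap_scores(fx$scores, fx$fit)
  it <- fx$fit$items
  ml_one <- function(row) {
    nll <- function(t) {
      -sum(vapply(seq_along(row), function(k) {
        log(oracle_probs_1d(t, it$alpha[k],
                            c(it$beta1[k], it$beta2[k], it$beta3[k]))[row[k] + 1L])
      }, numeric(1)))
    }
    optimize(nll, c(-6, 6))$minimum
  }
  idx <- order(abs(est$eap_theta1), decreasing = TRUE)[1:8]
  for (j in idx) {
    ml <- ml_one(fx$scores[j, ])
    expect_lt(abs(est$eap_theta1[j]), abs(ml) + 1e-8)
  }
})

test_that("EAP is strictly increasing in the sum score under the common-slope model", {
  items <- tibble::tibble(item = paste0("item", 1:3),
                          beta1 = c(0, .5, -.5), beta2 = c(.2, 0, .4),
                          beta3 = c(-.1, .3, 0))
  patterns <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  colnames(patterns) <- items$item
  fit <- fit_dsrt(patterns, "pcm", control = list(max_iter = 1))
  fit$par <- dsrt:::make_family("pcm", 4L)$from_natural(items)
  est <- eap_scores(patterns, fit)
  agg <- tapply(est$eap_theta1, rowSums(patterns), function(x) {
    expect_lt(diff(range(x)), 1e-10)  # equal sum scores -> equal EAP
    mean(x)
  })
  expect_true(all(diff(agg) > 0))     # higher sum score -> strictly higher EAP
})

test_that("reliability formula behaves at its limits", {
  est <- tibble::tibble(eap_theta1 = rnorm(100), psd_theta1 = 1e-9)
  expect_gt(eap_reliability(est), 0.999999)
  est2 <- tibble::tibble(eap_theta1 = rep(1, 50), psd_theta1 = 0.5)
  expect_equal(eap_reliability(est2), 0)
  est3 <- tibble::tibble(eap_theta1 = rnorm(2000), psd_theta1 = 1)
  r <- eap_reliability(est3)
  expect_true(r > 0 && r < 1)
  expect_error(eap_reliability(est3[1, ]), "two persons")
})

test_that("bias/variance/MSE aggregation and decomposition are exact", {
  truth <- c(-1, 0, 2)
  est <- rbind(truth, truth, truth)
  out <- bias_var_mse(est, truth)
  expect_equal(c(out$bias, out$variance, out$mse), c(0, 0, 0))
  out2 <- bias_var_mse(matrix(rep(truth + 0.3, each = 5), 5), truth)
  expect_equal(c(out2$bias, out2$variance, out2$mse), c(0.3, 0, 0.09))
  set.seed(1)
  est3 <- matrix(rnorm(200), 20, 10)
  out3 <- bias_var_mse(est3, rnorm(10))
  pp <- out3$per_person
  expect_equal(pp$mse, pp$bias^2 + pp$variance, tolerance = 1e-12)
  expect_equal(out3$mse, mean(pp$mse))
  expect_error(bias_var_mse(est3, rnorm(4)), "match")
})
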