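test_that("latent draws have the requested moments and are reproducible", {
  th <- draw_latents(1e5, rho = 0.5, seed = 21)
  expect_lt(abs(cor(th)[1, 2] - 0.5), 0.01)
  expect_lt(abs(mean(th[, 1])), 0.02)
  expect_lt(abs(sd(th[, 2]) - 1), 0.01)
  th0 <- draw_latents(1e5, rho = 0, seed = 22)
  expect_lt(abs(cor(th0)[1, 2]), 0.01)
  expect_identical(draw_latents(50, .3, seed = 1), draw_latents(50, .3, seed = 1))
  expect_error(draw_latents(10, rho = 1), "rho")
  # standardized draws hit the identification constraints exactly
  ts <- draw_latents(500, 0.4, seed = 9, standardize = TRUE)
  expect_equal(colMeans(ts), c(theta1 = 0, theta2 = 0), tolerance = 1e-12)
  expect_equal(unname(diag(var(ts))), c(1, 1), tolerance = 1e-12)
  expect_equal(cor(ts)[1, 2], 0.4, tolerance = 1e-12)
})

test_that("item bank tiles the five intercept sets with the requested slopes", {
  it <- study_item_bank(20, speed_slope = 1)
  expect_equal(nrow(it), 20)
  expect_equal(unique(it$alpha1), 0.5)
  expect_equal(unique(it$alpha2), 1)
  b <- as.matrix(it[, c("beta1", "beta2", "beta3")])
  expect_equal(b[1:5, ], reference_beta_sets(), ignore_attr = TRUE)
  expect_equal(b[6:10, ], reference_beta_sets(), ignore_attr = TRUE)
  expect_error(study_item_bank(21), "multiple of 5")
})

test_that("simulated category frequencies match the analytic probabilities", {
  n <- 1e5
  items <- study_item_bank(5, speed_slope = 0)
  theta <- cbind(rep(0, n), rep(0, n))  # degenerate persons isolate the item model
  s <- simulate_scores(items, theta, "srt2d", seed = 31)
  # item 2 has intercepts [1.5, 1.5, 0]: P(score = 1) = .409 at the mean
  p_hat <- tabulate(s[, 2] + 1L, 4) / n
  p_true <- oracle_probs_1d(0, 0.5, c(1.5, 1.5, 0))
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_true(all(abs(p_hat - p_true) < 3 * se))
  expect_equal(round(p_hat[2], 1), 0.4)
  # 2D generator at nonzero speed values
  items2 <- study_item_bank(5, speed_slope = 1)
  theta2 <- cbind(rep(0.4, n), rep(-0.8, n))
  s2 <- simulate_scores(items2, theta2, "srt2d", seed = 32)
  p_hat2 <- tabulate(s2[, 1] + 1L, 4) / n
  p_true2 <- oracle_probs_2d(0.4, -0.8, 0.5, 1, c(0, 0, 0))
  expect_true(all(abs(p_hat2 - p_true2) < 3 * sqrt(p_true2 * (1 - p_true2) / n)))
})

test_that("higher speed raises the fast-response share; seeds reproduce", {
  items <- study_item_bank(10, speed_slope = 1)
  n <- 20000
  th_hi <- cbind(rnorm(n), rep(1, n))
  th_lo <- cbind(rnorm(n), rep(-1, n))
  fast_share <- function(s) mean(s %in% c(0, 3))
  set.seed(8)
  expect_gt(fast_share(simulate_scores(items, th_hi, "srt2d")),
            fast_share(simulate_scores(items, th_lo, "srt2d")))
  expect_identical(simulate_scores(items, th_hi, "srt2d", seed = 4),
                   simulate_scores(items, th_hi, "srt2d", seed = 4))
})

test_that("hierarchical and IRTree generators follow their composed probabilities", {
  n <- 6e4
  hm_items <- tibble::tibble(item = "i1", alpha_acc = 1, beta_acc = 0.5,
                             alpha_spd = 1, beta_spd = -0.3)
  s <- simulate_scores(hm_items, cbind(rep(0.2, n), rep(0.6, n)), "hm", seed = 41)
  px <- plogis(0.2 + 0.5); pf <- plogis(0.6 - 0.3)
  p_true <- c((1 - px) * pf, (1 - px) * (1 - pf), px * (1 - pf), px * pf)
  p_hat <- tabulate(s[, 1] + 1L, 4) / n
  expect_true(all(abs(p_hat - p_true) < 3 * sqrt(p_true * (1 - p_true) / n)))

  tr_items <- tibble::tibble(item = "i1", alpha_spd = 1, beta_spd = 0,
                             alpha_fast = 1, beta_fast = 0,
                             alpha_slow = 1, beta_slow = 1)
  s2 <- simulate_scores(tr_items, cbind(rep(0, n), rep(0, n)), "irtree", seed = 42)
  # P(fast, correct) = .5 * .5 at the origin with unit slopes, zero intercepts
  expect_equal(mean(s2[, 1] == 3), 0.25, tolerance = 0.015)
  # slow branch uses its own intercept: P(correct | slow) = plogis(1)
  expect_equal(mean(s2[s2[, 1] %in% c(1, 2), 1] == 2), plogis(1), tolerance = 0.015)
})

test_that("missing-at-random masking preserves observed category frequencies", {
  items <- study_item_bank(10, 0)
  theta <- draw_latents(20000, 0, seed = 51)
  s <- simulate_scores(items, theta, "srt2d", seed = 52)
  sm <- inject_missing(s, prop = 0.4, seed = 53)
  expect_equal(mean(is.na(sm)), 0.4, tolerance = 0.01)
  f_all <- tabulate(s + 1L, 4) / length(s)
  f_obs <- tabulate(sm + 1L, 4) / sum(!is.na(sm))
  expect_equal(f_obs, f_all, tolerance = 0.02)
})
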