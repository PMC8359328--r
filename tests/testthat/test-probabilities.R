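test_that("single-parameter model is softmax of s*(theta - delta)", {
  expect_equal(prob_coomans(1, 1), rep(.25, 4), ignore_attr = TRUE)
  # softmax of (0, 1, 2, 3)
  e <- exp(0:3) / sum(exp(0:3))
  expect_equal(prob_coomans(1.5, 0.5), e, ignore_attr = TRUE)
  expect_equal(round(e, 3), c(0.032, 0.087, 0.237, 0.644))
  p <- prob_coomans(2, 1)
  expect_true(all(diff(p) > 0)) # increasing in s when theta > delta
})

test_that("slope-generalized model reproduces the reference probability vectors", {
  # the four non-uniform intercept sets at the population mean, one decimal
  expect_equal(round(prob_gpcm1d(0, 0.5, c(1.5, 1.5, 0)), 1), c(.1, .4, .4, .1),
               ignore_attr = TRUE)
  expect_equal(round(prob_gpcm1d(0, 0.5, c(-1.5, -1.5, 0)), 1), c(.4, .1, .1, .4),
               ignore_attr = TRUE)
  expect_equal(round(prob_gpcm1d(0, 0.5, c(0, 1.5, 1.5)), 1), c(.1, .1, .4, .4),
               ignore_attr = TRUE)
  expect_equal(round(prob_gpcm1d(0, 0.5, c(0, -1.5, -1.5)), 1), c(.4, .4, .1, .1),
               ignore_attr = TRUE)
  # beta = 0 gives the uniform vector (.25 each), not a ".5 each" line
  expect_equal(prob_gpcm1d(0, 0.5, c(0, 0, 0)), rep(.25, 4), ignore_attr = TRUE)
  expect_error(prob_gpcm1d(0, -1, c(0, 0, 0)), "positive")
})

test_that("model reduction chain holds numerically on random inputs", {
  set.seed(42)
  for (i in 1:20) {
    th1 <- rnorm(1); th2 <- rnorm(1)
    a1 <- runif(1, .3, 2); a2 <- runif(1, .3, 2)
    beta <- rnorm(3); delta <- rnorm(1)
    # general nominal form with the default scoring vectors == 2D model
    expect_equal(
      prob_nominal(cbind(th1, th2), list(0:3, c(1, 0, 0, 1)),
                   alpha = c(a1, a2), beta = beta),
      prob_2d(th1, th2, a1, a2, beta), ignore_attr = TRUE, tolerance = 1e-12)
    # 2D with a dead speed loading == 1D slope model
    expect_equal(prob_2d(th1, th2, a1, 1e-300, beta),
                 prob_gpcm1d(th1, a1, beta), ignore_attr = TRUE, tolerance = 1e-12)
    # slope 1 == partial credit form; beta_s = -s*delta == single-parameter model
    expect_equal(prob_gpcm1d(th1, 1, -(1:3) * delta),
                 prob_coomans(th1, delta), ignore_attr = TRUE, tolerance = 1e-12)
    p <- prob_2d(th1, th2, a1, a2, beta)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("two-dimensional probabilities respond to speed as expected", {
  p <- prob_2d(0, 1, 0.5, 1, c(0, 0, 0))
  e <- exp(1)
  expect_equal(p, c(e, 1, 1, e) / (2 * e + 2), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(p[1] + p[4], e / (e + 1), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(round(prob_2d(0, 0, 0.5, 1, c(1.5, 1.5, 0))[2], 1), 0.4,
               ignore_attr = TRUE)
  # total fast probability strictly increasing in theta2
  pf <- vapply(seq(-2, 2, by = .5),
               function(t2) sum(prob_2d(0.3, t2, 0.5, 1, c(1, -1, .5))[c(1, 4)]),
               numeric(1))
  expect_true(all(diff(pf) > 0))
  expect_error(prob_2d(0, 0, .5, 1, c(0, 0, 0), c2 = c(1, 0, 0)), "length")
})

test_that("step-parameter conversion round-trips and preserves probabilities", {
  expect_equal(masters_to_intercepts(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(masters_to_intercepts(c(1, -1, 0)), c(-1, 0, 0))
  set.seed(7)
  for (i in 1:10) {
    b <- rnorm(3)
    expect_equal(masters_to_intercepts(intercepts_to_masters(b)), b)
    bs <- intercepts_to_masters(b)
    # direct evaluation of the step ("Masters") form of the model
    th <- rnorm(1)
    num <- c(1, exp(cumsum(th - bs)))
    expect_equal(prob_gpcm1d(th, 1, b), num / sum(num),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("fast-response probability given accuracy behaves as a logistic in theta", {
  expect_equal(p_fast_given_accuracy(0, 1, c(0, 0, 0), x = 1), 0.5)
  expect_equal(p_fast_given_accuracy(0, 1, c(0, 0, 0), x = 0), 0.5)
  expect_equal(p_fast_given_accuracy(1, 1, c(0, 0, 0), x = 1), plogis(1),
               tolerance = 1e-12)
  th <- seq(-2, 2, by = .5)
  p1 <- p_fast_given_accuracy(th, 0.7, c(.3, -.2, .4), x = 1)
  p0 <- p_fast_given_accuracy(th, 0.7, c(.3, -.2, .4), x = 0)
  expect_true(all(diff(p1) > 0))  # increasing in theta for correct responses
  expect_true(all(diff(p0) < 0))  # decreasing for incorrect
  # ratio-of-category-probabilities identity
  p <- prob_gpcm1d(1.3, 0.7, c(.3, -.2, .4))
  expect_equal(p_fast_given_accuracy(1.3, 0.7, c(.3, -.2, .4), x = 1),
               p[4] / (p[3] + p[4]), ignore_attr = TRUE)
})

test_that("speed indicators correlate positively given equal accuracy, negatively otherwise", {
  # symmetric intercept sets (beta3 - beta2 = -beta1) at nonzero theta: the
  # fast probability given correct minus given incorrect has a common sign
  # across items, so conditioning on the accuracy event signs the covariance
  set.seed(11)
  for (i in 1:10) {
    a <- runif(2, .4, 1.5)
    b1 <- runif(2, -2, 2)
    bmat <- cbind(b1, runif(2, -2, 2), 0)
    bmat[, 3] <- bmat[, 2] - b1            # enforce symmetry
    theta <- 1
    p_i <- prob_gpcm1d(theta, a[1], bmat[1, ])
    p_k <- prob_gpcm1d(theta, a[2], bmat[2, ])
    joint <- outer(p_i, p_k)               # 16 outcomes, local independence
    fast <- c(1, 0, 0, 1); corr <- c(0, 0, 1, 1)
    cor_given <- function(keep) {
      w <- joint * keep; w <- w / sum(w)
      fi <- outer(fast, rep(1, 4)); fk <- outer(rep(1, 4), fast)
      m1 <- sum(w * fi); m2 <- sum(w * fk)
      (sum(w * fi * fk) - m1 * m2) /
        sqrt(m1 * (1 - m1) * m2 * (1 - m2))
    }
    same <- outer(corr, corr, function(a, b) as.numeric(a == b))
    expect_gt(cor_given(same), 0)
    expect_lt(cor_given(1 - same), 0)
  }
})

test_that("sum score is sufficient for the person under the common-slope model", {
  # K = 3 items, all patterns enumerated: equal-sum-score patterns have
  # proportional likelihoods as functions of theta
  set.seed(3)
  betas <- matrix(rnorm(9), 3)
  th <- seq(-2, 2, length.out = 9)
  patterns <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  lik <- apply(patterns, 1L, function(pat) {
    apply(vapply(1:3, function(k) {
      vapply(th, function(t) oracle_probs_1d(t, 1, betas[k, ])[pat[k] + 1L], numeric(1))
    }, numeric(length(th))), 1L, prod)
  })
  ss <- rowSums(patterns)
  for (s in unique(ss)) {
    idx <- which(ss == s)
    if (length(idx) < 2L) next
    ratios <- lik[, idx] / lik[, idx[1L]]
    expect_lt(max(apply(ratios, 2L, function(r) diff(range(r)) / mean(r))), 1e-10)
  }
})
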