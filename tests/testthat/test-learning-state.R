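test_that("degenerate blocks give the expected bounds and no learning trial", {
  err <- em_learning_curve(rep(0, 20))
  expect_lt(tail(err$p_upper95, 1), 0.5)
  expect_true(is.na(attr(err, "learning_trial")))
  ok <- em_learning_curve(rep(1, 30))
  expect_gt(tail(ok$p_lower95, 1), 0.5)
  expect_false(is.na(attr(ok, "learning_trial")))
  expect_error(em_learning_curve(c(1, 0, 1)), "at least 5")
})

test_that("bound ordering and variance positivity hold on random sequences", {
  set.seed(31)
  for (i in 1:10) {
    y <- rbinom(sample(10:40, 1), 1, runif(1, 0.2, 0.9))
    if (length(unique(y)) == 1) y[1] <- 1 - y[1]
    est <- em_learning_curve(y)
    expect_true(all(est$p_lower95 <= est$p_mode))
    expect_true(all(est$p_mode <= est$p_upper95))
    expect_true(all(est$p_mode > 0 & est$p_mode < 1))
    expect_gt(attr(est, "process_variance"), 0)
  }
})

test_that("the Gaussian smoother agrees with the dense-grid exact smoother", {
  set.seed(32)
  worst <- 0
  for (i in 1:20) {
    y <- rbinom(15, 1, 0.5)
    est <- em_learning_curve(y)
    g <- em_grid_smoother(y, attr(est, "process_variance"))
    worst <- max(worst, max(abs(est$p_mode - g$p_median)))
  }
  expect_lt(worst, 0.05)
})

test_that("learning-trial detection follows the persistence rule", {
  expect_equal(
    detect_learning_trial(data.frame(p_lower95 = c(.3, .4, .6, .4, .6, .7, .8))),
    5L
  )
  expect_equal(
    detect_learning_trial(data.frame(p_lower95 = c(.3, .4, .45, .55, .6, .7))),
    4L
  )
  expect_true(is.na(detect_learning_trial(data.frame(p_lower95 = rep(.4, 6)))))
  # bound exactly at chance does not count as above
  expect_equal(
    detect_learning_trial(data.frame(p_lower95 = c(.5, .6, .7))), 2L
  )
})

test_that("appending correct trials never lowers the final smoothed estimate", {
  set.seed(33)
  for (i in 1:6) {
    y <- rbinom(20, 1, 0.6)
    base <- em_learning_curve(y)
    longer <- em_learning_curve(c(y, rep(1, 5)))
    expect_gte(tail(longer$p_mode, 1) + 1e-6, tail(base$p_mode, 1))
  }
})

test_that("the exact data log-likelihood is non-decreasing over EM iterations", {
  set.seed(34)
  for (i in 1:3) {
    y <- step_block(sample(8:14, 1), n = 25)
    est <- em_learning_curve(y, track_loglik = TRUE)
    ll <- attr(est, "loglik_trace")
    expect_gt(length(ll), 1)
    expect_true(all(diff(ll) > -1e-4))
  }
})

test_that("EM detects step-change learning with small median error", {
  set.seed(35)
  res <- t(replicate(60, {
    k <- sample(8:20, 1)
    lt <- glance(em_learning_curve(step_block(k)))$learning_trial
    c(k, lt)
  }))
  d <- res[, 2] - res[, 1]
  detected <- !is.na(d)
  expect_gt(mean(detected), 0.7)
  expect_lte(abs(median(d[detected])), 3)
  expect_gt(mean(abs(d[detected]) <= 5), 0.75)
})
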