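levels6 <- c("c1", "c2", "up", "down", "left", "right")

test_that("object value is the weighted combination of feature values", {
  v <- setNames(rep(0.5, 6), levels6)
  expect_equal(object_value(v, c("c1", "up", "left")), 0.5)
  v2 <- setNames(c(1, 0, 0, 0, 0, 0), levels6)
  expect_equal(object_value(v2, c("c1", "up", "left")), 1 / 3)
  v3 <- setNames(c(0.8, 0, 0, 0, 0, 0), levels6)
  expect_equal(object_value(v3, c("c1", "up", "left"), c(1, 0, 0)), 0.8)
  expect_error(object_value(v, c("c1", "up", "left"), c(1, 1, 0)),
               "sum to 1")
})

test_that("softmax choice probability is symmetric, stable, and exact", {
  expect_equal(choice_probability(0.7, 0.7, 3), 0.5)
  expect_equal(choice_probability(0.9, 0.1, 0), 0.5)
  expect_equal(choice_probability(1, 0, log(3)), 0.75)
  expect_equal(choice_probability(1, 0, 1e6), 1)
  expect_equal(choice_probability(0, 1, 1e6), 0)
  # complementary probabilities sum to one
  for (b in c(0, 1, 7, 50)) {
    expect_equal(choice_probability(0.3, 0.8, b) +
                   choice_probability(0.8, 0.3, b), 1)
  }
})

test_that("value updates scale the RPE and decay the unchosen features", {
  v <- setNames(rep(0.5, 6), levels6)
  frozen <- update_values(v, c("c1", "up", "left"), c("c2", "down", "right"),
                          1, agent_params(1e-9, 5, 0))
  expect_equal(frozen$delta, 0.5)
  expect_equal(unname(frozen$values), rep(0.5, 6), tolerance = 1e-8)
  upd <- update_values(v, c("c1", "up", "left"), c("c2", "down", "right"),
                       1, agent_params(0.4, 5, 0))
  expect_equal(upd$delta, 0.5)
  expect_equal(unname(upd$values["c1"]), 0.7)
  # full decay resets unchosen levels to the initial value
  v4 <- setNames(c(0.9, 0.1, 0.8, 0.2, 0.7, 0.3), levels6)
  full <- update_values(v4, c("c1", "up", "left"), c("c2", "down", "right"),
                        0, agent_params(0.2, 5, 1))
  expect_equal(unname(full$values[c("c2", "down", "right")]), rep(0.5, 3))
})

test_that("latent replay matches the generator to machine precision", {
  s <- fixture_session()
  lat <- fixture_latents()
  expect_equal(lat$p_choice, s$latents$p_choice, tolerance = 1e-12)
  expect_equal(lat$rpe, s$latents$rpe, tolerance = 1e-12)
  expect_equal(lat$rpe_pos, pmax(lat$rpe, 0))
  expect_equal(lat$rpe_neg, pmin(lat$rpe, 0))
  # first trial of the session: all values at v0 = 0.5
  expect_equal(lat$v_chosen[1], 0.5)
  expect_equal(abs(lat$rpe[1]), 0.5)
  expect_true(all(lat$rpe[s$trials$outcome == 0] <= 0))
  expect_true(all(lat$rpe[s$trials$outcome == 1] >= 0))
  expect_error(compute_latents(s$trials[, 1:4], fixture_agent()),
               "missing column")
})

test_that("feature values stay in [0,1] and RPEs in [-1,1] across a sweep", {
  set.seed(21)
  for (i in 1:6) {
    ag <- agent_params(runif(1, 0.05, 1), runif(1, 0, 10), runif(1, 0, 1))
    s <- simulate_session(4, ag, seed = 300 + i)
    lat <- compute_latents(s$trials, ag, learning_trials = tibble::tibble(
      session_id = character(), block_index = integer(),
      learning_trial = integer()
    ))
    expect_true(all(lat$v_chosen >= 0 & lat$v_chosen <= 1))
    expect_true(all(lat$rpe >= -1 & lat$rpe <= 1))
  }
})

test_that("chance model likelihood is exactly n log(1/2)", {
  s <- fixture_session()
  ag <- agent_params(0.3, 0, 0.1)
  expect_equal(agent_log_likelihood(s$trials, ag),
               nrow(s$trials) * log(0.5))
})

test_that("the fitted maximum beats a parameter grid around the truth", {
  truth <- agent_params(0.2, 6, 0.15)
  s <- simulate_session(24, truth, seed = 401)
  fit <- fit_agent_mle(s$trials, seed = 1)
  grid <- expand.grid(
    eta = truth$learning_rate * c(0.6, 0.8, 1, 1.25, 1.6),
    beta = truth$inverse_temperature * c(0.6, 0.8, 1, 1.25, 1.6),
    gamma = truth$decay * c(0.6, 0.8, 1, 1.25, 1.6)
  )
  ll_grid <- apply(grid, 1, function(p) {
    agent_log_likelihood(s$trials, agent_params(p[1], p[2], p[3]))
  })
  expect_gte(fit$logLik + 1e-6, max(ll_grid))
  expect_gte(fit$logLik, agent_log_likelihood(s$trials, truth))
})

test_that("fits are deterministic given a seed and expose tidy methods", {
  s <- fixture_session()
  f1 <- fit_agent_mle(s$trials, seed = 8, n_restarts = 4)
  f2 <- fit_agent_mle(s$trials, seed = 8, n_restarts = 4)
  expect_identical(tidy(f1), tidy(f2))
  td <- tidy(f1)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 3)
  gl <- glance(f1)
  expect_true(all(c("logLik", "n_trials", "converged") %in% names(gl)))
  expect_equal(gl$n_trials, nrow(s$trials))
})
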