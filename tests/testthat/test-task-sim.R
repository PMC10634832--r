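test_that("block switch rule needs 30 trials and 90% over the last 12", {
  spec <- block_spec()
  expect_false(check_block_switch(rep(1, 29), spec))
  expect_true(check_block_switch(rep(1, 30), spec))
  # 2 errors inside the final 12-trial window: 10/12 < 0.9
  outcomes <- c(rep(1, 18), rep(1, 12))
  outcomes[c(20, 25)] <- 0
  expect_false(check_block_switch(outcomes, spec))
  # errors before the window do not block the switch
  outcomes2 <- c(rep(0, 18), rep(1, 12))
  expect_true(check_block_switch(outcomes2, spec))
  # hard cap ends a block regardless of performance
  expect_true(check_block_switch(rep(0, spec$max_trials), spec))
  expect_error(check_block_switch(integer(0), spec), "at least one")
})

test_that("stimulus pairs are mutually opposite, seeded, and balanced", {
  s <- make_trial_stimuli(rng_seed = 5)
  expect_false(s$stim_A_color == s$stim_B_color)
  expect_false(s$stim_A_motion == s$stim_B_motion)
  expect_false(s$stim_A_location == s$stim_B_location)
  expect_identical(s, make_trial_stimuli(rng_seed = 5))
  set.seed(9)
  draws <- flexshift:::draw_stimulus_pairs(10000)
  # colour-location pairing uniform: P(c1 with left) = 0.5 +/- 0.02
  p_cl <- mean((draws$stim_A_color == "c1") == (draws$stim_A_location == "left"))
  expect_lt(abs(p_cl - 0.5), 0.02)
  p_cm <- mean((draws$stim_A_color == "c1") == (draws$stim_A_motion == "up"))
  expect_lt(abs(p_cm - 0.5), 0.02)
})

test_that("simulated sessions alternate the rewarded colour and obey block bounds", {
  s <- fixture_session()
  spec <- block_spec()
  per_block <- dplyr::summarise(
    dplyr::group_by(s$trials, block_index),
    n = dplyr::n(), col = rewarded_color[1], .groups = "drop"
  )
  expect_true(all(per_block$col[-1] != per_block$col[-nrow(per_block)]))
  expect_true(all(per_block$n >= spec$min_trials))
  expect_true(all(per_block$n <= spec$max_trials))
  expect_equal(sum(per_block$n), nrow(s$trials))
  expect_equal(nrow(s$trials), nrow(s$latents))
  # outcome consistent with rewarded colour
  chosen_color <- ifelse(s$trials$chosen_stim == "A",
                         s$trials$stim_A_color, s$trials$stim_B_color)
  expect_equal(s$trials$outcome,
               as.integer(chosen_color == s$trials$rewarded_color))
  # event times strictly increasing
  tmat <- as.matrix(s$trials[, c("t_fixation_on", "t_color_on", "t_motion_on",
                                 "t_dimming", "t_saccade", "t_feedback")])
  expect_true(all(apply(tmat, 1, function(x) all(diff(x) > 0))))
})

test_that("seeded sessions are exactly reproducible", {
  a <- simulate_session(3, fixture_agent(), seed = 77)
  b <- simulate_session(3, fixture_agent(), seed = 77)
  expect_identical(a, b)
})

test_that("a random agent performs at chance", {
  s <- simulate_session(60, agent_params(0.3, 0, 0.1),
                        spec = block_spec(max_trials = 80), seed = 12)
  expect_gte(nrow(s$trials), 4800) # random agent never reaches criterion
  expect_lt(abs(mean(s$trials$outcome) - 0.5), 0.02)
})

test_that("a sharp agent learns every block once values separate", {
  s <- simulate_session(10, agent_params(0.5, 40, 0.2), seed = 13)
  late <- dplyr::filter(s$trials, trial_in_block > 20)
  acc <- dplyr::summarise(dplyr::group_by(late, block_index),
                          acc = mean(outcome))
  expect_true(all(acc$acc > 0.9))
})

test_that("invalid configurations are rejected", {
  expect_error(simulate_session(0, fixture_agent()), "n_blocks")
  bad <- fixture_agent()
  bad$inverse_temperature <- Inf
  expect_error(simulate_session(2, bad), "finite")
  expect_error(block_spec(switch_window = 40), "switch_window")
})
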