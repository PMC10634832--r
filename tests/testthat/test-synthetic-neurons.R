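test_that("untuned units fire at baseline with Poisson statistics", {
  tr <- flat_trials(1000)
  lat <- flat_latents(tr)
  us <- unit_spec("p1", baseline_rate = 5)
  rec <- generate_spike_trains(us, tr, lat, seed = 51)
  # feedback epoch is 0.95 s; expected count 4.75, 3 SE of the mean
  counts <- epoch_rate(rec, tr, "feedback", method = "count")$rate * 0.95
  expect_lt(abs(mean(counts) - 4.75), 3 * sqrt(4.75 / 1000))
  fano <- var(counts) / mean(counts)
  expect_lt(abs(fano - 1), 0.15)
})

test_that("seeded spike generation is exactly reproducible", {
  tr <- flat_trials(50, seed = 1)
  lat <- flat_latents(tr)
  us <- unit_spec("d1", baseline_rate = 10)
  a <- generate_spike_trains(us, tr, lat, seed = 52)
  b <- generate_spike_trains(us, tr, lat, seed = 52)
  expect_identical(a$spikes, b$spikes)
})

test_that("a positive outcome gain raises correct-trial epoch rates", {
  set.seed(53)
  out <- rbinom(600, 1, 0.5)
  tr <- flat_trials(600, outcome = as.integer(out))
  lat <- flat_latents(tr)
  us <- unit_spec("g1", baseline_rate = 8, tuning = c(outcome = 0.5))
  rec <- generate_spike_trains(us, tr, lat, seed = 54)
  er <- epoch_rate(rec, tr, "feedback", method = "count")
  r_correct <- mean(er$rate[tr$outcome == 1])
  r_error <- mean(er$rate[tr$outcome == 0])
  expect_gt(r_correct, r_error)
})

test_that("an injected log-linear gain is recoverable by Poisson regression", {
  set.seed(55)
  out <- rbinom(500, 1, 0.5)
  tr <- flat_trials(500, outcome = as.integer(out))
  lat <- flat_latents(tr)
  gain <- 0.3
  us <- unit_spec("g2", baseline_rate = 10, tuning = c(rpe_signed = gain))
  rec <- generate_spike_trains(us, tr, lat, seed = 56)
  counts <- round(epoch_rate(rec, tr, "feedback", method = "count")$rate * 0.95)
  regs <- build_regressors(tr, lat, learning_trials = tibble::tibble(
    session_id = "flat", block_index = 1L, learning_trial = NA_integer_
  ), epoch = "feedback")
  z <- scale(regs$rpe_signed)[, 1]
  slope <- unname(coef(glm(counts ~ z, family = poisson()))[2])
  expect_lt(abs(slope - gain) / gain, 0.15)
})

test_that("excessive gains are rejected", {
  tr <- flat_trials(50, outcome = rep(c(0L, 1L), 25))
  lat <- flat_latents(tr)
  us <- unit_spec("x1", baseline_rate = 90, tuning = c(outcome = 5))
  expect_error(generate_spike_trains(us, tr, lat, seed = 57), "500 Hz")
})

test_that("generated waveforms hit their drawn metric targets", {
  wf <- generate_waveforms(default_waveform_classes("cortical", 0.5),
                           n_units = 24, seed = 58)
  m <- measure_waveforms(wf)
  expect_lt(max(abs(m$peak_to_trough_ms - wf$target_peak_to_trough_ms)),
            0.011)
  rel <- abs(m$time_to_repolarization_ms /
               wf$target_time_to_repolarization_ms - 1)
  expect_lt(max(rel), 0.05)
  wfs <- generate_waveforms(default_waveform_classes("striatal", 0.5),
                            n_units = 24, seed = 59)
  ms <- measure_waveforms(wfs)
  expect_lt(max(abs(ms$peak_width_half_max_ms /
                      wfs$target_peak_width_half_max_ms - 1)), 0.05)
  expect_lt(max(abs(ms$valley_decay_slope /
                      wfs$target_valley_decay_slope - 1)), 0.05)
})

test_that("indistinguishable class parameters yield chance classification", {
  cp <- default_waveform_classes("cortical", 0.5)
  cp$classes$NS <- cp$classes$BS
  wf <- generate_waveforms(cp, n_units = 40, seed = 60)
  cl <- classify_units(measure_waveforms(wf), "cortical")
  acc <- mean(cl$label == cl$true_class)
  expect_lt(acc, 0.75)
  expect_gt(acc, 0.25)
})
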