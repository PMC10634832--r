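test_that("spike density is a sum of unit-area Gaussian kernels", {
  peak <- spike_density(0.5, 0.5)
  expect_equal(peak, 1 / (0.05 * sqrt(2 * pi)), tolerance = 1e-10)
  # unit area per spike
  grid <- seq(-0.5, 1.5, by = 0.001)
  expect_equal(sum(spike_density(0.5, grid)) * 0.001, 1, tolerance = 1e-3)
  # far-apart spikes superpose linearly
  two <- spike_density(c(0.2, 5.2), c(0.2, 5.2))
  expect_equal(two, rep(peak, 2), tolerance = 1e-6)
  expect_equal(spike_density(numeric(0), grid), rep(0, length(grid)))
})

test_that("epoch rates match the kernel closed form and Poisson expectation", {
  tr <- flat_trials(400)
  lat <- flat_latents(tr)
  rec <- generate_spike_trains(unit_spec("e1", baseline_rate = 10), tr, lat,
                               seed = 71)
  er <- epoch_rate(rec, tr, "feedback")
  expect_lt(abs(mean(er$rate) - 10), 3 * sqrt(10 / 0.95 / 400))
  # kernel mode equals the mean of the gridded density trace
  t1 <- rec$spikes$spike_time_s[rec$spikes$trial_index == 1]
  grid <- seq(2.80, 3.75, by = 0.001)
  expect_equal(er$rate[1], mean(spike_density(t1, grid)), tolerance = 0.02)
  none <- manual_unit(list(numeric(0), numeric(0)))
  tr2 <- flat_trials(2)
  expect_equal(epoch_rate(none, tr2, "feedback")$rate, c(0, 0))
  expect_error(epoch_rate(rec, tr, "reward"), "unknown epoch")
})

test_that("the regressor table applies learning masks and error ranks", {
  out <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L, rep(1L, 8))
  tr <- flat_trials(length(out), outcome = out)
  lat <- flat_latents(tr)
  lt <- tibble::tibble(session_id = "flat", block_index = 1L,
                       learning_trial = 12L)
  regs <- build_regressors(tr, lat, lt, epoch = "feedback")
  expect_equal(ncol(regs), 18)
  expect_true(all(is.na(regs$outcome_during_learning[12:15])))
  expect_equal(regs$outcome_during_learning[1:11], as.numeric(out[1:11]))
  expect_true(all(is.na(regs$outcome_after_learning[1:11])))
  # errors at trials 2, 5, 7 before learning -> descending ranks 3, 2, 1
  expect_equal(regs$error_order_during_learning[c(2, 5, 7)], c(3, 2, 1))
  expect_true(all(is.na(regs$error_order_during_learning[-c(2, 5, 7)])))
  # prior-outcome variables condition on the current trial's outcome
  expect_true(is.na(regs$prior_outcome_given_correct[1]))
  expect_equal(regs$prior_outcome_given_error[2], 1)
  expect_true(is.na(regs$prior_outcome_given_error[3]))
  allc <- build_regressors(flat_trials(10), flat_latents(flat_trials(10)),
                           tibble::tibble(session_id = "flat",
                                          block_index = 1L,
                                          learning_trial = 5L),
                           epoch = "feedback")
  expect_true(all(is.na(allc$prior_outcome_given_error)))
  att <- build_regressors(tr, lat, lt, epoch = "attention")
  expect_true(all(c("choice_probability", "value_chosen_rewarded",
                    "value_chosen_unrewarded") %in% names(att)))
  expect_true(all(is.na(att$value_chosen_unrewarded[out == 1])))
})

test_that("univariate regression reports r, R2 and the 30-trial rule", {
  x <- rnorm(40)
  perfect <- regress_unit(2 * x, x)
  expect_equal(perfect$r, 1, tolerance = 1e-10)
  expect_equal(perfect$r2, 1, tolerance = 1e-10)
  expect_true(perfect$significant)
  const <- regress_unit(rnorm(40), rep(1, 40))
  expect_false(const$significant)
  expect_true(is.na(const$r))
  short <- regress_unit(2 * x[1:29], x[1:29])
  expect_false(short$significant)
  expect_equal(short$n_trials, 29)
  # NA pairs are dropped per regressor, not per unit
  xm <- x
  xm[1:5] <- NA
  dropped <- regress_unit(2 * x, xm)
  expect_equal(dropped$n_trials, 35)
  expect_true(dropped$significant)
})

test_that("tuned units are detected and untuned units stay at the alpha level", {
  set.seed(72)
  out <- rbinom(400, 1, 0.5)
  tr <- flat_trials(400, outcome = as.integer(out))
  lat <- flat_latents(tr)
  lt <- tibble::tibble(session_id = "flat", block_index = 1L,
                       learning_trial = NA_integer_)
  regs <- build_regressors(tr, lat, lt, epoch = "feedback")
  z <- scale(regs$rpe_signed)[, 1]
  run_unit <- function(gain) {
    lam <- 8 * exp(gain * z) * 0.95
    counts <- rpois(400, lam)
    regress_unit(counts / 0.95, regs$rpe_signed)
  }
  tuned <- dplyr::bind_rows(lapply(1:40, function(i) run_unit(0.3)))
  untuned <- dplyr::bind_rows(lapply(1:60, function(i) run_unit(0)))
  expect_gte(mean(tuned$significant), 0.9)
  expect_lte(mean(untuned$significant), 0.1)
  expect_gte(mean(tuned$r > 0), 0.95) # sign matches the injected gain
})

test_that("the permutation comparison is exchangeable and respects min_n", {
  set.seed(73)
  res <- tibble::tibble(
    unit_id = sprintf("u%02d", 1:40),
    area = "ACC", epoch = "feedback", variable = "outcome",
    condition = rep(c("drug", "control"), each = 20),
    r = c(rnorm(20, 0.3, 0.1), rnorm(20, 0.15, 0.1)),
    significant = TRUE
  )
  cmp <- population_compare(res, n_perm = 500, seed = 9,
                            by = c("area", "variable"))
  uns <- dplyr::filter(cmp, sign_class == "unsigned")
  swapped <- population_compare(res, conditions = c("control", "drug"),
                                n_perm = 500, seed = 9,
                                by = c("area", "variable"))
  uns2 <- dplyr::filter(swapped, sign_class == "unsigned")
  expect_equal(uns$delta, -uns2$delta)
  expect_equal(uns$permutation_p, uns2$permutation_p)
  small <- dplyr::mutate(res, condition = c(rep("drug", 2),
                                            rep("control", 38)))
  cmp_small <- population_compare(small, n_perm = 100,
                                  by = c("area", "variable"))
  expect_false(any(cmp_small$tested[cmp_small$sign_class == "unsigned"]))
  expect_true(all(is.na(cmp_small$permutation_p[!cmp_small$tested])))
})

test_that("best-variable selection maximises R2 among significant fits", {
  set.seed(74)
  res <- tidyr::expand_grid(
    unit_id = sprintf("u%02d", 1:12),
    variable = c("outcome", "rpe_signed", "chosen_color")
  ) |>
    dplyr::mutate(
      area = "ACC", condition = "drug", epoch = "feedback",
      r2 = runif(dplyr::n()), r = sqrt(r2),
      significant = runif(dplyr::n()) < 0.7
    )
  bv <- best_variable(res)
  for (i in seq_len(nrow(bv))) {
    sub <- dplyr::filter(res, unit_id == bv$unit_id[i], significant)
    expect_equal(bv$r2[i], max(sub$r2))
  }
  expect_true(all(bv$unit_id %in%
                    res$unit_id[res$significant]))
})

test_that("Kendall tau of orderings matches brute-force pair counting", {
  expect_equal(ranking_tau(c("A", "B", "C", "D"), c("A", "B", "C", "D"))$tau, 1)
  expect_equal(ranking_tau(c("A", "B", "C", "D"), c("D", "C", "B", "A"))$tau, -1)
  expect_equal(ranking_tau(c("A", "B", "C", "D"), c("A", "C", "B", "D"))$tau,
               2 / 3, tolerance = 1e-10)
})

test_that("variable rankings and prevalence comparisons count correctly", {
  set.seed(75)
  res <- tidyr::expand_grid(
    unit_id = sprintf("u%03d", 1:60),
    variable = c("outcome", "rpe_signed", "chosen_color")
  ) |>
    dplyr::mutate(
      area = "ACC", epoch = "feedback",
      condition = rep(c("drug", "control"), each = 90),
      r2 = runif(dplyr::n()), r = sqrt(r2) * sign(rnorm(dplyr::n())),
      significant = runif(dplyr::n()) < 0.6
    )
  rk <- rank_variables(res)
  expect_equal(sort(rk$ranking$best_variable),
               sort(c("outcome", "rpe_signed", "chosen_color")))
  expect_true(rk$comparison$tau >= -1 && rk$comparison$tau <= 1)
  prev <- prevalence_compare(res, "outcome")
  expect_equal(prev$n_1, 30)
  ident <- prevalence_compare(
    dplyr::mutate(res, significant = variable == "outcome"), "outcome"
  )
  expect_equal(ident$difference, 0)
  expect_equal(ident$prop_1, 1)
})

test_that("ISI statistics match closed forms", {
  expect_equal(isi_stats(rep(0.01, 100))$cv, 0)
  expect_equal(isi_stats(rep(0.01, 100))$lv, 0)
  expect_equal(isi_stats(c(0.010, 0.030))$lv, 0.75)
  expect_true(is.na(isi_stats(0.01)$cv))
  set.seed(76)
  pois <- isi_stats(rexp(10000, 50))
  expect_lt(abs(pois$cv - 1), 0.05)
  expect_lt(abs(pois$lv - 1), 0.05)
})

test_that("spiking stats pool ISIs within the epoch window", {
  # 3 spikes per trial, 10 ms apart, inside the feedback window
  tr <- flat_trials(5)
  spikes <- lapply(seq_len(5), function(i) 2.85 + c(0, 0.01, 0.02))
  unit <- manual_unit(spikes)
  st <- spiking_stats(unit, tr, "feedback")
  expect_equal(st$cv, 0)
  expect_equal(st$lv, 0)
  expect_equal(st$n_isi, 10L)
  expect_equal(st$mean_rate, 3 / 0.95, tolerance = 1e-10)
})

test_that("noise correlations detect shared gain and not independence", {
  set.seed(77)
  n <- 600
  tr <- flat_trials(n)
  window <- c(2.80, 3.75)
  mk_unit <- function(lam, id) {
    counts <- rpois(n, lam)
    manual_unit(lapply(counts, function(k) runif(k, window[1], window[2])),
                unit_id = id)
  }
  u1 <- mk_unit(rep(8, n), "i1")
  u2 <- mk_unit(rep(8, n), "i2")
  ind <- noise_correlations(list(u1, u2), tr)
  expect_lt(abs(ind$r), 0.1)
  # common multiplicative rate fluctuation (SD 30% of the mean)
  shared <- pmax(rnorm(n, 1, 0.3), 0.1) * 8
  u3 <- mk_unit(shared, "s1")
  u4 <- mk_unit(shared, "s2")
  dep <- noise_correlations(list(u3, u4), tr)
  expect_gt(dep$r, 0.2)
  expect_gt(dep$n_trials, 30)
  # a unit against a copy of itself correlates perfectly
  u5 <- u3
  u5$unit_id <- "s1copy"
  self <- noise_correlations(list(u3, u5), tr)
  expect_equal(self$r, 1)
})
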