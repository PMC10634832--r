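# Ground-truth validation studies: parameter recovery, smoother oracle
# agreement, learning-trial detection, encoding recovery, permutation-test
# calibration and classification recovery. These are the package's
# self-checks on synthetic data with known truth; the test suite and the
# acceptance script run them at their reference sizes.

#' RL parameter-recovery study
#'
#' Simulates sessions under known parameters and refits each by maximum
#' likelihood.
#'
#' @param n_sessions Number of replicate sessions.
#' @param n_blocks Blocks per session.
#' @param truth Generating [agent_params()].
#' @param seed Integer seed.
#' @param n_restarts Optimiser restarts per fit.
#' @return A list: `fits` (per-session tibble of estimates) and `summary`
#'   (median absolute relative error per parameter).
#' @export
validate_rl_recovery <- function(n_sessions = 50, n_blocks = 24,
                                 truth = agent_params(0.2, 6, 0.15),
                                 seed = 1, n_restarts = 10) {
  seed <- as.integer(seed) %% 100000L
  fits <- purrr::map(seq_len(n_sessions), function(i) {
    s <- simulate_session(n_blocks, truth, seed = seed * 1000 + i)
    f <- fit_agent_mle(s$trials, seed = seed * 2000 + i,
                       n_restarts = n_restarts)
    tibble::tibble(
      session = i, n_trials = nrow(s$trials),
      learning_rate = f$params$learning_rate,
      inverse_temperature = f$params$inverse_temperature,
      decay = f$params$decay,
      logLik = f$logLik
    )
  }) |>
    dplyr::bind_rows()
  rel_err <- function(est, tr) median(abs(est - tr) / tr)
  summary <- tibble::tibble(
    parameter = c("learning_rate", "inverse_temperature", "decay"),
    true_value = c(truth$learning_rate, truth$inverse_temperature,
                   truth$decay),
    median_abs_rel_error = c(
      rel_err(fits$learning_rate, truth$learning_rate),
      rel_err(fits$inverse_temperature, truth$inverse_temperature),
      rel_err(fits$decay, truth$decay)
    )
  )
  list(fits = fits, summary = summary)
}

#' Gaussian-smoother versus exact-grid oracle agreement
#'
#' On random chance-level (Bernoulli 0.5) binary sequences, compares the
#' Gaussian-approximation smoothed probability curve with the posterior
#' median of the exact dense-grid smoother run at the same process
#' variance; the median is the monotone-link-invariant location that the
#' Gaussian centre estimates.
#'
#' @param n_sequences Number of random sequences.
#' @param len Sequence length.
#' @param seed Integer seed.
#' @param n_bins Grid bins of the oracle.
#' @return A list with `max_abs_diff` and the per-sequence differences.
#' @export
validate_em_oracle <- function(n_sequences = 100, len = 15, seed = 1,
                               n_bins = 400) {
  diffs <- with_local_seed(seed, {
    vapply(seq_len(n_sequences), function(i) {
      y <- rbinom(len, 1, 0.5)
      est <- em_learning_curve(y)
      g <- em_grid_smoother(y, attr(est, "process_variance"),
                            n_bins = n_bins)
      max(abs(est$p_mode - g$p_median))
    }, 0)
  })
  list(max_abs_diff = max(diffs), diffs = diffs)
}

#' Learning-trial detection on step-change blocks
#'
#' Simulates blocks whose Bernoulli probability of a correct choice jumps
#' from `p0` to `p1` at a known trial `k`, then measures how often the EM
#' learning trial and the windowed criterion learning trial fall within
#' `tolerance` trials of `k`.
#'
#' @param n_blocks Number of simulated blocks.
#' @param n_trials Trials per block.
#' @param k_range Range the true change trial is drawn from.
#' @param p0,p1 Pre/post-change probability correct.
#' @param tolerance Accepted |detected - k| in trials.
#' @param seed Integer seed.
#' @return A list: per-block tibble and summary rates (`em_hit_rate`,
#'   `criterion_hit_rate`, `em_detected_rate`, `em_hit_rate_detected`).
#' @export
validate_learning_detection <- function(n_blocks = 500, n_trials = 40,
                                        k_range = c(8, 20), p0 = 0.5,
                                        p1 = 0.9, tolerance = 5, seed = 1) {
  blocks <- with_local_seed(seed, {
    purrr::map(seq_len(n_blocks), function(i) {
      k <- sample(seq(k_range[1], k_range[2]), 1)
      y <- c(rbinom(k - 1, 1, p0), rbinom(n_trials - k + 1, 1, p1))
      tibble::tibble(
        block = i, k = k,
        em_learning_trial = glance(em_learning_curve(y))$learning_trial,
        criterion_learning_trial = criterion_learning_trial(y)
      )
    }) |>
      dplyr::bind_rows()
  })
  hit <- function(lt) !is.na(lt) & abs(lt - blocks$k) <= tolerance
  em_hit <- hit(blocks$em_learning_trial)
  list(
    blocks = blocks,
    em_hit_rate = mean(em_hit),
    criterion_hit_rate = mean(hit(blocks$criterion_learning_trial)),
    em_detected_rate = mean(!is.na(blocks$em_learning_trial)),
    em_hit_rate_detected =
      mean(em_hit[!is.na(blocks$em_learning_trial)])
  )
}

# Session material (trials, latents, feedback regressors) truncated to
# n_trials, shared by the encoding validations.
encoding_ground_truth <- function(n_trials, agent, seed) {
  s <- simulate_session(ceiling(n_trials / 30) + 2, agent, seed = seed)
  stopifnot(nrow(s$trials) >= n_trials)
  trials <- s$trials[seq_len(n_trials), ]
  latents <- compute_latents(trials, agent)
  regs <- build_regressors(trials, latents, epoch = "feedback")
  list(trials = trials, latents = latents, regressors = regs)
}

#' Encoding-recovery study
#'
#' Generates tuned and untuned Poisson units on a simulated session and
#' checks that the regression battery detects the tuned units (sensitivity),
#' stays near the alpha level on untuned units (false-positive rate), and
#' recovers the sign of the injected gain.
#'
#' @param n_tuned,n_untuned Unit counts.
#' @param n_trials Trials per unit.
#' @param gain Injected log-linear gain on the tuned variable.
#' @param variable Tuned regressor name.
#' @param baseline_rate Baseline rate (Hz).
#' @param agent Generating agent for the behavioral session.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return A list: per-unit results and `sensitivity`,
#'   `false_positive_rate`, `sign_agreement`.
#' @export
validate_encoding_recovery <- function(n_tuned = 50, n_untuned = 150,
                                       n_trials = 400, gain = 0.3,
                                       variable = "rpe_signed",
                                       baseline_rate = 8,
                                       agent = agent_params(0.3, 6, 0.1),
                                       alpha = 0.05, seed = 1) {
  seed <- as.integer(seed) %% 100000L
  gt <- with_local_seed(seed, encoding_ground_truth(n_trials, agent, seed))
  epochs <- default_epochs()["feedback"]
  n_total <- n_tuned + n_untuned
  res <- purrr::map(seq_len(n_total), function(i) {
    tuned <- i <= n_tuned
    us <- unit_spec(
      sprintf("v%03d", i), baseline_rate = baseline_rate,
      tuning = if (tuned) setNames(gain, variable) else numeric(0)
    )
    rec <- generate_spike_trains(us, gt$trials, gt$latents, epochs = epochs,
                                 seed = seed * 10000 + i,
                                 regressors = list(feedback = gt$regressors))
    rates <- epoch_rate(rec, gt$trials, "feedback", epochs)
    fit <- regress_unit(rates$rate, gt$regressors[[variable]],
                        alpha = alpha)
    dplyr::mutate(fit, unit = i, tuned = tuned, .before = 1)
  }) |>
    dplyr::bind_rows()
  tuned <- dplyr::filter(res, .data$tuned)
  untuned <- dplyr::filter(res, !.data$tuned)
  hits <- dplyr::filter(tuned, .data$significant)
  list(
    results = res,
    sensitivity = mean(tuned$significant),
    false_positive_rate = mean(untuned$significant),
    sign_agreement = if (nrow(hits)) mean(sign(hits$r) == sign(gain)) else NA
  )
}

# Per-unit correlation of epoch spike counts with a z-scored regressor,
# simulated at the count level of the log-linear rate model.
simulate_unit_r <- function(n_units, z, gain, baseline_rate, width) {
  vapply(seq_len(n_units), function(i) {
    counts <- rpois(length(z), baseline_rate * exp(gain * z) * width)
    if (var(counts) == 0) 0 else cor(counts, z)
  }, 0)
}

#' Power of the condition permutation comparison
#'
#' Repeatedly simulates a "drug" and a "control" unit population whose
#' encoding gains differ, computes per-unit correlation coefficients, and
#' runs the label-permutation comparison; reports the rejection rate.
#'
#' @param n_repeats Simulation repeats.
#' @param gain_a,gain_b Gains of the two populations.
#' @param n_per_group Units per group.
#' @param n_trials Trials per unit.
#' @param baseline_rate Baseline rate (Hz).
#' @param n_perm Permutations per comparison.
#' @param alpha Rejection level.
#' @param seed Integer seed.
#' @return A list with `power` and the per-repeat p values.
#' @export
validate_permutation_power <- function(n_repeats = 200, gain_a = 0.4,
                                       gain_b = 0.2, n_per_group = 30,
                                       n_trials = 400, baseline_rate = 8,
                                       n_perm = 1000, alpha = 0.05,
                                       seed = 1) {
  with_local_seed(seed, {
    z <- scale(rnorm(n_trials))[, 1]
    width <- 0.95
    p_values <- vapply(seq_len(n_repeats), function(i) {
      r_a <- simulate_unit_r(n_per_group, z, gain_a, baseline_rate, width)
      r_b <- simulate_unit_r(n_per_group, z, gain_b, baseline_rate, width)
      res <- tibble::tibble(
        unit_id = sprintf("u%03d", seq_len(2 * n_per_group)),
        area = "ACC", variable = "rpe_signed",
        condition = rep(c("drug", "control"), each = n_per_group),
        r = c(r_a, r_b), significant = TRUE
      )
      cmp <- population_compare(res, n_perm = n_perm,
                                by = c("area", "variable"))
      cmp$permutation_p[cmp$sign_class == "unsigned"]
    }, 0)
    list(power = mean(p_values < alpha), p_values = p_values)
  })
}

#' Type-I error of the condition permutation comparison
#'
#' Both groups are drawn from the same distribution of correlation
#' coefficients; reports the rejection rate at `alpha`.
#'
#' @param n_repeats Simulation repeats.
#' @param n_per_group Units per group.
#' @param n_perm Permutations per comparison.
#' @param alpha Rejection level.
#' @param seed Integer seed.
#' @return A list with `type1_rate` and the per-repeat p values.
#' @export
validate_permutation_calibration <- function(n_repeats = 500,
                                             n_per_group = 30,
                                             n_perm = 1000, alpha = 0.05,
                                             seed = 1) {
  with_local_seed(seed, {
    p_values <- vapply(seq_len(n_repeats), function(i) {
      res <- tibble::tibble(
        unit_id = sprintf("u%03d", seq_len(2 * n_per_group)),
        area = "ACC", variable = "outcome",
        condition = rep(c("drug", "control"), each = n_per_group),
        r = rnorm(2 * n_per_group, 0.15, 0.08), significant = TRUE
      )
      cmp <- population_compare(res, n_perm = n_perm,
                                by = c("area", "variable"))
      cmp$permutation_p[cmp$sign_class == "unsigned"]
    }, 0)
    list(type1_rate = mean(p_values < alpha), p_values = p_values)
  })
}

#' Waveform classification recovery
#'
#' Generates a two-class waveform population at the default class
#' separation and scores the NS/BS classifier against the ground truth.
#'
#' @param n_units Population size.
#' @param scheme `"cortical"` or `"striatal"`.
#' @param prop_ns True NS fraction.
#' @param seed Integer seed.
#' @return A list: `accuracy`, `ns_fraction_error`, `silhouette`.
#' @export
validate_classification <- function(n_units = 200, scheme = "cortical",
                                    prop_ns = 0.3, seed = 1) {
  wf <- generate_waveforms(default_waveform_classes(scheme, prop_ns),
                           n_units = n_units, seed = seed)
  cl <- classify_units(measure_waveforms(wf), scheme, seed = seed)
  list(
    accuracy = mean(cl$label == cl$true_class),
    ns_fraction_error = abs(mean(cl$label == "NS") - prop_ns),
    silhouette = attr(cl, "silhouette")
  )
}
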