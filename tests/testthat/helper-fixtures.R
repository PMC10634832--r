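# Shared fixtures, built once per test run.

fixture_agent <- function() agent_params(0.3, 6, 0.1)

# Small simulated session cached across tests.
fixture_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_session(8, fixture_agent(), seed = 101,
                                 session_id = "fix", condition = "control")
    }
    cache
  }
})

fixture_latents <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- fixture_session()
      cache <<- compute_latents(s$trials, fixture_agent())
    }
    cache
  }
})

# Minimal flat trial table with fixed event times, for spike-train tests
# that do not need task structure.
flat_trials <- function(n, outcome = rep(1L, n), seed = NULL) {
  with_seed <- function(code) {
    if (is.null(seed)) return(code)
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  with_seed(tibble::tibble(
    session_id = "flat", condition = "control", block_index = 1L,
    trial_in_block = seq_len(n), rewarded_color = "c1",
    stim_A_color = "c1", stim_A_motion = "up", stim_A_location = "left",
    stim_B_color = "c2", stim_B_motion = "down", stim_B_location = "right",
    chosen_stim = ifelse(outcome == 1, "A", "B"), outcome = outcome,
    t_fixation_on = 0, t_color_on = 1, t_motion_on = 1.7, t_dimming = 2.4,
    t_saccade = 2.7, t_feedback = 2.75
  ))
}

# Flat latents matching flat_trials (values at chance, rpe = outcome - 0.5).
flat_latents <- function(trials) {
  tibble::tibble(
    v_chosen = 0.5, v_unchosen = 0.5, p_choice = 0.5,
    rpe = trials$outcome - 0.5,
    rpe_pos = pmax(trials$outcome - 0.5, 0),
    rpe_neg = pmin(trials$outcome - 0.5, 0),
    learning_phase = NA_integer_
  )
}

# Hand-built unit recording from per-trial spike-time lists.
manual_unit <- function(spike_list, unit_id = "m1", area = "ACC",
                        condition = "control") {
  idx <- rep.int(seq_along(spike_list), lengths(spike_list))
  structure(
    list(unit_id = unit_id, area = area, condition = condition,
         true_class = "BS",
         spikes = tibble::tibble(trial_index = idx,
                                 spike_time_s = unlist(spike_list)),
         n_trials = length(spike_list), waveform = NULL),
    class = "unit_recording"
  )
}

# Step-change outcome sequence: Bernoulli 0.5 before trial k, 0.9 after.
step_block <- function(k, n = 40, p0 = 0.5, p1 = 0.9) {
  c(rbinom(k - 1, 1, p0), rbinom(n - k + 1, 1, p1))
}
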