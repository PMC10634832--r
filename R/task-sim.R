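# Simulation of the two-stimulus feature-based colour-reversal task.
#
# Each trial shows two peripheral grating stimuli that always carry opposite
# feature levels on three dimensions (colour, motion direction, location).
# Only colour predicts reward; the rewarded colour reverses without cue at
# block boundaries.

.fs_colors <- c("c1", "c2")
.fs_motions <- c("up", "down")
.fs_locations <- c("left", "right")
.fs_levels <- c(.fs_colors, .fs_motions, .fs_locations)

#' Block-structure specification
#'
#' Rules governing when the rewarded colour reverses. A block runs for at
#' least `min_trials` trials and ends once performance over the preceding
#' `switch_window` trials reaches `switch_criterion`; a hard cap of
#' `max_trials` bounds blocks for non-learning agents.
#'
#' @param min_trials Minimum block length in trials.
#' @param switch_criterion Proportion correct over the trailing window that
#'   triggers a reversal.
#' @param switch_window Number of trailing trials the criterion is computed
#'   over.
#' @param max_trials Hard upper bound on block length.
#' @return A list of class `block_spec`.
#' @examples
#' spec <- block_spec()
#' check_block_switch(rep(1, 30), spec)
#' @export
block_spec <- function(min_trials = 30, switch_criterion = 0.90,
                       switch_window = 12, max_trials = 80) {
  stopifnot(
    min_trials >= 1, max_trials >= min_trials,
    switch_criterion > 0, switch_criterion <= 1,
    switch_window >= 1, switch_window <= min_trials
  )
  structure(
    list(
      min_trials = as.integer(min_trials),
      switch_criterion = switch_criterion,
      switch_window = as.integer(switch_window),
      max_trials = as.integer(max_trials)
    ),
    class = "block_spec"
  )
}

#' Should the rewarded colour reverse after these outcomes?
#'
#' @param outcomes Integer/logical vector of block-so-far outcomes
#'   (1 = correct, 0 = error), oldest first.
#' @param spec A [block_spec()].
#' @return `TRUE` if the block ends after the last outcome in `outcomes`.
#' @export
check_block_switch <- function(outcomes, spec = block_spec()) {
  if (length(outcomes) == 0) {
    stop("`outcomes` must contain at least one trial", call. = FALSE)
  }
  stopifnot(all(outcomes %in% c(0, 1)))
  n <- length(outcomes)
  if (n >= spec$max_trials) {
    return(TRUE)
  }
  if (n < spec$min_trials) {
    return(FALSE)
  }
  window <- tail(outcomes, spec$switch_window)
  mean(window) >= spec$switch_criterion
}

# Draw n mutually-opposite stimulus pairs; uniform over the 8 configurations
# of stimulus A. Returns a tibble with stim_A_* / stim_B_* columns.
draw_stimulus_pairs <- function(n) {
  a_color <- sample(.fs_colors, n, replace = TRUE)
  a_motion <- sample(.fs_motions, n, replace = TRUE)
  a_location <- sample(.fs_locations, n, replace = TRUE)
  opposite <- function(x, levels) ifelse(x == levels[1], levels[2], levels[1])
  tibble::tibble(
    stim_A_color = a_color,
    stim_A_motion = a_motion,
    stim_A_location = a_location,
    stim_B_color = opposite(a_color, .fs_colors),
    stim_B_motion = opposite(a_motion, .fs_motions),
    stim_B_location = opposite(a_location, .fs_locations)
  )
}

#' Draw one pair of mutually opposite stimuli
#'
#' The two stimuli carry opposite levels on every dimension; the assignment
#' of levels to stimulus A is uniform over the eight valid configurations.
#'
#' @param rng_seed Optional integer seed; when given, the draw is
#'   reproducible and the caller's RNG state is left untouched.
#' @return A one-row tibble with `stim_A_*` and `stim_B_*` columns.
#' @examples
#' make_trial_stimuli(rng_seed = 1)
#' @export
make_trial_stimuli <- function(rng_seed = NULL) {
  with_local_seed(rng_seed, draw_stimulus_pairs(1L))
}

# Run `code` under `seed` without disturbing the caller's RNG stream.
# A NULL seed runs the code on the ambient stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Event times (s from trial start), matching the task's printed ranges:
# fixation 0.5-0.9 s, 0.4 s to first feature onset, 0.5-0.9 s to the second,
# 0.4-1 s to dimming, saccade within 0.55 s of the go cue. Times are rounded
# to microseconds so tables round-trip exactly through TSV.
draw_event_times <- function(n) {
  fixation_on <- rep(0, n)
  color_on <- runif(n, 0.5, 0.9) + 0.4
  motion_on <- color_on + runif(n, 0.5, 0.9)
  dimming <- motion_on + runif(n, 0.4, 1.0)
  saccade <- dimming + runif(n, 0.15, 0.55)
  feedback <- saccade + 0.05
  tibble::tibble(
    t_fixation_on = fixation_on,
    t_color_on = round(color_on, 6),
    t_motion_on = round(motion_on, 6),
    t_dimming = round(dimming, 6),
    t_saccade = round(saccade, 6),
    t_feedback = round(feedback, 6)
  )
}

#' Simulate a session of the reversal task with an RL agent
#'
#' Drives a feature-value reinforcement-learning agent (see
#' [agent_params()]) through `n_blocks` colour-reversal blocks. The rewarded
#' colour alternates across blocks; block lengths follow
#' [check_block_switch()]. Feature values are initialised at the start of the
#' session and persist across reversals within it, so the agent must unlearn
#' the stale colour-value association after each reversal.
#'
#' @param n_blocks Number of reversal blocks (>= 1).
#' @param agent An [agent_params()] object.
#' @param spec A [block_spec()].
#' @param seed Integer seed; every random element of the session is derived
#'   from it.
#' @param session_id Session identifier stored in the trial table.
#' @param condition Session-level condition label (e.g. `"drug"` or
#'   `"control"`).
#' @return A list with elements `trials` (one row per trial: block structure,
#'   stimulus features, rewarded colour, choice, outcome, event times) and
#'   `latents` (row-aligned model variables: chosen/unchosen value, choice
#'   probability, signed/positive/negative reward prediction error).
#' @examples
#' sess <- simulate_session(2, agent_params(0.3, 6, 0.1), seed = 1)
#' head(sess$trials)
#' @export
simulate_session <- function(n_blocks, agent = agent_params(),
                             spec = block_spec(), seed = NULL,
                             session_id = "S1", condition = "control") {
  stopifnot(n_blocks >= 1)
  validate_agent_params(agent)
  with_local_seed(seed, {
    values <- init_feature_values(agent)
    first_color <- sample(.fs_colors, 1)
    blocks <- vector("list", n_blocks)
    lat <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      rewarded <- .fs_colors[1 + (match(first_color, .fs_colors) + b) %% 2]
      stim <- draw_stimulus_pairs(spec$max_trials)
      outcomes <- integer(0)
      rows <- vector("list", spec$max_trials)
      lrows <- vector("list", spec$max_trials)
      t <- 0L
      repeat {
        t <- t + 1L
        s <- stim[t, ]
        va <- object_value_(values, stimulus_levels(s, "A"), agent$weights)
        vb <- object_value_(values, stimulus_levels(s, "B"), agent$weights)
        p_a <- choice_probability(va, vb, agent$inverse_temperature)
        choose_a <- runif(1) < p_a
        chosen <- if (choose_a) "A" else "B"
        chosen_levels <- stimulus_levels(s, chosen)
        unchosen_levels <- stimulus_levels(s, if (choose_a) "B" else "A")
        outcome <- as.integer(s[[paste0("stim_", chosen, "_color")]] == rewarded)
        v_chosen <- if (choose_a) va else vb
        v_unchosen <- if (choose_a) vb else va
        upd <- update_values_(values, chosen_levels, unchosen_levels,
                              outcome, agent)
        values <- upd$values
        rows[[t]] <- list(chosen_stim = chosen, outcome = outcome)
        lrows[[t]] <- list(
          v_chosen = v_chosen, v_unchosen = v_unchosen,
          p_choice = if (choose_a) p_a else 1 - p_a,
          rpe = upd$delta
        )
        outcomes <- c(outcomes, outcome)
        if (check_block_switch(outcomes, spec)) break
      }
      n_t <- t
      blocks[[b]] <- dplyr::bind_cols(
        tibble::tibble(
          session_id = session_id,
          condition = condition,
          block_index = b,
          trial_in_block = seq_len(n_t),
          rewarded_color = rewarded
        ),
        stim[seq_len(n_t), ],
        tibble::tibble(
          chosen_stim = vapply(rows[seq_len(n_t)], `[[`, "", "chosen_stim"),
          outcome = vapply(rows[seq_len(n_t)], `[[`, 0L, "outcome")
        ),
        draw_event_times(n_t)
      )
      lat[[b]] <- tibble::tibble(
        v_chosen = vapply(lrows[seq_len(n_t)], `[[`, 0, "v_chosen"),
        v_unchosen = vapply(lrows[seq_len(n_t)], `[[`, 0, "v_unchosen"),
        p_choice = vapply(lrows[seq_len(n_t)], `[[`, 0, "p_choice"),
        rpe = vapply(lrows[seq_len(n_t)], `[[`, 0, "rpe")
      )
    }
    trials <- dplyr::bind_rows(blocks)
    latents <- dplyr::bind_rows(lat) |>
      dplyr::mutate(
        rpe_pos = pmax(.data$rpe, 0),
        rpe_neg = pmin(.data$rpe, 0),
        learning_phase = NA_integer_
      )
    list(trials = trials, latents = latents)
  })
}

# Feature levels (names into the 6-element value vector) of stimulus A/B in
# a one-row stimulus tibble.
stimulus_levels <- function(stim_row, which = c("A", "B")) {
  which <- match.arg(which)
  c(
    stim_row[[paste0("stim_", which, "_color")]],
    stim_row[[paste0("stim_", which, "_motion")]],
    stim_row[[paste0("stim_", which, "_location")]]
  )
}
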