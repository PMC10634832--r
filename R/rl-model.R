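# Feature-value reinforcement-learning model.
#
# Each object's value is a weighted combination of the values of its three
# feature levels; choices arise from a softmax over the two object values; a
# reward prediction error (outcome minus chosen-object value), scaled by the
# learning rate, updates the chosen object's feature values while the
# unchosen object's feature values decay back toward their initial value.

#' Parameters of the feature-value RL agent
#'
#' @param learning_rate Learning rate in (0, 1]; scales the reward
#'   prediction error applied to the chosen stimulus' feature values.
#' @param inverse_temperature Softmax inverse temperature (>= 0); 0 yields
#'   random choice.
#' @param decay Decay rate in \[0, 1\]; per trial, unchosen-stimulus feature
#'   values relax by this fraction toward `initial_value`.
#' @param initial_value Initial (and decay-target) feature value; 0.5 anchors
#'   values at chance reward expectation.
#' @param weights Nonnegative weights over the colour, motion and location
#'   dimensions; normalised to sum to 1.
#' @return A list of class `agent_params`.
#' @examples
#' agent_params(learning_rate = 0.3, inverse_temperature = 6, decay = 0.1)
#' @export
agent_params <- function(learning_rate = 0.3, inverse_temperature = 5,
                         decay = 0.1, initial_value = 0.5,
                         weights = c(1, 1, 1) / 3) {
  p <- structure(
    list(
      learning_rate = learning_rate,
      inverse_temperature = inverse_temperature,
      decay = decay,
      initial_value = initial_value,
      weights = weights / sum(weights)
    ),
    class = "agent_params"
  )
  validate_agent_params(p)
  p
}

validate_agent_params <- function(p) {
  ok <- is.list(p) &&
    all(vapply(p[c("learning_rate", "inverse_temperature", "decay",
                   "initial_value")], is.numeric, TRUE)) &&
    all(is.finite(unlist(p[c("learning_rate", "inverse_temperature",
                             "decay", "initial_value")]))) &&
    length(p$weights) == 3 && all(is.finite(p$weights))
  if (!ok) {
    stop("agent parameters must be finite numerics with 3 weights",
         call. = FALSE)
  }
  stopifnot(
    p$learning_rate > 0, p$learning_rate <= 1,
    p$inverse_temperature >= 0,
    p$decay >= 0, p$decay <= 1,
    all(p$weights >= 0)
  )
  if (abs(sum(p$weights) - 1) > 1e-8) {
    stop("dimension weights must sum to 1", call. = FALSE)
  }
  invisible(p)
}

init_feature_values <- function(agent) {
  setNames(rep(agent$initial_value, 6), .fs_levels)
}

# Weighted object value for a set of 3 feature levels (named into `values`).
object_value_ <- function(values, levels, weights) {
  sum(weights * values[levels])
}

#' Value of a stimulus under the feature-value model
#'
#' @param values Named numeric vector of the six feature-level values
#'   (`c1, c2, up, down, left, right`).
#' @param stim Character vector of the stimulus' three feature levels, e.g.
#'   `c("c1", "up", "left")`.
#' @param weights Dimension weights (colour, motion, location) summing to 1.
#' @return The weighted combination of the stimulus' feature values.
#' @examples
#' v <- setNames(rep(0.5, 6), c("c1", "c2", "up", "down", "left", "right"))
#' object_value(v, c("c1", "up", "left"))
#' @export
object_value <- function(values, stim, weights = c(1, 1, 1) / 3) {
  stopifnot(length(stim) == 3, all(stim %in% names(values)),
            all(is.finite(values)))
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("dimension weights must sum to 1", call. = FALSE)
  }
  object_value_(values, stim, weights)
}

#' Softmax probability of choosing stimulus A
#'
#' Numerically stable for arbitrarily large `beta`.
#'
#' @param v_a,v_b Object values of the two stimuli.
#' @param beta Inverse temperature (>= 0).
#' @return P(choose A) = exp(beta v_a) / (exp(beta v_a) + exp(beta v_b)).
#' @examples
#' choice_probability(1, 0, log(3)) # 0.75
#' @export
choice_probability <- function(v_a, v_b, beta) {
  stopifnot(beta >= 0)
  plogis(beta * (v_a - v_b))
}

# One learning step. Returns the updated value vector and the RPE.
update_values_ <- function(values, chosen_levels, unchosen_levels, outcome,
                           agent) {
  delta <- outcome - object_value_(values, chosen_levels, agent$weights)
  values[chosen_levels] <- values[chosen_levels] + agent$learning_rate * delta
  values[unchosen_levels] <- values[unchosen_levels] +
    agent$decay * (agent$initial_value - values[unchosen_levels])
  list(values = values, delta = delta)
}

#' Apply one feature-value update
#'
#' @inheritParams object_value
#' @param chosen,unchosen Feature levels (length-3 character) of the chosen
#'   and unchosen stimulus.
#' @param outcome 1 (rewarded) or 0 (error).
#' @param params An [agent_params()] object.
#' @return A list with `values` (updated vector) and `delta` (the signed
#'   reward prediction error).
#' @export
update_values <- function(values, chosen, unchosen, outcome,
                          params = agent_params()) {
  stopifnot(outcome %in% c(0, 1), all(c(chosen, unchosen) %in% names(values)))
  validate_agent_params(params)
  update_values_(values, chosen, unchosen, outcome, params)
}

# 0-based indices of the chosen/unchosen feature levels per trial, for the
# compiled likelihood and the R replay.
trial_level_indices <- function(trials) {
  need <- c("chosen_stim", "outcome", "session_id",
            paste0("stim_A_", c("color", "motion", "location")),
            paste0("stim_B_", c("color", "motion", "location")))
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("trial table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  a <- cbind(
    match(trials$stim_A_color, .fs_levels),
    match(trials$stim_A_motion, .fs_levels),
    match(trials$stim_A_location, .fs_levels)
  )
  b <- cbind(
    match(trials$stim_B_color, .fs_levels),
    match(trials$stim_B_motion, .fs_levels),
    match(trials$stim_B_location, .fs_levels)
  )
  chose_a <- trials$chosen_stim == "A"
  chosen <- ifelse(matrix(chose_a, nrow(trials), 3), a, b)
  unchosen <- ifelse(matrix(chose_a, nrow(trials), 3), b, a)
  new_session <- c(TRUE, trials$session_id[-1] != trials$session_id[-nrow(trials)])
  list(chosen = chosen - 1L, unchosen = unchosen - 1L,
       outcome = as.integer(trials$outcome), new_session = new_session)
}

#' Replay trials through the model and extract latent variables
#'
#' Recomputes, deterministically, the per-trial model variables for an
#' observed (or simulated) trial table under given parameters: chosen and
#' unchosen object values, softmax probability of the made choice, and the
#' signed / positive / negative reward prediction error. Feature values reset
#' to `params$initial_value` at each session boundary and persist across
#' block reversals within a session.
#'
#' @param trials A trial table as produced by [simulate_session()] or
#'   [read_trials()].
#' @param params An [agent_params()] object.
#' @param learning_trials Optional tibble (`session_id`, `block_index`,
#'   `learning_trial`) used to fill `learning_phase` (0 before the
#'   statistically defined learning trial, 1 from it onward). When `NULL`,
#'   learning trials are estimated per block with [em_learning_curve()].
#' @return A tibble aligned row-for-row with `trials`: `v_chosen`,
#'   `v_unchosen`, `p_choice`, `rpe`, `rpe_pos`, `rpe_neg`,
#'   `learning_phase`.
#' @export
compute_latents <- function(trials, params = agent_params(),
                            learning_trials = NULL) {
  validate_agent_params(params)
  idx <- trial_level_indices(trials)
  n <- nrow(trials)
  v_chosen <- v_unchosen <- p_choice <- rpe <- numeric(n)
  values <- init_feature_values(params)
  w <- params$weights
  for (t in seq_len(n)) {
    if (idx$new_session[t]) values <- init_feature_values(params)
    ch <- .fs_levels[idx$chosen[t, ] + 1L]
    un <- .fs_levels[idx$unchosen[t, ] + 1L]
    vc <- object_value_(values, ch, w)
    vu <- object_value_(values, un, w)
    v_chosen[t] <- vc
    v_unchosen[t] <- vu
    p_choice[t] <- choice_probability(vc, vu, params$inverse_temperature)
    upd <- update_values_(values, ch, un, idx$outcome[t], params)
    values <- upd$values
    rpe[t] <- upd$delta
  }
  if (is.null(learning_trials)) {
    learning_trials <- estimate_learning_trials(trials)
  }
  phase <- trials |>
    dplyr::select("session_id", "block_index", "trial_in_block") |>
    dplyr::left_join(learning_trials, by = c("session_id", "block_index")) |>
    dplyr::mutate(
      learning_phase = dplyr::case_when(
        is.na(.data$learning_trial) ~ 0L,
        .data$trial_in_block >= .data$learning_trial ~ 1L,
        TRUE ~ 0L
      )
    )
  tibble::tibble(
    v_chosen = v_chosen, v_unchosen = v_unchosen, p_choice = p_choice,
    rpe = rpe, rpe_pos = pmax(rpe, 0), rpe_neg = pmin(rpe, 0),
    learning_phase = phase$learning_phase
  )
}

#' Fit the feature-value RL model by maximum likelihood
#'
#' Maximises the summed log softmax probability of the observed choices over
#' (learning rate, inverse temperature, decay) with bounded multi-start
#' local optimisation (`L-BFGS-B`); the dimension weights and initial value
#' are held fixed. Restart ties are broken by the first-found maximum.
#'
#' @param trials Trial table (>= 100 trials recommended).
#' @param lower,upper Parameter bounds, ordered (learning_rate,
#'   inverse_temperature, decay).
#' @param n_restarts Number of optimiser starts (the first is a fixed
#'   central start, the rest uniform draws within the bounds).
#' @param seed Integer seed controlling the restart draws.
#' @param weights,initial_value Fixed model constants (see
#'   [agent_params()]).
#' @return An object of class `rl_fit`; see [tidy.rl_fit()] and
#'   [glance.rl_fit()].
#' @examples
#' \donttest{
#' sess <- simulate_session(6, agent_params(0.25, 6, 0.1), seed = 2)
#' fit <- fit_agent_mle(sess$trials, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_agent_mle <- function(trials, lower = c(1e-3, 0, 0),
                          upper = c(1, 50, 1), n_restarts = 10, seed = NULL,
                          weights = c(1, 1, 1) / 3, initial_value = 0.5) {
  stopifnot(length(lower) == 3, length(upper) == 3, all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower), n_restarts >= 1)
  idx <- trial_level_indices(trials)
  w <- weights / sum(weights)
  negll <- function(par) {
    rl_negloglik_cpp(idx$chosen, idx$unchosen, idx$outcome, idx$new_session,
                     w, par[1], par[2], par[3], initial_value)
  }
  with_local_seed(seed, {
    starts <- rbind(
      c(0.3, 5, 0.1),
      cbind(
        runif(n_restarts - 1, lower[1], upper[1]),
        runif(n_restarts - 1, lower[2], min(upper[2], 12)),
        runif(n_restarts - 1, lower[3], upper[3])
      )
    )[seq_len(n_restarts), , drop = FALSE]
    fits <- apply(starts, 1, function(s) {
      optim(s, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300))
    })
    nll <- vapply(fits, `[[`, 0, "value")
    best <- fits[[which.min(nll)]]
    on_boundary <- any(abs(best$par - lower) < 1e-6) ||
      any(abs(best$par - upper) < 1e-6)
    structure(
      list(
        params = agent_params(
          learning_rate = best$par[1],
          inverse_temperature = best$par[2],
          decay = best$par[3],
          initial_value = initial_value,
          weights = w
        ),
        logLik = -best$value,
        n_trials = nrow(trials),
        n_restarts = n_restarts,
        converged = best$convergence == 0,
        boundary = on_boundary,
        restart_logLik = -nll
      ),
      class = "rl_fit"
    )
  })
}

#' Log-likelihood of a trial table under fixed parameters
#'
#' @inheritParams compute_latents
#' @return The summed log probability of the observed choices.
#' @export
agent_log_likelihood <- function(trials, params) {
  validate_agent_params(params)
  idx <- trial_level_indices(trials)
  -rl_negloglik_cpp(idx$chosen, idx$unchosen, idx$outcome, idx$new_session,
                    params$weights, params$learning_rate,
                    params$inverse_temperature, params$decay,
                    params$initial_value)
}

#' @export
print.rl_fit <- function(x, ...) {
  cat("Feature-value RL model fit\n")
  cat(sprintf("  learning_rate = %.4f, inverse_temperature = %.3f, decay = %.4f\n",
              x$params$learning_rate, x$params$inverse_temperature,
              x$params$decay))
  cat(sprintf("  logLik = %.2f on %d trials (%d restarts%s)\n",
              x$logLik, x$n_trials, x$n_restarts,
              if (x$boundary) ", boundary estimate" else ""))
  invisible(x)
}
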