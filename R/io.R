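# Trial-table and configuration I/O (plain TSV / YAML).

.trial_columns <- c(
  "session_id", "condition", "block_index", "trial_in_block",
  "rewarded_color",
  "stim_A_color", "stim_A_motion", "stim_A_location",
  "stim_B_color", "stim_B_motion", "stim_B_location",
  "chosen_stim", "outcome",
  "t_fixation_on", "t_color_on", "t_motion_on", "t_dimming", "t_saccade",
  "t_feedback"
)

validate_trials <- function(trials) {
  missing <- setdiff(.trial_columns, names(trials))
  if (length(missing)) {
    stop("trial table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(trials) == 0) {
    return(invisible(trials))
  }
  if (!all(trials$outcome %in% c(0, 1))) {
    stop("column `outcome` must be 0/1", call. = FALSE)
  }
  if (!all(trials$chosen_stim %in% c("A", "B"))) {
    stop("column `chosen_stim` must be 'A' or 'B'", call. = FALSE)
  }
  if (!all(trials$rewarded_color %in% .fs_colors)) {
    stop("column `rewarded_color` must be one of ",
         paste(.fs_colors, collapse = "/"), call. = FALSE)
  }
  invisible(trials)
}

#' Read / write a trial table
#'
#' Tab-separated text with a header row, one row per trial, times in
#' seconds with microsecond precision. Writing then reading reproduces the
#' table exactly.
#'
#' @param trials A trial table ([simulate_session()]).
#' @param path File path.
#' @return `read_trials()` returns a validated tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  out <- trials |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("t_"),
                                ~ round(.x, 6))) |>
    dplyr::select(dplyr::all_of(.trial_columns))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- readr::read_tsv(
    path,
    col_types = readr::cols(
      session_id = readr::col_character(),
      condition = readr::col_character(),
      block_index = readr::col_integer(),
      trial_in_block = readr::col_integer(),
      rewarded_color = readr::col_character(),
      stim_A_color = readr::col_character(),
      stim_A_motion = readr::col_character(),
      stim_A_location = readr::col_character(),
      stim_B_color = readr::col_character(),
      stim_B_motion = readr::col_character(),
      stim_B_location = readr::col_character(),
      chosen_stim = readr::col_character(),
      outcome = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  validate_trials(trials)
  trials
}

#' Read / write a run configuration
#'
#' YAML key/value files holding the block specification, agent parameters,
#' unit-population settings, epoch and statistical settings, and seeds (see
#' [default_config()]).
#'
#' @param config A configuration list.
#' @param path File path.
#' @return `read_config()` returns the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Default demonstration configuration
#'
#' A small, fully seeded run: two sessions (one drug, one control), a
#' modest synthetic unit population, and reduced permutation counts so the
#' whole report completes quickly.
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A configuration list for [run_report()].
#' @export
default_config <- function(seed = 42) {
  list(
    seed = seed,
    sessions = list(n_per_condition = 1, n_blocks = 8),
    block_spec = list(min_trials = 30, switch_criterion = 0.9,
                      switch_window = 12, max_trials = 80),
    agent = list(learning_rate = 0.3, inverse_temperature = 6, decay = 0.1,
                 initial_value = 0.5),
    units = list(n_per_condition = 9, baseline_rate = 8,
                 tuned_fraction = 0.3, tuning_variable = "rpe_signed",
                 gain_drug = 0.4, gain_control = 0.2,
                 scheme = "cortical", prop_ns = 0.3),
    stats = list(alpha = 0.05, n_perm = 200, min_trials = 30, min_units = 3),
    epoch = "feedback"
  )
}
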