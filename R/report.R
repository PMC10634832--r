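# End-to-end report: simulate -> fit -> learning state -> behavior metrics
# -> synthetic neurons -> classify -> encode -> compare, all driven by a
# seeded configuration.

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

# Deterministic per-stage seeds derived from the master seed.
derive_seeds <- function(seed) {
  base <- as.integer(seed) %% 100000L
  list(
    sessions = base + 1L,
    units = base + 2L,
    waveforms = base + 3L,
    spikes = base + 4L,
    fit = base + 5L,
    compare = base + 6L,
    classify = base + 7L
  )
}

#' Run the full pipeline and write a report directory
#'
#' Executes every stage of the pipeline on simulated ground truth: task and
#' agent simulation per condition, RL model fitting, EM learning-state
#' estimation, behavioral metrics, synthetic unit generation, waveform
#' classification, the encoding battery, and the condition comparisons.
#' All tabular outputs are TSV; figures are PNG; a YAML manifest records
#' the configuration, derived seeds and package version so the run can be
#' replayed exactly.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the path to the report directory.
#' @export
run_report <- function(config = default_config(), out_dir = tempfile("report_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed)
  conditions <- c("drug", "control")
  spec <- do.call(block_spec, config$block_spec)
  agent <- do.call(agent_params, config$agent)

  stage_msg("simulate", "simulating %d session(s) per condition",
            config$sessions$n_per_condition)
  sessions <- list()
  k <- 0L
  for (cond in conditions) {
    for (i in seq_len(config$sessions$n_per_condition)) {
      k <- k + 1L
      sessions[[k]] <- simulate_session(
        config$sessions$n_blocks, agent, spec,
        seed = seeds$sessions + k,
        session_id = sprintf("%s_%02d", cond, i), condition = cond
      )
    }
  }
  trials <- dplyr::bind_rows(lapply(sessions, `[[`, "trials"))
  write_trials(trials, file.path(out_dir, "trials.tsv"))

  stage_msg("learning-state", "estimating per-block learning trials")
  summaries <- block_summaries(trials)
  readr::write_tsv(summaries, file.path(out_dir, "block_summaries.tsv"))
  learning_trials <- dplyr::select(summaries, "session_id", "block_index",
                                   learning_trial = "em_learning_trial")

  stage_msg("fit-rl", "fitting the RL model per condition")
  fits <- purrr::map(setNames(conditions, conditions), function(cond) {
    fit_agent_mle(dplyr::filter(trials, .data$condition == cond),
                  seed = seeds$fit)
  })
  fit_tbl <- purrr::imap(fits, function(f, cond) {
    dplyr::mutate(
      dplyr::bind_cols(tidyr::pivot_wider(tidy(f), names_from = "term",
                                          values_from = "estimate"),
                       glance(f)),
      condition = cond, .before = 1
    )
  }) |>
    dplyr::bind_rows()
  readr::write_tsv(fit_tbl, file.path(out_dir, "rl_fits.tsv"))

  latents <- compute_latents(trials, agent, learning_trials)
  readr::write_tsv(dplyr::bind_cols(
    dplyr::select(trials, "session_id", "block_index", "trial_in_block"),
    latents
  ), file.path(out_dir, "latents.tsv"))

  stage_msg("behavior", "learning curves and post-outcome accuracy")
  curves <- purrr::map(setNames(conditions, conditions), function(cond) {
    average_learning_curve(dplyr::filter(trials, .data$condition == cond))
  })
  readr::write_tsv(dplyr::bind_rows(curves, .id = "condition"),
                   file.path(out_dir, "learning_curves.tsv"))
  ecn <- purrr::map(setNames(conditions, conditions), function(cond) {
    tr <- dplyr::filter(trials, .data$condition == cond)
    dplyr::bind_rows(
      error_early = post_outcome_accuracy(tr, anchor = "error",
                                          phase = "early"),
      correct_early = post_outcome_accuracy(tr, anchor = "correct",
                                            phase = "early"),
      first_error = post_outcome_accuracy(tr, anchor = "first_error"),
      .id = "analysis"
    )
  }) |>
    dplyr::bind_rows(.id = "condition")
  readr::write_tsv(ecn, file.path(out_dir, "post_outcome_accuracy.tsv"))
  behavior_test <- rank_sum_compare(
    dplyr::filter(summaries, !is.na(.data$criterion_learning_trial)),
    "criterion_learning_trial"
  )
  readr::write_tsv(behavior_test,
                   file.path(out_dir, "behavior_comparison.tsv"))
  ggplot2::ggsave(file.path(out_dir, "learning_curves.png"),
                  plot_learning_curves(curves), width = 6, height = 4,
                  dpi = 150)

  n_units <- config$units$n_per_condition
  if (is.null(n_units) || n_units == 0) {
    stage_msg("neurons", "no units configured; neural stages skipped")
    write_manifest(config, seeds, out_dir)
    return(invisible(out_dir))
  }

  stage_msg("neurons", "generating %d unit(s) per condition", n_units)
  areas <- c("dlPFC", "ACC", "striatum")
  epoch <- config$epoch
  unit_rows <- list()
  results <- list()
  u <- 0L
  for (cond in conditions) {
    tr <- dplyr::filter(trials, .data$condition == cond)
    la <- latents[trials$condition == cond, ]
    lt <- dplyr::semi_join(learning_trials,
                           dplyr::distinct(tr, .data$session_id),
                           by = "session_id")
    regs <- lapply(setNames(names(default_epochs()),
                            names(default_epochs())), function(e) {
      build_regressors(tr, la, lt, epoch = e)
    })
    gain <- if (cond == "drug") config$units$gain_drug else
      config$units$gain_control
    n_tuned <- round(config$units$tuned_fraction * n_units)
    for (i in seq_len(n_units)) {
      u <- u + 1L
      tuning <- if (i <= n_tuned) {
        setNames(gain, config$units$tuning_variable)
      } else {
        numeric(0)
      }
      us <- unit_spec(sprintf("u%03d", u), area = areas[1 + (u %% 3)],
                      baseline_rate = config$units$baseline_rate,
                      tuning = tuning, condition = cond)
      rec <- generate_spike_trains(us, tr, la, seed = seeds$spikes + u,
                                   regressors = regs)
      unit_rows[[u]] <- tibble::tibble(
        unit_id = us$unit_id, area = us$area, condition = cond,
        tuned = i <= n_tuned, gain = if (i <= n_tuned) gain else 0
      )
      results[[u]] <- encode_unit(rec, tr, la, epoch = epoch,
                                  regressors = regs[[epoch]],
                                  min_trials = config$stats$min_trials,
                                  alpha = config$stats$alpha)
    }
  }
  manifest_units <- dplyr::bind_rows(unit_rows)

  stage_msg("classify", "waveform generation and NS/BS classification")
  wf <- generate_waveforms(
    default_waveform_classes(config$units$scheme, config$units$prop_ns),
    n_units = 2 * n_units, seed = seeds$waveforms
  )
  classified <- classify_units(measure_waveforms(wf), config$units$scheme,
                               seed = seeds$classify)
  manifest_units$cell_class <- classified$label[seq_len(nrow(manifest_units))]
  readr::write_tsv(manifest_units, file.path(out_dir, "units.tsv"))
  readr::write_tsv(dplyr::select(classified, -dplyr::any_of("waveform")),
                   file.path(out_dir, "cell_classes.tsv"))
  ggplot2::ggsave(file.path(out_dir, "waveform_classes.png"),
                  plot_waveform_classes(classified), width = 5, height = 4,
                  dpi = 150)

  stage_msg("encode", "encoding results and condition comparisons")
  res <- dplyr::bind_rows(results) |>
    dplyr::select(-"cell_class") |>
    dplyr::left_join(
      dplyr::select(manifest_units, "unit_id", "cell_class"),
      by = "unit_id"
    )
  readr::write_tsv(res, file.path(out_dir, "encoding_results.tsv"))
  comparison <- population_compare(
    res, conditions = conditions, n_perm = config$stats$n_perm,
    min_n = config$stats$min_units, seed = seeds$compare,
    by = c("area", "variable")
  )
  readr::write_tsv(comparison, file.path(out_dir, "population_comparison.tsv"))
  ggplot2::ggsave(file.path(out_dir, "comparison_grid.png"),
                  plot_comparison_grid(comparison, config$stats$alpha),
                  width = 8, height = 6, dpi = 150)
  ranking <- tryCatch(rank_variables(res, conditions), error = function(e) NULL)
  if (!is.null(ranking)) {
    readr::write_tsv(ranking$ranking, file.path(out_dir, "variable_ranking.tsv"))
    readr::write_tsv(ranking$comparison,
                     file.path(out_dir, "ranking_comparison.tsv"))
  }
  prev <- prevalence_compare(res, config$units$tuning_variable,
                             conditions = conditions)
  readr::write_tsv(prev, file.path(out_dir, "prevalence.tsv"))

  write_manifest(config, seeds, out_dir)
  stage_msg("report", "done: %s", out_dir)
  invisible(out_dir)
}

write_manifest <- function(config, seeds, out_dir) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("flexshift")),
    config = config,
    derived_seeds = seeds,
    files = sort(list.files(out_dir))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}
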