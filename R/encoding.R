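# Neural encoding battery: spike-density conversion, epoch firing rates,
# the 18-variable regression set, permutation comparisons between
# conditions, best-variable rankings, and spiking variability statistics.

#' Gaussian spike-density function
#'
#' Sum of unit-area Gaussian kernels centred at the spike times, evaluated
#' on a time grid; units are Hz.
#'
#' @param spike_times Spike times (s).
#' @param time_grid Evaluation grid (s); step should be <= 5 ms.
#' @param kernel_sd Kernel standard deviation (s).
#' @return Numeric rate trace, one value per grid point.
#' @examples
#' spike_density(0.5, c(0.4, 0.5, 0.6)) # peak 1/(0.05 sqrt(2 pi)) ~ 7.98 Hz
#' @export
spike_density <- function(spike_times, time_grid, kernel_sd = 0.050) {
  stopifnot(kernel_sd > 0)
  if (length(spike_times) == 0) {
    return(rep(0, length(time_grid)))
  }
  vapply(time_grid, function(t) {
    sum(dnorm(t - spike_times, sd = kernel_sd))
  }, 0)
}

#' Per-trial mean firing rate in an analysis epoch
#'
#' The mean of the Gaussian spike-density trace over the epoch window; this
#' equals, in closed form, the sum over spikes of the normal CDF mass inside
#' the window divided by the window length (so no grid is needed). A raw
#' spike-count mode is also available.
#'
#' @param unit A `unit_recording` (see [generate_spike_trains()]).
#' @param trials Trial table providing the alignment-event times.
#' @param epoch Epoch name in `epochs`.
#' @param epochs Epoch definitions ([default_epochs()]).
#' @param kernel_sd Kernel SD (s) for the density mode.
#' @param method `"kernel"` (mean smoothed rate) or `"count"`
#'   (spikes / window).
#' @return A tibble `trial_index`, `rate` (Hz); trials with a missing
#'   alignment event are dropped.
#' @export
epoch_rate <- function(unit, trials, epoch = "feedback",
                       epochs = default_epochs(), kernel_sd = 0.050,
                       method = c("kernel", "count")) {
  method <- match.arg(method)
  if (!epoch %in% names(epochs)) {
    stop("unknown epoch: ", epoch, call. = FALSE)
  }
  ev <- trials[[epochs[[epoch]]$event]]
  if (is.null(ev)) {
    stop("trial table lacks event column ", epochs[[epoch]]$event,
         call. = FALSE)
  }
  win <- epochs[[epoch]]$window
  width <- win[2] - win[1]
  n <- nrow(trials)
  keep <- which(is.finite(ev))
  spk <- unit$spikes
  rate <- numeric(length(keep))
  start <- ev[keep] + win[1]
  end <- ev[keep] + win[2]
  grp <- split(spk$spike_time_s, factor(spk$trial_index, levels = keep))
  for (i in seq_along(keep)) {
    s <- grp[[i]]
    if (is.null(s) || !length(s)) {
      rate[i] <- 0
    } else if (method == "count") {
      rate[i] <- sum(s >= start[i] & s <= end[i]) / width
    } else {
      rate[i] <- sum(pnorm(end[i], s, kernel_sd) -
                       pnorm(start[i], s, kernel_sd)) / width
    }
  }
  tibble::tibble(trial_index = keep, rate = rate)
}

#' The 18 per-trial regressors of the encoding battery
#'
#' Six binary stimulus variables (colour, motion, location of the chosen and
#' of the rewarded/target stimulus), six outcome variables (outcome; outcome
#' during / after learning; prior outcome given a correct / an error trial;
#' error order during learning), and six epoch-dependent latent model
#' variables: in the feedback epoch the signed / positive / negative reward
#' prediction errors and their learning-restricted versions; in the
#' attention epoch the choice probability and the chosen value on rewarded /
#' unrewarded trials, plus learning-restricted versions. Learning-restricted
#' regressors are defined only on trials before the statistically defined
#' learning trial; undefined entries are `NA` and are excluded from that
#' regressor's fit only.
#'
#' @param trials Trial table.
#' @param latents Row-aligned latent table ([compute_latents()]).
#' @param learning_trials Optional tibble (`session_id`, `block_index`,
#'   `learning_trial`); estimated with [em_learning_curve()] when `NULL`.
#' @param epoch `"feedback"` or `"attention"`.
#' @return A tibble with 18 named regressor columns, row-aligned with
#'   `trials`.
#' @export
build_regressors <- function(trials, latents, learning_trials = NULL,
                             epoch = c("feedback", "attention")) {
  epoch <- match.arg(epoch)
  stopifnot(nrow(trials) == nrow(latents))
  if (is.null(learning_trials)) {
    learning_trials <- estimate_learning_trials(trials)
  }
  lt <- trials |>
    dplyr::select("session_id", "block_index", "trial_in_block") |>
    dplyr::left_join(learning_trials, by = c("session_id", "block_index"))
  # during learning: before the learning trial; an unlearned block is all
  # during-learning
  during <- is.na(lt$learning_trial) | lt$trial_in_block < lt$learning_trial
  after <- !during
  chosen_is_a <- trials$chosen_stim == "A"
  pick <- function(col_a, col_b) {
    ifelse(chosen_is_a, trials[[col_a]], trials[[col_b]])
  }
  chosen_color <- pick("stim_A_color", "stim_B_color")
  chosen_motion <- pick("stim_A_motion", "stim_B_motion")
  chosen_location <- pick("stim_A_location", "stim_B_location")
  target_is_a <- trials$stim_A_color == trials$rewarded_color
  tpick <- function(col_a, col_b) {
    ifelse(target_is_a, trials[[col_a]], trials[[col_b]])
  }
  bin <- function(x, one) as.numeric(x == one)
  outcome <- trials$outcome
  # previous outcome within block
  prev <- dplyr::lag(outcome)
  prev[trials$trial_in_block == 1] <- NA
  mask <- function(x, keep) replace(x, !keep, NA)
  # error order during learning: descending rank over pre-learning errors
  err_order <- rep(NA_real_, nrow(trials))
  key <- paste(trials$session_id, trials$block_index)
  for (k in unique(key)) {
    i <- which(key == k)
    e <- i[outcome[i] == 0 & during[i]]
    if (length(e)) err_order[e] <- rev(seq_along(e))
  }
  out <- tibble::tibble(
    chosen_color = bin(chosen_color, .fs_colors[2]),
    chosen_motion = bin(chosen_motion, .fs_motions[2]),
    chosen_location = bin(chosen_location, .fs_locations[2]),
    target_color = bin(trials$rewarded_color, .fs_colors[2]),
    target_motion = bin(tpick("stim_A_motion", "stim_B_motion"),
                        .fs_motions[2]),
    target_location = bin(tpick("stim_A_location", "stim_B_location"),
                          .fs_locations[2]),
    outcome = as.numeric(outcome),
    outcome_during_learning = mask(as.numeric(outcome), during),
    outcome_after_learning = mask(as.numeric(outcome), after),
    prior_outcome_given_correct = mask(prev, outcome == 1),
    prior_outcome_given_error = mask(prev, outcome == 0),
    error_order_during_learning = err_order
  )
  if (epoch == "feedback") {
    out$rpe_signed <- latents$rpe
    out$rpe_positive <- latents$rpe_pos
    out$rpe_negative <- latents$rpe_neg
    out$rpe_signed_learning <- mask(latents$rpe, during)
    out$rpe_positive_learning <- mask(latents$rpe_pos, during)
    out$rpe_negative_learning <- mask(latents$rpe_neg, during)
  } else {
    out$choice_probability <- latents$p_choice
    out$value_chosen_rewarded <- mask(latents$v_chosen, outcome == 1)
    out$value_chosen_unrewarded <- mask(latents$v_chosen, outcome == 0)
    out$choice_probability_learning <- mask(latents$p_choice, during)
    out$value_chosen_rewarded_learning <-
      mask(latents$v_chosen, outcome == 1 & during)
    out$value_chosen_unrewarded_learning <-
      mask(latents$v_chosen, outcome == 0 & during)
  }
  out
}

#' Univariate regression of epoch firing rate on one variable
#'
#' Ordinary least squares of the per-trial rate on a single regressor;
#' reports the signed correlation coefficient, its square, and the slope
#' test p value. Fits with fewer than `min_trials` valid pairs or with
#' zero-variance inputs are undefined (not significant).
#'
#' @param rates Per-trial rates.
#' @param variable Per-trial regressor values (NA = undefined).
#' @param min_trials Minimum number of valid pairs.
#' @param alpha Significance level.
#' @return One-row tibble: `r`, `r2`, `p_value`, `n_trials`, `significant`.
#' @export
regress_unit <- function(rates, variable, min_trials = 30, alpha = 0.05) {
  stopifnot(length(rates) == length(variable))
  ok <- is.finite(rates) & is.finite(variable)
  x <- variable[ok]
  y <- rates[ok]
  n <- length(x)
  if (n < min_trials || var(x) == 0 || var(y) == 0) {
    return(tibble::tibble(r = NA_real_, r2 = NA_real_, p_value = NA_real_,
                          n_trials = n, significant = FALSE))
  }
  ct <- suppressWarnings(cor.test(x, y))
  r <- unname(ct$estimate)
  tibble::tibble(r = r, r2 = r^2, p_value = ct$p.value, n_trials = n,
                 significant = is.finite(ct$p.value) && ct$p.value < alpha)
}

#' Run the full regression battery for one unit and epoch
#'
#' @param unit A `unit_recording`.
#' @param trials,latents Session tables aligned with the unit's spikes.
#' @param epoch `"feedback"` or `"attention"`.
#' @param regressors Optional precomputed [build_regressors()] table.
#' @param cell_class Optional waveform class label to carry along.
#' @inheritParams regress_unit
#' @inheritParams epoch_rate
#' @return A long tibble with one row per regressor: unit metadata, `r`,
#'   `r2`, `p_value`, `n_trials`, `significant`.
#' @export
encode_unit <- function(unit, trials, latents, epoch = "feedback",
                        regressors = NULL, cell_class = NA_character_,
                        epochs = default_epochs(), min_trials = 30,
                        alpha = 0.05, method = "kernel") {
  if (is.null(regressors)) {
    regressors <- build_regressors(trials, latents, epoch = epoch)
  }
  er <- epoch_rate(unit, trials, epoch, epochs, method = method)
  rates <- rep(NA_real_, nrow(trials))
  rates[er$trial_index] <- er$rate
  purrr::imap(regressors, function(v, nm) {
    dplyr::mutate(
      regress_unit(rates, v, min_trials, alpha),
      variable = nm, .before = 1
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      unit_id = unit$unit_id, area = unit$area, condition = unit$condition,
      cell_class = cell_class, epoch = epoch, .before = 1
    )
}

#' Best encoded variable per unit
#'
#' Among a unit's significant fits, the variable with the highest R^2;
#' units with no significant fit are dropped.
#'
#' @param results Long results from [encode_unit()] (possibly several
#'   units).
#' @return One row per unit with a best variable: `unit_id`, `area`,
#'   `condition`, `epoch`, `best_variable`, `r2`.
#' @export
best_variable <- function(results) {
  results |>
    dplyr::filter(.data$significant) |>
    dplyr::group_by(.data$unit_id, .data$area, .data$condition,
                    .data$epoch) |>
    dplyr::slice_max(.data$r2, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("unit_id", "area", "condition", "epoch",
                  best_variable = "variable", "r2")
}

# Permutation p for a difference of group means; two-sided, add-one.
perm_mean_diff <- function(values, is_a, n_perm) {
  n <- length(values)
  n_a <- sum(is_a)
  obs <- mean(values[is_a]) - mean(values[!is_a])
  sum_all <- sum(values)
  null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, n_a)
    sa <- sum(values[idx])
    sa / n_a - (sum_all - sa) / (n - n_a)
  }, 0)
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
  list(delta = obs, p = p)
}

#' Permutation comparison of encoding strength between conditions
#'
#' For every (area, variable, sign class, cell class) cell, compares the
#' mean correlation coefficient of significant units between the two
#' condition labels by shuffling condition labels (`n_perm` permutations;
#' two-sided, add-one p). The unsigned class uses |r| of all significant
#' units; the positive / negative classes subset units by the sign of r.
#' Cells where either group has fewer than `min_n` units are not tested.
#'
#' @param results Long results from [encode_unit()] for both conditions.
#' @param conditions Length-2 character: the condition treated as group A
#'   (e.g. drug) and group B (e.g. control).
#' @param n_perm Number of permutations.
#' @param min_n Minimum units per group for a cell to be tested.
#' @param seed Integer seed for the permutations.
#' @param by Grouping columns defining the comparison grid (in addition to
#'   sign class).
#' @return A tibble with one row per grid cell: group means, `delta`
#'   (A minus B), `permutation_p`, group sizes, `tested`.
#' @export
population_compare <- function(results, conditions = c("drug", "control"),
                               n_perm = 5000, min_n = 3, seed = NULL,
                               by = c("area", "variable", "cell_class")) {
  stopifnot(length(conditions) == 2)
  by <- intersect(by, names(results))
  sig <- results |>
    dplyr::filter(.data$significant, .data$condition %in% conditions)
  grid_one <- function(df, sign_class) {
    vals <- switch(sign_class,
      unsigned = abs(df$r),
      positive = df$r[df$r > 0],
      negative = df$r[df$r < 0]
    )
    conds <- switch(sign_class,
      unsigned = df$condition,
      positive = df$condition[df$r > 0],
      negative = df$condition[df$r < 0]
    )
    is_a <- conds == conditions[1]
    n_a <- sum(is_a)
    n_b <- sum(!is_a)
    out <- tibble::tibble(
      sign_class = sign_class,
      mean_r_a = if (n_a) mean(vals[is_a]) else NA_real_,
      mean_r_b = if (n_b) mean(vals[!is_a]) else NA_real_,
      delta = NA_real_, permutation_p = NA_real_,
      n_a = n_a, n_b = n_b,
      tested = n_a >= min_n && n_b >= min_n
    )
    if (out$tested) {
      pr <- perm_mean_diff(vals, is_a, n_perm)
      out$delta <- pr$delta
      out$permutation_p <- pr$p
    }
    out
  }
  with_local_seed(seed, {
    sig |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(function(df, key) {
        dplyr::bind_rows(
          grid_one(df, "unsigned"),
          grid_one(df, "positive"),
          grid_one(df, "negative")
        )
      }) |>
      dplyr::ungroup() |>
      dplyr::rename_with(
        ~ sub("_a$", paste0("_", conditions[1]),
              sub("_b$", paste0("_", conditions[2]), .x)),
        dplyr::matches("_(a|b)$")
      )
  })
}

#' Kendall's tau between two variable orderings
#'
#' @param order_a,order_b Character vectors giving the two orderings (same
#'   elements), or numeric rank vectors.
#' @return One-row tibble with `tau` and `p_value`.
#' @examples
#' ranking_tau(c("A", "B", "C", "D"), c("A", "C", "B", "D")) # tau = 2/3
#' @export
ranking_tau <- function(order_a, order_b) {
  if (is.character(order_a)) {
    stopifnot(setequal(order_a, order_b))
    items <- order_a
    ra <- seq_along(items)
    rb <- match(items, order_b)
  } else {
    ra <- order_a
    rb <- order_b
  }
  ct <- suppressWarnings(cor.test(ra, rb, method = "kendall"))
  tibble::tibble(tau = unname(ct$estimate), p_value = ct$p.value)
}

#' Rank variables by how often they best explain a unit
#'
#' Ranks the regressor variables by the fraction of units for which each is
#' the best-fit (highest significant R^2) variable, separately per
#' condition, and compares the two rankings with Kendall's tau.
#'
#' @param results Long results from [encode_unit()].
#' @param conditions Length-2 condition labels to compare.
#' @return A list with `ranking` (per-variable fractions and ranks per
#'   condition) and `comparison` (tau, p value).
#' @export
rank_variables <- function(results, conditions = c("drug", "control")) {
  best <- best_variable(
    dplyr::filter(results, .data$condition %in% conditions)
  )
  if (nrow(best) == 0) {
    stop("no units with a significant fit; ranking is empty", call. = FALSE)
  }
  variables <- unique(results$variable)
  frac <- best |>
    dplyr::count(.data$condition, .data$best_variable) |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    tidyr::complete(
      condition = conditions,
      best_variable = variables,
      fill = list(n = 0L, fraction = 0)
    ) |>
    tidyr::pivot_wider(
      id_cols = "best_variable",
      names_from = "condition",
      values_from = "fraction",
      values_fill = 0
    )
  ra <- rank(-frac[[conditions[1]]])
  rb <- rank(-frac[[conditions[2]]])
  ranking <- dplyr::mutate(
    frac,
    rank_a = ra, rank_b = rb
  )
  list(ranking = ranking, comparison = ranking_tau(ra, rb))
}

#' Compare the prevalence of significant encoding between conditions
#'
#' @param results Long results from [encode_unit()].
#' @param variable Regressor name.
#' @param area Recording area (or `NULL` for all).
#' @param conditions Length-2 condition labels.
#' @return One-row tibble: per-condition significant fractions and counts,
#'   and the two-sided two-proportion test p value.
#' @export
prevalence_compare <- function(results, variable, area = NULL,
                               conditions = c("drug", "control")) {
  df <- results |>
    dplyr::filter(.data$variable == !!variable,
                  .data$condition %in% conditions)
  if (!is.null(area)) {
    df <- dplyr::filter(df, .data$area == !!area)
  }
  tab <- df |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$significant),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$condition, conditions))
  stopifnot(nrow(tab) == 2)
  pt <- suppressWarnings(prop.test(tab$k, tab$n, correct = FALSE))
  tibble::tibble(
    variable = variable,
    area = if (is.null(area)) NA_character_ else area,
    prop_1 = tab$k[1] / tab$n[1], prop_2 = tab$k[2] / tab$n[2],
    n_1 = tab$n[1], n_2 = tab$n[2],
    difference = tab$k[1] / tab$n[1] - tab$k[2] / tab$n[2],
    p_value = pt$p.value
  )
}

#' Interspike-interval statistics
#'
#' CV (SD over mean of the ISIs) and the local variation LV
#' `3/(n-1) * sum(((isi_i - isi_{i+1}) / (isi_i + isi_{i+1}))^2)`;
#' both are 1 for Poisson firing and 0 for perfectly regular firing.
#'
#' @param isis Interspike intervals (s).
#' @return One-row tibble `cv`, `lv`, `n_isi` (`NA` values when fewer than
#'   2 ISIs for CV / LV).
#' @examples
#' isi_stats(c(0.010, 0.030))$lv # 0.75
#' @export
isi_stats <- function(isis) {
  isis <- isis[is.finite(isis) & isis > 0]
  n <- length(isis)
  if (n < 2) {
    return(tibble::tibble(cv = NA_real_, lv = NA_real_, n_isi = n))
  }
  cv <- sd(isis) / mean(isis)
  d <- (isis[-n] - isis[-1]) / (isis[-n] + isis[-1])
  lv <- 3 / (n - 1) * sum(d^2)
  tibble::tibble(cv = cv, lv = lv, n_isi = n)
}

#' Epoch firing statistics for one unit
#'
#' Mean rate plus CV and LV of the interspike intervals pooled across
#' trials within the epoch window.
#'
#' @inheritParams epoch_rate
#' @param min_isi Minimum number of ISIs required; below it the statistics
#'   are `NA`.
#' @return One-row tibble: `mean_rate`, `cv`, `lv`, `n_isi`.
#' @export
spiking_stats <- function(unit, trials, epoch = "feedback",
                          epochs = default_epochs(), min_isi = 3) {
  ev <- trials[[epochs[[epoch]]$event]]
  win <- epochs[[epoch]]$window
  width <- win[2] - win[1]
  isis <- unlist(lapply(seq_len(nrow(trials)), function(t) {
    s <- unit$spikes$spike_time_s[unit$spikes$trial_index == t]
    s <- sort(s[s >= ev[t] + win[1] & s <= ev[t] + win[2]])
    if (length(s) > 1) diff(s) else numeric(0)
  }))
  total_spikes <- sum(vapply(seq_len(nrow(trials)), function(t) {
    s <- unit$spikes$spike_time_s[unit$spikes$trial_index == t]
    sum(s >= ev[t] + win[1] & s <= ev[t] + win[2])
  }, 0))
  st <- if (length(isis) >= min_isi) {
    isi_stats(isis)
  } else {
    tibble::tibble(cv = NA_real_, lv = NA_real_, n_isi = length(isis))
  }
  dplyr::mutate(st, mean_rate = total_spikes / (nrow(trials) * width),
                .before = 1)
}

#' Pairwise spike-count correlations between simultaneously recorded units
#'
#' Pearson correlation of per-trial epoch spike counts for every unit pair
#' sharing at least `min_shared` trials.
#'
#' @param units List of `unit_recording`s from the same session.
#' @inheritParams epoch_rate
#' @param min_shared Minimum number of shared trials per pair.
#' @return A long tibble `unit_i`, `unit_j`, `n_trials`, `r` (`NA` for
#'   zero-variance units).
#' @export
noise_correlations <- function(units, trials, epoch = "feedback",
                               epochs = default_epochs(), min_shared = 30) {
  stopifnot(length(units) >= 2)
  counts <- vapply(units, function(u) {
    er <- epoch_rate(u, trials, epoch, epochs, method = "count")
    out <- rep(NA_real_, nrow(trials))
    out[er$trial_index] <- er$rate
    out
  }, numeric(nrow(trials)))
  ids <- vapply(units, `[[`, "", "unit_id")
  pairs <- utils::combn(seq_along(units), 2)
  purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    ok <- is.finite(counts[, i]) & is.finite(counts[, j])
    r <- if (sum(ok) < min_shared ||
             var(counts[ok, i]) == 0 || var(counts[ok, j]) == 0) {
      NA_real_
    } else {
      cor(counts[ok, i], counts[ok, j])
    }
    tibble::tibble(unit_i = ids[i], unit_j = ids[j], n_trials = sum(ok),
                   r = r)
  }) |>
    dplyr::bind_rows()
}
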