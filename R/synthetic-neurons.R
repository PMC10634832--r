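# Ground-truth synthetic units: Poisson spike trains whose epoch firing
# rates are modulated log-linearly by chosen task/latent regressors, and
# two-class parametric spike waveforms for classification validation.

#' Analysis epoch definitions
#'
#' Feedback epoch 0.05-1 s after reward feedback; attention epoch 0.05-0.7 s
#' after colour-cue onset.
#'
#' @return Named list of epochs, each with `event` (a `t_*` column of the
#'   trial table) and `window` (start/end offsets in seconds).
#' @export
default_epochs <- function() {
  list(
    feedback = list(event = "t_feedback", window = c(0.05, 1.0)),
    attention = list(event = "t_color_on", window = c(0.05, 0.7))
  )
}

#' Specification of one synthetic unit
#'
#' @param unit_id Unit identifier.
#' @param area Recording area (`"dlPFC"`, `"ACC"`, `"striatum"`).
#' @param true_class Ground-truth waveform class (`"NS"` or `"BS"`).
#' @param baseline_rate Baseline firing rate (Hz, <= 100).
#' @param tuning Named numeric vector: fractional log-rate gain per unit of
#'   z-scored regressor, names drawn from the encoding regressor set (e.g.
#'   `c(rpe_signed = 0.3)`). Empty for untuned units.
#' @param condition Condition label (`"drug"` or `"control"`).
#' @return A list of class `unit_spec`.
#' @export
unit_spec <- function(unit_id, area = c("dlPFC", "ACC", "striatum"),
                      true_class = c("BS", "NS"), baseline_rate = 5,
                      tuning = numeric(0),
                      condition = c("control", "drug")) {
  area <- match.arg(area)
  true_class <- match.arg(true_class)
  condition <- match.arg(condition)
  stopifnot(baseline_rate > 0, baseline_rate <= 100,
            all(is.finite(tuning)))
  structure(
    list(unit_id = unit_id, area = area, true_class = true_class,
         baseline_rate = baseline_rate, tuning = tuning,
         condition = condition),
    class = "unit_spec"
  )
}

# z-score a numeric vector; undefined (NA) entries carry no modulation.
zscore0 <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    return(rep(0, length(x)))
  }
  z <- (x - mean(x, na.rm = TRUE)) / s
  z[is.na(z)] <- 0
  z
}

#' Generate a Poisson spike train for one unit
#'
#' Within each analysis epoch the rate on trial t is
#' `baseline * exp(sum_v gain_v * z(variable_v, t))`; outside the epochs the
#' unit fires at baseline. Spikes are drawn from a homogeneous Poisson
#' process within each segment. Undefined regressor values (e.g.
#' learning-restricted variables after learning) contribute no modulation.
#'
#' @param spec A [unit_spec()].
#' @param trials Trial table for the unit's session(s).
#' @param latents Row-aligned latent table (see [compute_latents()]).
#' @param epochs Epoch definitions, see [default_epochs()].
#' @param seed Integer seed.
#' @param regressors Optional named list of precomputed regressor tables per
#'   epoch (from [build_regressors()]); computed internally when `NULL`.
#' @param trial_padding Seconds of baseline firing retained after the last
#'   epoch of each trial.
#' @return A `unit_recording`: list with `unit_id`, `area`, `condition`,
#'   `true_class`, `spikes` (tibble `trial_index`, `spike_time_s`),
#'   `n_trials`, `waveform` (`NULL` here; see [generate_waveforms()]).
#' @export
generate_spike_trains <- function(spec, trials, latents,
                                  epochs = default_epochs(), seed = NULL,
                                  regressors = NULL, trial_padding = 0.2) {
  stopifnot(inherits(spec, "unit_spec"), nrow(trials) == nrow(latents))
  if (is.null(regressors)) {
    regressors <- lapply(setNames(names(epochs), names(epochs)), function(e) {
      build_regressors(trials, latents, epoch = e)
    })
  }
  n <- nrow(trials)
  # per-epoch absolute windows and modulated rates
  seg <- lapply(names(epochs), function(e) {
    ev <- trials[[epochs[[e]]$event]]
    win <- epochs[[e]]$window
    gains <- spec$tuning[names(spec$tuning) %in% names(regressors[[e]])]
    logmod <- rep(0, n)
    for (v in names(gains)) {
      logmod <- logmod + gains[[v]] * zscore0(regressors[[e]][[v]])
    }
    rate <- spec$baseline_rate * exp(logmod)
    if (any(rate > 500)) {
      stop("epoch rate exceeds 500 Hz; check tuning gains", call. = FALSE)
    }
    list(start = ev + win[1], end = ev + win[2], rate = rate)
  })
  names(seg) <- names(epochs)
  trial_end <- do.call(pmax, lapply(seg, `[[`, "end")) + trial_padding
  with_local_seed(seed, {
    pieces <- list()
    # epoch segments at modulated rates
    for (e in names(seg)) {
      s <- seg[[e]]
      counts <- rpois(n, s$rate * (s$end - s$start))
      idx <- rep.int(seq_len(n), counts)
      if (length(idx)) {
        pieces[[e]] <- tibble::tibble(
          trial_index = idx,
          spike_time_s = runif(length(idx), s$start[idx], s$end[idx])
        )
      }
    }
    # baseline segments: complement of the epoch windows within the trial
    starts <- do.call(cbind, lapply(seg, `[[`, "start"))
    ends <- do.call(cbind, lapply(seg, `[[`, "end"))
    ord <- if (ncol(starts) == 1) {
      matrix(1L, n, 1)
    } else {
      t(apply(starts, 1, order))
    }
    bounds <- lapply(seq_len(n), function(t) {
      o <- ord[t, ]
      lo <- c(0, ends[t, o])
      hi <- c(starts[t, o], trial_end[t])
      cbind(lo, hi)[hi > lo, , drop = FALSE]
    })
    base_pieces <- purrr::imap(bounds, function(b, t) {
      len <- b[, 2] - b[, 1]
      counts <- rpois(nrow(b), spec$baseline_rate * len)
      k <- rep.int(seq_len(nrow(b)), counts)
      if (!length(k)) {
        return(NULL)
      }
      tibble::tibble(
        trial_index = t,
        spike_time_s = runif(length(k), b[k, 1], b[k, 2])
      )
    })
    spikes <- dplyr::bind_rows(c(pieces, base_pieces)) |>
      dplyr::arrange(.data$trial_index, .data$spike_time_s)
    structure(
      list(unit_id = spec$unit_id, area = spec$area,
           condition = spec$condition, true_class = spec$true_class,
           spikes = spikes, n_trials = n, waveform = NULL),
      class = "unit_recording"
    )
  })
}

#' Default waveform class parameters
#'
#' Class-defining metric targets (mean, SD) for narrow- (NS) and
#' broad-spiking (BS) units. Cortical units are characterised by
#' trough-to-peak duration and time to repolarization; striatal units by the
#' half-maximum peak width and the initial valley-decay slope.
#'
#' @param scheme `"cortical"` or `"striatal"`.
#' @param prop_ns Proportion of NS units in a generated population.
#' @return A list with per-class metric targets.
#' @export
default_waveform_classes <- function(scheme = c("cortical", "striatal"),
                                     prop_ns = 0.3) {
  scheme <- match.arg(scheme)
  params <- if (scheme == "cortical") {
    list(
      NS = list(peak_to_trough_ms = c(mean = 0.20, sd = 0.04),
                time_to_repolarization_ms = c(mean = 0.18, sd = 0.03)),
      BS = list(peak_to_trough_ms = c(mean = 0.45, sd = 0.04),
                time_to_repolarization_ms = c(mean = 0.38, sd = 0.05))
    )
  } else {
    list(
      NS = list(peak_width_half_max_ms = c(mean = 0.12, sd = 0.02),
                valley_decay_slope = c(mean = 5.5, sd = 0.5)),
      BS = list(peak_width_half_max_ms = c(mean = 0.25, sd = 0.03),
                valley_decay_slope = c(mean = 2.2, sd = 0.4))
    )
  }
  list(scheme = scheme, prop_ns = prop_ns, classes = params)
}

# Build one biphasic waveform (negative Gaussian trough followed by a
# positive Gaussian peak) whose measured metrics match the targets, by
# iterative refinement against waveform_metrics().
synth_waveform <- function(targets, scheme, sampling_rate = 40000,
                           duration_ms = 2.0, peak_time_ms = 0.95) {
  t_ms <- seq(0, duration_ms, by = 1000 / sampling_rate)
  make <- function(par) {
    # par: t0 (trough time), s1 (trough sd), t1 (peak time), s2 (peak sd)
    -1 * exp(-(t_ms - par[1])^2 / (2 * par[2]^2)) +
      0.55 * exp(-(t_ms - par[3])^2 / (2 * par[4]^2))
  }
  if (scheme == "cortical") {
    ptt <- max(targets[["peak_to_trough_ms"]], 0.08)
    repol <- max(targets[["time_to_repolarization_ms"]], 0.06)
    # trough width scales with the trough-peak separation so the positive
    # peak is never submerged under the trough lobe
    par <- c(peak_time_ms - ptt, min(0.09, 0.4 * ptt), peak_time_ms,
             repol / 1.6651)
    for (i in 1:20) {
      m <- waveform_metrics(make(par), sampling_rate, "cortical")
      err_ptt <- targets[["peak_to_trough_ms"]] - m$peak_to_trough_ms
      par[1] <- max(min(par[1] - err_ptt, par[3] - 0.05), 0.15)
      par[4] <- par[4] * targets[["time_to_repolarization_ms"]] /
        m$time_to_repolarization_ms
      if (abs(err_ptt) < 1e-4 &&
          abs(m$time_to_repolarization_ms -
              targets[["time_to_repolarization_ms"]]) < 1e-4) break
    }
  } else {
    width <- max(targets[["peak_width_half_max_ms"]], 0.05)
    slope <- min(max(targets[["valley_decay_slope"]], 0.5), 9.5)
    d <- 0.1
    s1 <- d / sqrt(-2 * log(max(1 - slope * d, 1e-3)))
    # wide trough-peak separation keeps the peak lobe out of the
    # valley-decay measurement window
    par <- c(peak_time_ms - 0.55, s1, peak_time_ms, width / 2.3548)
    for (i in 1:40) {
      m <- waveform_metrics(make(par), sampling_rate, "striatal")
      par[4] <- par[4] * targets[["peak_width_half_max_ms"]] /
        m$peak_width_half_max_ms
      ratio <- m$valley_decay_slope / targets[["valley_decay_slope"]]
      par[2] <- par[2] * ratio^0.8
      if (abs(m$peak_width_half_max_ms -
              targets[["peak_width_half_max_ms"]]) < 1e-4 &&
          abs(ratio - 1) < 1e-3) break
    }
  }
  make(par)
}

#' Generate a two-class synthetic waveform population
#'
#' Draws per-unit metric targets from the class distributions and builds
#' biphasic (difference-of-Gaussians) waveforms, sampled at `sampling_rate`,
#' whose measured metrics match the drawn targets.
#'
#' @param class_params Output of [default_waveform_classes()] (possibly
#'   modified).
#' @param n_units Number of units; NS count is `round(prop_ns * n_units)`.
#' @param seed Integer seed.
#' @param sampling_rate Waveform sampling rate in Hz.
#' @return A tibble with `unit_id`, `true_class`, `scheme`, the drawn metric
#'   targets, and a `waveform` list-column of amplitude vectors.
#' @export
generate_waveforms <- function(class_params = default_waveform_classes(),
                               n_units = 100, seed = NULL,
                               sampling_rate = 40000) {
  scheme <- class_params$scheme
  metric_names <- names(class_params$classes$NS)
  n_ns <- round(class_params$prop_ns * n_units)
  labels <- c(rep("NS", n_ns), rep("BS", n_units - n_ns))
  with_local_seed(seed, {
    rows <- purrr::map(seq_len(n_units), function(i) {
      cls <- class_params$classes[[labels[i]]]
      targets <- vapply(metric_names, function(mn) {
        rnorm(1, cls[[mn]]["mean"], cls[[mn]]["sd"])
      }, 0)
      lo <- if (scheme == "cortical") c(0.08, 0.06) else c(0.05, 0.5)
      hi <- if (scheme == "cortical") c(0.8, 0.6) else c(0.5, 9.0)
      targets <- pmin(pmax(targets, lo), hi)
      wf <- synth_waveform(targets, scheme, sampling_rate)
      out <- tibble::tibble(
        unit_id = sprintf("wf%03d", i),
        true_class = labels[i],
        scheme = scheme
      )
      out[paste0("target_", metric_names)] <- as.list(targets)
      out$waveform <- list(wf)
      out
    })
    dplyr::bind_rows(rows)
  })
}
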