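# Criterion-based learning measures, averaged learning curves, and
# post-error / post-correct (EC_n / CC_n) accuracy analyses.

#' Criterion-based learning trial
#'
#' First trial from which performance over the subsequent `window` trials
#' (including the trial itself) reaches `threshold` proportion correct.
#' Windows extending past the end of the block are not evaluated.
#'
#' @param outcomes Binary outcome sequence (1 = correct).
#' @param threshold Proportion-correct criterion (met when the window mean is
#'   `>= threshold`, so 7/10 meets the 0.70 default).
#' @param window Window length in trials.
#' @return 1-based trial index, or `NA` if the criterion is never met.
#' @examples
#' criterion_learning_trial(c(0, 0, 0, rep(1, 10))) # 1 (7/10 = 0.7)
#' @export
criterion_learning_trial <- function(outcomes, threshold = 0.70,
                                     window = 10) {
  stopifnot(window >= 1, all(outcomes %in% c(0, 1)))
  n <- length(outcomes)
  if (n < window) {
    return(NA_integer_)
  }
  means <- vapply(seq_len(n - window + 1),
                  function(t) mean(outcomes[t:(t + window - 1)]), 0)
  hit <- which(means >= threshold)
  if (length(hit)) hit[1] else NA_integer_
}

#' Per-block learning summaries
#'
#' Computes, for every (session, block), the block length, the
#' criterion-based learning trial ([criterion_learning_trial()]) and the
#' EM ideal-observer learning trial ([em_learning_curve()]); a block counts
#' as learned when the EM learning trial exists.
#'
#' @param trials Trial table with `session_id`, `condition`, `block_index`,
#'   `outcome`.
#' @param threshold,window Criterion parameters.
#' @return A tibble with one row per block.
#' @export
block_summaries <- function(trials, threshold = 0.70, window = 10) {
  trials |>
    dplyr::group_by(.data$session_id, .data$condition, .data$block_index) |>
    dplyr::summarise(
      block_length = dplyr::n(),
      criterion_learning_trial =
        criterion_learning_trial(.data$outcome, threshold, window),
      em_learning_trial =
        glance(em_learning_curve(.data$outcome))$learning_trial,
      .groups = "drop"
    ) |>
    dplyr::mutate(learned = !is.na(.data$em_learning_trial))
}

#' Averaged learning curve across blocks
#'
#' Trial-wise mean proportion correct across blocks, with a trailing
#' moving-average smoothing applied from `smooth_from_trial` onward and the
#' standard error computed across blocks at each trial index.
#'
#' @param blocks Either a list of binary outcome vectors (one per block) or
#'   a trial table; for a trial table, the first block of each session is
#'   excluded and only blocks with a criterion learning trial are kept.
#' @param smooth_window Moving-average window (trials).
#' @param smooth_from_trial First trial index at which smoothing applies;
#'   earlier trials keep the raw mean.
#' @return A tibble: `trial`, `n_blocks`, `prop_correct_raw`, `se`,
#'   `prop_correct` (smoothed).
#' @export
average_learning_curve <- function(blocks, smooth_window = 4,
                                   smooth_from_trial = 4) {
  if (is.data.frame(blocks)) {
    keep <- blocks |>
      dplyr::group_by(.data$session_id, .data$block_index) |>
      dplyr::summarise(
        clt = criterion_learning_trial(.data$outcome), .groups = "drop"
      ) |>
      dplyr::filter(.data$block_index > 1, !is.na(.data$clt))
    blocks <- blocks |>
      dplyr::semi_join(keep, by = c("session_id", "block_index")) |>
      dplyr::group_by(.data$session_id, .data$block_index) |>
      dplyr::group_map(~ .x$outcome)
  }
  if (length(blocks) == 0) {
    stop("no learned blocks to average", call. = FALSE)
  }
  max_len <- max(lengths(blocks))
  by_trial <- purrr::map(seq_len(max_len), function(t) {
    vals <- unlist(purrr::map(blocks, function(b) {
      if (length(b) >= t) b[t] else NULL
    }))
    tibble::tibble(
      trial = t,
      n_blocks = length(vals),
      prop_correct_raw = mean(vals),
      se = if (length(vals) > 1) sd(vals) / sqrt(length(vals)) else 0
    )
  }) |>
    dplyr::bind_rows()
  raw <- by_trial$prop_correct_raw
  smoothed <- raw
  for (t in seq_along(raw)) {
    if (t >= smooth_from_trial) {
      smoothed[t] <- mean(raw[max(1, t - smooth_window + 1):t])
    }
  }
  by_trial$prop_correct <- smoothed
  by_trial
}

#' Post-error / post-correct accuracy (EC_n / CC_n)
#'
#' Proportion of correct outcomes at each lag 1..`n_after` following an
#' anchor trial, counted within block boundaries. Anchors are error trials
#' (`EC_n`), correct trials (`CC_n`) or only the first error of each block;
#' the block phase restricts the anchor position (early: trials 1-9, late:
#' trial 10 onward).
#'
#' @param trials Trial table with `session_id`, `block_index`,
#'   `trial_in_block`, `outcome`.
#' @param n_after Maximum lag.
#' @param anchor One of `"error"`, `"correct"`, `"first_error"`.
#' @param phase One of `"all"`, `"early"`, `"late"`.
#' @param early_trials Last trial index counted as early in the block.
#' @return A tibble with `lag`, `n` (lagged trials observed) and
#'   `prop_correct` (`NA` when no anchor trial yields that lag).
#' @examples
#' tr <- tibble::tibble(
#'   session_id = "s", block_index = 1, trial_in_block = 1:7,
#'   outcome = c(1, 0, 1, 0, 0, 1, 1)
#' )
#' post_outcome_accuracy(tr, n_after = 1, anchor = "error") # 2/3
#' @export
post_outcome_accuracy <- function(trials, n_after = 5,
                                  anchor = c("error", "correct",
                                             "first_error"),
                                  phase = c("all", "early", "late"),
                                  early_trials = 9) {
  anchor <- match.arg(anchor)
  phase <- match.arg(phase)
  pairs <- trials |>
    dplyr::group_by(.data$session_id, .data$block_index) |>
    dplyr::group_map(function(b, key) {
      b <- b[order(b$trial_in_block), ]
      out <- b$outcome
      pos <- b$trial_in_block
      idx <- switch(anchor,
        error = which(out == 0),
        correct = which(out == 1),
        first_error = utils::head(which(out == 0), 1)
      )
      idx <- switch(phase,
        all = idx,
        early = idx[pos[idx] <= early_trials],
        late = idx[pos[idx] > early_trials]
      )
      if (!length(idx)) {
        return(NULL)
      }
      purrr::map(idx, function(i) {
        lag <- seq_len(min(n_after, length(out) - i))
        if (!length(lag)) {
          return(NULL)
        }
        tibble::tibble(lag = lag, outcome = out[i + lag])
      }) |>
        dplyr::bind_rows()
    }) |>
    dplyr::bind_rows()
  base <- tibble::tibble(lag = seq_len(n_after))
  if (nrow(pairs) == 0) {
    return(dplyr::mutate(base, n = 0L, prop_correct = NA_real_))
  }
  pairs |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(n = dplyr::n(), prop_correct = mean(.data$outcome),
                     .groups = "drop") |>
    dplyr::right_join(base, by = "lag") |>
    dplyr::arrange(.data$lag) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Rank-sum comparison of a behavioral metric between conditions
#'
#' Wilcoxon rank-sum test on a per-session (or per-block) metric between two
#' condition labels.
#'
#' @param data A data frame.
#' @param value Column name (string) of the metric.
#' @param condition Column name (string) of the two-level condition label.
#' @return A one-row tibble with group medians, the W statistic and p value.
#' @export
rank_sum_compare <- function(data, value, condition = "condition") {
  groups <- split(data[[value]], data[[condition]])
  groups <- lapply(groups, function(x) x[!is.na(x)])
  stopifnot(length(groups) == 2)
  wt <- stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE)
  tibble::tibble(
    group_1 = names(groups)[1], group_2 = names(groups)[2],
    median_1 = median(groups[[1]]), median_2 = median(groups[[2]]),
    statistic = unname(wt$statistic), p_value = wt$p.value
  )
}
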