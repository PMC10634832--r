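# Waveform metrics and narrow/broad-spiking classification.
#
# Cortical units are split on trough-to-peak duration and time to
# repolarization; striatal units on half-maximum peak width and the initial
# slope of the valley decay. Units are clustered on the first principal
# component of the z-scored scheme metrics (k-means, k = 2).

#' Waveform shape metrics
#'
#' Metrics are measured after amplitude normalisation (max |amplitude| = 1)
#' and cubic-spline upsampling to 100 kHz. The waveform must contain a
#' trough followed by a positive peak.
#'
#' @param waveform Numeric amplitude vector.
#' @param sampling_rate Sampling rate of `waveform` in Hz.
#' @param scheme `"cortical"` or `"striatal"` (determines which metrics are
#'   primary; all four are returned).
#' @param repol_frac Fraction of the peak amplitude whose first
#'   post-peak crossing defines the repolarization time.
#' @param slope_window_ms Window after the trough over which the valley
#'   decay slope is measured.
#' @return A one-row tibble: `peak_to_trough_ms`,
#'   `time_to_repolarization_ms`, `peak_width_half_max_ms`,
#'   `valley_decay_slope` (normalised amplitude per ms), `scheme`.
#' @export
waveform_metrics <- function(waveform, sampling_rate = 40000,
                             scheme = c("cortical", "striatal"),
                             repol_frac = 0.25, slope_window_ms = 0.1) {
  scheme <- match.arg(scheme)
  stopifnot(length(waveform) > 4, all(is.finite(waveform)))
  dur_ms <- (length(waveform) - 1) / sampling_rate * 1000
  if (dur_ms < 1) {
    stop("waveform must span at least 1 ms", call. = FALSE)
  }
  w <- waveform / max(abs(waveform))
  t_ms <- seq(0, dur_ms, length.out = length(w))
  up <- stats::spline(t_ms, w, n = ceiling(dur_ms * 100) + 1)
  tu <- up$x
  wu <- up$y
  i_trough <- which.min(wu)
  i_peak <- which.max(wu)
  if (i_peak <= i_trough || wu[i_trough] >= 0 || wu[i_peak] <= 0) {
    stop("waveform has no trough followed by a peak; unit not measurable",
         call. = FALSE)
  }
  # parabolic sub-sample refinement of an extremum position
  refine <- function(i) {
    if (i <= 1 || i >= length(wu)) {
      return(tu[i])
    }
    denom <- wu[i - 1] - 2 * wu[i] + wu[i + 1]
    if (abs(denom) < 1e-12) {
      return(tu[i])
    }
    tu[i] + 0.5 * (tu[i] - tu[i - 1]) * (wu[i - 1] - wu[i + 1]) / denom
  }
  peak_to_trough <- refine(i_peak) - refine(i_trough)
  # linear interpolation of a downward threshold crossing between samples
  cross_down <- function(i0, i1, thr) {
    # first index in i0:i1 with wu <= thr, interpolated
    below <- which(wu[i0:i1] <= thr)
    if (!length(below)) {
      return(NA_real_)
    }
    j <- i0 + below[1] - 1
    if (j == i0) {
      return(tu[j])
    }
    tu[j - 1] + (tu[j] - tu[j - 1]) * (wu[j - 1] - thr) / (wu[j - 1] - wu[j])
  }
  cross_up_last <- function(i0, i1, thr) {
    # last index in i0:i1 with wu <= thr, crossing to > thr, interpolated
    below <- which(wu[i0:i1] <= thr)
    if (!length(below)) {
      return(NA_real_)
    }
    j <- i0 + max(below) - 1
    if (j == i1) {
      return(tu[j])
    }
    tu[j] + (tu[j + 1] - tu[j]) * (thr - wu[j]) / (wu[j + 1] - wu[j])
  }
  # repolarization: first return to repol_frac * peak after the peak
  t_rep <- cross_down(i_peak, length(wu), repol_frac * wu[i_peak])
  repol <- if (is.na(t_rep)) NA_real_ else t_rep - tu[i_peak]
  # half-max width of the positive peak lobe
  half <- 0.5 * wu[i_peak]
  t_left <- cross_up_last(1, i_peak, half)
  t_right <- cross_down(i_peak, length(wu), half)
  width <- if (is.na(t_left) || is.na(t_right)) NA_real_ else t_right - t_left
  # initial valley-decay slope over slope_window_ms after the trough
  t_end <- tu[i_trough] + slope_window_ms
  i_end <- which.min(abs(tu - t_end))
  slope <- (wu[i_end] - wu[i_trough]) / (tu[i_end] - tu[i_trough])
  tibble::tibble(
    peak_to_trough_ms = peak_to_trough,
    time_to_repolarization_ms = repol,
    peak_width_half_max_ms = width,
    valley_decay_slope = slope,
    scheme = scheme
  )
}

#' Measure waveform metrics for a waveform table
#'
#' Applies [waveform_metrics()] to every row of a waveform table (e.g. from
#' [generate_waveforms()]).
#'
#' @param waveforms Data frame with a `waveform` list-column and a `scheme`
#'   column.
#' @param sampling_rate Sampling rate in Hz.
#' @return The table with the four metric columns appended (the `waveform`
#'   column is dropped).
#' @export
measure_waveforms <- function(waveforms, sampling_rate = 40000) {
  stopifnot(is.data.frame(waveforms), "waveform" %in% names(waveforms))
  mets <- purrr::map(waveforms$waveform, function(w) {
    waveform_metrics(w, sampling_rate, waveforms$scheme[1])
  }) |>
    dplyr::bind_rows()
  dplyr::bind_cols(
    dplyr::select(waveforms, -dplyr::any_of(c("waveform", "scheme"))),
    mets
  )
}

scheme_metric_cols <- function(scheme) {
  if (scheme == "cortical") {
    c("peak_to_trough_ms", "time_to_repolarization_ms")
  } else {
    c("peak_width_half_max_ms", "valley_decay_slope")
  }
}

#' Classify units into narrow- and broad-spiking classes
#'
#' z-scores the scheme's two waveform metrics, projects units onto the first
#' principal component, and partitions them with 2-means clustering
#' (50 restarts). The cluster with the smaller mean trough-to-peak duration
#' (cortical) or smaller half-maximum peak width (striatal) is labelled NS.
#'
#' @param metrics A data frame of per-unit metrics, e.g. from
#'   [measure_waveforms()]; must contain the scheme's two metric columns.
#' @param scheme `"cortical"` or `"striatal"`.
#' @param seed Integer seed for the k-means restarts.
#' @return The input tibble with added columns `pc1`, `label`
#'   (`"NS"`/`"BS"`) and `sil_width` (per-unit silhouette on PC1); the mean
#'   silhouette is attached as attribute `"silhouette"`.
#' @export
classify_units <- function(metrics, scheme = c("cortical", "striatal"),
                           seed = 1) {
  scheme <- match.arg(scheme)
  cols <- scheme_metric_cols(scheme)
  stopifnot(all(cols %in% names(metrics)))
  x <- as.matrix(metrics[, cols])
  if (nrow(x) < 10) {
    stop("need at least 10 units per scheme to classify", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("non-finite metrics; exclude unmeasurable units first",
         call. = FALSE)
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("degenerate clustering: zero variance in metric(s) ",
         paste(cols[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- scale(x)
  pc1 <- prcomp(z, center = FALSE, scale. = FALSE)$x[, 1]
  km <- with_local_seed(seed, kmeans(pc1, centers = 2, nstart = 50))
  narrowness <- tapply(x[, cols[1]], km$cluster, mean)
  ns_cluster <- as.integer(names(which.min(narrowness)))
  label <- ifelse(km$cluster == ns_cluster, "NS", "BS")
  sil <- silhouette_1d(pc1, km$cluster)
  out <- tibble::as_tibble(metrics)
  out$pc1 <- as.numeric(pc1)
  out$label <- label
  out$sil_width <- sil
  attr(out, "silhouette") <- mean(sil)
  out
}

# Silhouette widths for a 1-D clustering (euclidean distance).
silhouette_1d <- function(x, cluster) {
  vapply(seq_along(x), function(i) {
    own <- cluster[i]
    a_vals <- abs(x[i] - x[cluster == own])
    a <- if (length(a_vals) > 1) sum(a_vals) / (length(a_vals) - 1) else 0
    b <- min(vapply(setdiff(unique(cluster), own), function(k) {
      mean(abs(x[i] - x[cluster == k]))
    }, 0))
    if (length(a_vals) == 1) {
      return(0)
    }
    (b - a) / max(a, b)
  }, 0)
}
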