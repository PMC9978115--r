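#' Per-channel recording spike frequency
#'
#' The firing rate of one electrode over a recording:
#' `f = (spikes - 1) / dt`, where `spikes` is the number of spikes on the
#' channel and `dt` the time between its first and last spike.
#'
#' @param times Sorted numeric spike times of one electrode, seconds.
#' @return Rate in Hz, or `NA` (with a message in the attribute) when the
#'   train has fewer than two spikes and the rate is undefined.
#' @examples
#' firing_rate(c(0, 1, 2, 3, 4))  # 1 Hz
#' @export
firing_rate <- function(times) {
  n <- length(times)
  if (n < 2L) return(NA_real_)
  (n - 1) / (times[n] - times[1])
}

# Electrodes counted as active: overall rate of at least `min_rate` Hz
# (default 0.1 Hz, i.e. six spikes per minute).
active_electrodes <- function(recording, min_rate = 0.1) {
  rates <- lengths(recording$trains) / recording$duration
  names(recording$trains)[rates >= min_rate]
}

#' Instantaneous spike-frequency series on a sliding window
#'
#' For each window of width `width` stepped by `step` across the recording,
#' `f_window = spikes / (n * width)` where `spikes` counts pooled spikes of
#' the active electrodes falling in the half-open window and `n` is the
#' number of active electrodes of the recording (fixed per recording, not
#' per window). Windows start at `0, step, 2*step, ...` up to
#' `duration - width` inclusive.
#'
#' @param recording An [mea_recording()].
#' @param width Window width in seconds (default 1.0).
#' @param step Step size in seconds (default 0.1).
#' @param min_active_rate Activity cut for the electrode denominator, Hz.
#' @return A data.frame of class `mea_window_series` with columns
#'   `window_start`, `count`, `value` (Hz); attributes `width`, `step`,
#'   `n_active`.
#' @export
instantaneous_rate <- function(recording, width = 1.0, step = 0.1,
                               min_active_rate = 0.1) {
  stopifnot(inherits(recording, "mea_recording"))
  if (n_spikes(recording) == 0L) stop("recording has no spikes", call. = FALSE)
  act <- active_electrodes(recording, min_active_rate)
  if (length(act) == 0L) {
    stop("no active electrodes at the given activity cut", call. = FALSE)
  }
  times <- sort(unlist(recording$trains[act], use.names = FALSE))
  if (recording$duration < width) {
    stop("recording shorter than one window", call. = FALSE)
  }
  starts <- seq(0, recording$duration - width + 1e-9, by = step)
  # half-open [a, a+width): #{t < b} - #{t < a} via left-open findInterval
  below <- function(x) findInterval(x, times, left.open = TRUE)
  count <- below(starts + width) - below(starts)
  out <- data.frame(window_start = starts, count = count,
                    value = count / (length(act) * width))
  attr(out, "width") <- width
  attr(out, "step") <- step
  attr(out, "n_active") <- length(act)
  class(out) <- c("mea_window_series", "data.frame")
  out
}

#' Burstiness index of a window series
#'
#' The fraction of total activity contained in the 15% most active sliding
#' windows (`f15`), optionally rescaled so that perfectly uniform activity
#' maps to 0 and total concentration in the top windows maps to 1:
#' `BI = (f15 - top_fraction) / (1 - top_fraction)`. The top
#' `ceiling(top_fraction * W)` windows are taken by spike count, ties broken
#' toward earlier windows.
#'
#' @param series An `mea_window_series` from [instantaneous_rate()].
#' @param top_fraction Fraction of windows counted as "most active"
#'   (default 0.15).
#' @param normalized Return the rescaled index (default) or raw `f15`.
#' @return Burstiness index; raw `f15` is attached as attribute `"f15"`.
#'   `NA` when the series has zero total activity.
#' @export
burstiness_index <- function(series, top_fraction = 0.15, normalized = TRUE) {
  stopifnot_scalar_number(top_fraction, "top_fraction",
                          min = .Machine$double.eps, max = 1)
  counts <- series$count
  total <- sum(counts)
  if (total <= 0) return(NA_real_)
  w <- length(counts)
  k <- ceiling(top_fraction * w)
  top <- utils::head(order(-counts, seq_len(w)), k)
  f15 <- sum(counts[top]) / total
  bi <- if (normalized) (f15 - top_fraction) / (1 - top_fraction) else f15
  attr(bi, "f15") <- f15
  bi
}

#' Coherence index of a window series
#'
#' The coefficient of variation of the instantaneous spike-frequency series:
#' population standard deviation divided by the mean. Activity concentrated
#' in co-occurring bursts across electrodes raises the index; constant-rate
#' activity gives 0.
#'
#' @param series An `mea_window_series` from [instantaneous_rate()].
#' @return Coherence index (dimensionless, >= 0); `NA` when the mean is 0.
#' @export
coherence_index <- function(series) {
  v <- series$value
  m <- mean(v)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  sqrt(mean((v - m)^2)) / m     # population SD: the series is the population
}

# mean gap between consecutive event intervals (end_k -> start_{k+1})
mean_gap <- function(start_s, end_s) {
  if (length(start_s) < 2L) return(NA_real_)
  mean(start_s[-1] - end_s[-length(end_s)])
}

#' Burst-composition statistics of one recording
#'
#' Given detections, computes the composition metrics: mean burst duration,
#' mean inter-burst interval (IBI; averaged within each electrode with at
#' least two bursts, then across electrodes, so burst-rich electrodes do not
#' dominate), mean network inter-burst interval (NIBI), fractions of spikes
#' in bursts and in network bursts, and the spikes-per-burst occurrence
#' histogram. Undefined means are `NA`, never zero.
#'
#' @param recording An [mea_recording()].
#' @param bursts Data.frame from [detect_bursts()] (per-electrode).
#' @param network_bursts Data.frame from [detect_network_bursts()].
#' @return A list: `mean_burst_duration`, `mean_ibi`, `mean_nibi`,
#'   `frac_spikes_in_bursts`, `frac_spikes_in_network_bursts`, `n_bursts`,
#'   `n_network_bursts`, `spikes_per_burst` (table of burst counts by spike
#'   count), `spikes_per_network_burst`.
#' @export
burst_composition <- function(recording, bursts, network_bursts) {
  total <- n_spikes(recording)
  in_burst <- 0L
  if (nrow(bursts)) in_burst <- sum(bursts$n_spikes)
  ibis <- if (nrow(bursts)) {
    per_el <- split(bursts, bursts$electrode)
    vals <- vapply(per_el, function(b) mean_gap(b$start_s, b$end_s), numeric(1))
    vals[!is.na(vals)]
  } else numeric(0)
  in_nb <- 0L
  nibi <- NA_real_
  if (nrow(network_bursts)) {
    in_nb <- sum(network_bursts$n_spikes)
    nibi <- mean_gap(network_bursts$start_s, network_bursts$end_s)
  }
  list(
    mean_burst_duration = if (nrow(bursts)) mean(bursts$end_s - bursts$start_s)
                          else NA_real_,
    mean_ibi = if (length(ibis)) mean(ibis) else NA_real_,
    mean_nibi = nibi,
    frac_spikes_in_bursts = if (total > 0) in_burst / total else NA_real_,
    frac_spikes_in_network_bursts = if (total > 0) in_nb / total else NA_real_,
    n_bursts = nrow(bursts),
    n_network_bursts = nrow(network_bursts),
    spikes_per_burst = if (nrow(bursts)) table(bursts$n_spikes) else table(integer(0)),
    spikes_per_network_burst = if (nrow(network_bursts))
      table(network_bursts$n_spikes) else table(integer(0)))
}

#' Full metric vector of one recording
#'
#' Runs detection and every per-recording metric: mean firing rate (mean of
#' per-electrode rates over active electrodes), mean ISI, burstiness index
#' (normalized, raw `f15` alongside), coherence index, and all
#' burst-composition statistics of [burst_composition()].
#'
#' @param recording An [mea_recording()].
#' @param bp A [burst_params()] object.
#' @param np An [nb_params()] object.
#' @param width,step Sliding-window parameters, seconds.
#' @param min_active_rate Activity cut for the electrode denominator, Hz.
#' @return A list of class `mea_metrics`: scalar metrics plus `bursts`,
#'   `network_bursts`, `threshold_diagnostics`, `spikes_per_burst`,
#'   `spikes_per_network_burst`.
#' @export
compute_metrics <- function(recording, bp = burst_params(), np = nb_params(),
                            width = 1.0, step = 0.1, min_active_rate = 0.1) {
  stopifnot(inherits(recording, "mea_recording"))
  act <- active_electrodes(recording, min_active_rate)
  rates <- vapply(recording$trains[act], firing_rate, numeric(1))
  rates <- rates[!is.na(rates)]
  isis <- unlist(lapply(recording$trains[act], diff), use.names = FALSE)

  bursts <- detect_bursts(recording, bp)
  total <- n_spikes(recording)
  if (total >= np$n_consecutive) {
    pooled <- flatten_recording(recording)
    nbs <- detect_network_bursts(pooled, np)
    diag <- attr(nbs, "diagnostics")
  } else {
    nbs <- detect_network_bursts(numeric(0), np, threshold = np$fallback_threshold)
    diag <- NULL
  }
  series <- if (total > 0 && length(act) > 0 && recording$duration >= width) {
    instantaneous_rate(recording, width = width, step = step,
                       min_active_rate = min_active_rate)
  } else NULL
  bi <- if (!is.null(series)) burstiness_index(series) else NA_real_
  comp <- burst_composition(recording, bursts, nbs)

  out <- list(
    mean_firing_rate = if (length(rates)) mean(rates) else NA_real_,
    mean_isi = if (length(isis)) mean(isis) else NA_real_,
    burstiness_index = as.numeric(bi),
    f15 = attr(bi, "f15") %||% NA_real_,
    coherence_index = if (!is.null(series)) coherence_index(series)
                      else NA_real_,
    mean_burst_duration = comp$mean_burst_duration,
    mean_ibi = comp$mean_ibi,
    mean_nibi = comp$mean_nibi,
    frac_spikes_in_bursts = comp$frac_spikes_in_bursts,
    frac_spikes_in_network_bursts = comp$frac_spikes_in_network_bursts,
    n_bursts = comp$n_bursts,
    n_network_bursts = comp$n_network_bursts,
    adaptive_threshold = if (!is.null(diag)) diag$threshold else NA_real_,
    threshold_fallback = if (!is.null(diag)) diag$fallback_used else NA,
    bursts = bursts, network_bursts = nbs, threshold_diagnostics = diag,
    spikes_per_burst = comp$spikes_per_burst,
    spikes_per_network_burst = comp$spikes_per_network_burst)
  class(out) <- "mea_metrics"
  out
}

#' @export
print.mea_metrics <- function(x, ...) {
  cat("<mea_metrics>\n")
  scalars <- c("mean_firing_rate", "mean_isi", "burstiness_index",
               "coherence_index", "mean_burst_duration", "mean_ibi",
               "mean_nibi", "frac_spikes_in_bursts",
               "frac_spikes_in_network_bursts", "n_bursts",
               "n_network_bursts", "adaptive_threshold")
  for (s in scalars) {
    cat(sprintf("  %-30s %s\n", s, format(x[[s]], digits = 4)))
  }
  invisible(x)
}

#' Long-format table of scalar metrics
#'
#' @param metrics An `mea_metrics` object from [compute_metrics()].
#' @param recording_id Identifier for the `recording_id` column.
#' @return Data.frame `recording_id,metric,value`.
#' @export
metrics_long <- function(metrics, recording_id = "recording") {
  scalars <- c("mean_firing_rate", "mean_isi", "burstiness_index", "f15",
               "coherence_index", "mean_burst_duration", "mean_ibi",
               "mean_nibi", "frac_spikes_in_bursts",
               "frac_spikes_in_network_bursts", "n_bursts",
               "n_network_bursts", "adaptive_threshold")
  data.frame(recording_id = recording_id, metric = scalars,
             value = vapply(scalars, function(s) as.numeric(metrics[[s]]),
                            numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
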