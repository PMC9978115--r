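#' Per-electrode burst detection parameters
#'
#' A burst is a maximal run of at least `min_spikes` consecutive spikes on
#' one electrode in which every inter-spike interval is strictly below
#' `isi_threshold`. Defaults are the standard fixed-threshold settings:
#' 100 ms and 4 spikes.
#'
#' @param isi_threshold ISI threshold in seconds (> 0), default 0.100.
#' @param min_spikes Minimum spikes per burst (>= 2), default 4.
#' @return A list of class `mea_burst_params`.
#' @export
burst_params <- function(isi_threshold = 0.100, min_spikes = 4L) {
  stopifnot_scalar_number(isi_threshold, "isi_threshold",
                          min = .Machine$double.eps)
  stopifnot_scalar_number(min_spikes, "min_spikes", min = 2)
  structure(list(isi_threshold = isi_threshold,
                 min_spikes = as.integer(min_spikes)),
            class = "mea_burst_params")
}

#' Network-burst detection parameters
#'
#' Network bursts are detected on the flattened (pooled) spike train via the
#' span of `n_consecutive` consecutive spikes (ISI_N with N = 6 by default).
#' The threshold on that span is adapted per recording from the log-binned
#' ISI_N histogram (see [adaptive_isi_threshold()]) and clamped to
#' `[threshold_min, threshold_max]` (12–300 ms by default); a candidate
#' network burst must contain at least `min_spikes_nb` spikes (6).
#'
#' @param n_consecutive Number of consecutive pooled spikes whose span is
#'   thresholded (default 6).
#' @param threshold_min,threshold_max Clamp bounds on the adaptive threshold,
#'   seconds (defaults 0.012 and 0.300).
#' @param min_spikes_nb Minimum spikes per network burst (default 6).
#' @param bins_per_decade Log10 histogram resolution (default 10).
#' @param smoothing_width Centred moving-average width in bins (default 3).
#' @param min_prominence Minimum peak height as a fraction of the tallest
#'   smoothed bin (default 0.05).
#' @param fallback_threshold Threshold used when the histogram does not show
#'   two peaks (default 0.100 s, the per-electrode ISI threshold).
#' @return A list of class `mea_nb_params`.
#' @export
nb_params <- function(n_consecutive = 6L, threshold_min = 0.012,
                      threshold_max = 0.300, min_spikes_nb = 6L,
                      bins_per_decade = 10L, smoothing_width = 3L,
                      min_prominence = 0.05, fallback_threshold = 0.100) {
  stopifnot(threshold_min < threshold_max, min_spikes_nb >= n_consecutive)
  structure(list(n_consecutive = as.integer(n_consecutive),
                 threshold_min = threshold_min, threshold_max = threshold_max,
                 min_spikes_nb = as.integer(min_spikes_nb),
                 bins_per_decade = as.integer(bins_per_decade),
                 smoothing_width = as.integer(smoothing_width),
                 min_prominence = min_prominence,
                 fallback_threshold = fallback_threshold),
            class = "mea_nb_params")
}

# Core single-train burst scan. Runs of gaps strictly below the threshold are
# found with rle(); a run of g qualifying gaps spans g+1 spikes.
detect_bursts_times <- function(times, params) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0), duration_s = numeric(0))
  n <- length(times)
  if (n < params$min_spikes) return(empty)
  ok <- diff(times) < params$isi_threshold
  r <- rle(ok)
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  sel <- r$values & r$lengths >= (params$min_spikes - 1L)
  if (!any(sel)) return(empty)
  i0 <- run_starts[sel]            # first gap index -> first spike index
  i1 <- run_ends[sel] + 1L         # last spike index
  data.frame(start_s = times[i0], end_s = times[i1],
             n_spikes = i1 - i0 + 1L, duration_s = times[i1] - times[i0])
}

#' Detect per-electrode bursts
#'
#' Finds, on each electrode's own spike train, every maximal run of at least
#' `min_spikes` spikes whose inter-spike intervals are all strictly below
#' `isi_threshold`. Burst boundaries are the first and last member spikes.
#'
#' @param x An [mea_recording()], or a sorted numeric vector of spike times
#'   for a single train.
#' @param params A [burst_params()] object.
#' @return A data.frame with columns `electrode` (absent for a bare numeric
#'   train), `start_s`, `end_s`, `n_spikes`, `duration_s`; one row per burst,
#'   ordered in time, non-overlapping within an electrode.
#' @examples
#' detect_bursts(c(0, 0.05, 0.10, 0.15), burst_params())
#' @export
detect_bursts <- function(x, params = burst_params()) {
  stopifnot(inherits(params, "mea_burst_params"))
  if (is.numeric(x)) {
    return(detect_bursts_times(as.numeric(x), params))
  }
  stopifnot(inherits(x, "mea_recording"))
  per <- lapply(names(x$trains), function(id) {
    b <- detect_bursts_times(x$trains[[id]], params)
    if (nrow(b)) cbind(electrode = id, b, stringsAsFactors = FALSE) else NULL
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per)) {
    return(data.frame(electrode = character(0), start_s = numeric(0),
                      end_s = numeric(0), n_spikes = integer(0),
                      duration_s = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, per)
}

# Span of n consecutive pooled spikes: isi_n[i] = t[i+n-1] - t[i].
isi_n <- function(times, n) {
  m <- length(times) - n + 1L
  if (m < 1L) return(numeric(0))
  times[seq.int(n, length(times))] - times[seq_len(m)]
}

#' Adapt the network-burst threshold from the log ISI_N histogram
#'
#' Computes the spans of `n_consecutive` consecutive spikes on the flattened
#' train, bins their base-10 logarithms (`bins_per_decade` bins per decade,
#' padded one empty bin on each side), smooths the counts with a centred
#' moving average, and finds local maxima with a minimum prominence. In the
#' typical bimodal histogram the low-span peak is the intra-burst mode and
#' the tallest peak at strictly larger span is the background mode; the
#' threshold is their geometric mean (the midpoint on the log scale), clamped
#' to `[threshold_min, threshold_max]`. When fewer than two such peaks exist
#' the fixed `fallback_threshold` is used and flagged.
#'
#' @param pooled An `mea_pooled` data.frame from [flatten_recording()], or a
#'   sorted numeric vector of pooled spike times.
#' @param params An [nb_params()] object.
#' @return A list of class `mea_threshold_diag`: `threshold` (seconds),
#'   `fallback_used`, `peaks` (seconds, all detected peak locations),
#'   `breaks` and `counts` (smoothed) of the log10 histogram, and
#'   `n_intervals`.
#' @export
adaptive_isi_threshold <- function(pooled, params = nb_params()) {
  stopifnot(inherits(params, "mea_nb_params"))
  times <- if (is.numeric(pooled)) as.numeric(pooled) else pooled$time
  if (length(times) < params$n_consecutive) {
    stop("pooled train has fewer spikes than one ISI_N window", call. = FALSE)
  }
  spans <- isi_n(times, params$n_consecutive)
  pos <- spans[spans > 0]      # zero spans (cross-electrode ties) have no log
  diag_out <- function(threshold, fallback, peaks = numeric(0),
                       breaks = numeric(0), counts = numeric(0)) {
    structure(list(threshold = threshold, fallback_used = fallback,
                   peaks = peaks, breaks = breaks, counts = counts,
                   n_intervals = length(spans)),
              class = "mea_threshold_diag")
  }
  if (length(pos) < 2L) {
    return(diag_out(params$fallback_threshold, TRUE))
  }
  w <- 1 / params$bins_per_decade
  lo <- floor(min(log10(pos)) / w) * w - w
  hi <- ceiling(max(log10(pos)) / w) * w + w
  breaks <- seq(lo, hi, by = w)
  counts <- graphics::hist(log10(pos), breaks = breaks, plot = FALSE)$counts
  k <- params$smoothing_width
  sm <- as.numeric(stats::filter(counts, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- 0
  centers <- breaks[-length(breaks)] + w / 2
  # local maxima with minimum prominence; ">=" on the right so the left edge
  # of a flat-topped (smoothed) peak still registers
  is_peak <- rep(FALSE, length(sm))
  if (length(sm) >= 3) {
    interior <- 2:(length(sm) - 1)
    is_peak[interior] <- sm[interior] > sm[interior - 1] &
      sm[interior] >= sm[interior + 1] &
      sm[interior] >= params$min_prominence * max(sm)
  }
  peak_pos <- 10^centers[is_peak]
  peak_height <- sm[is_peak]
  if (length(peak_pos) < 2L) {
    return(diag_out(params$fallback_threshold, TRUE, peaks = peak_pos,
                    breaks = breaks, counts = sm))
  }
  p_low <- peak_pos[1]                       # intra-burst mode
  upper_idx <- which(peak_pos > p_low)
  p_high <- peak_pos[upper_idx][which.max(peak_height[upper_idx])]
  thr <- sqrt(p_low * p_high)                # log-scale midpoint
  thr <- min(max(thr, params$threshold_min), params$threshold_max)
  diag_out(thr, FALSE, peaks = peak_pos, breaks = breaks, counts = sm)
}

#' @export
print.mea_threshold_diag <- function(x, ...) {
  cat(sprintf("<mea_threshold_diag> threshold = %.1f ms%s; %d peak(s), %d ISI_N intervals\n",
              1000 * x$threshold, if (x$fallback_used) " (fallback)" else "",
              length(x$peaks), x$n_intervals))
  invisible(x)
}

#' Detect network bursts on the flattened spike train
#'
#' Every position `i` in the pooled train whose span of `n_consecutive`
#' spikes is strictly below the threshold marks spikes `i ... i+n-1` as
#' in-burst; maximal unions of overlapping marked blocks form candidate
#' network bursts, and candidates with at least `min_spikes_nb` spikes are
#' returned with their electrode participation.
#'
#' @param pooled An `mea_pooled` data.frame from [flatten_recording()].
#' @param params An [nb_params()] object.
#' @param threshold Threshold in seconds; if `NULL` (default) it is adapted
#'   from the data via [adaptive_isi_threshold()].
#' @return A data.frame with columns `start_s`, `end_s`, `n_spikes`,
#'   `n_electrodes`, `duration_s`; the chosen threshold diagnostics are
#'   attached as attribute `"diagnostics"`.
#' @export
detect_network_bursts <- function(pooled, params = nb_params(),
                                  threshold = NULL) {
  stopifnot(inherits(params, "mea_nb_params"))
  if (is.numeric(pooled)) {
    pooled <- data.frame(time = as.numeric(pooled),
                         electrode = rep("E1", length(pooled)),
                         stringsAsFactors = FALSE)
  }
  diag <- NULL
  if (is.null(threshold)) {
    diag <- adaptive_isi_threshold(pooled, params)
    threshold <- diag$threshold
  }
  times <- pooled$time
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0), n_electrodes = integer(0),
                      duration_s = numeric(0))
  n <- params$n_consecutive
  if (length(times) < n) {
    attr(empty, "diagnostics") <- diag
    return(empty)
  }
  marked <- which(isi_n(times, n) < threshold)   # strict: "lower than"
  if (!length(marked)) {
    attr(empty, "diagnostics") <- diag
    return(empty)
  }
  # merge marked blocks [i, i+n-1] that overlap in spike indices
  starts <- marked
  ends <- marked + n - 1L
  new_block <- c(TRUE, starts[-1] > utils::head(ends, -1))
  grp <- cumsum(new_block)
  b_start <- tapply(starts, grp, min)
  b_end <- tapply(ends, grp, max)
  n_sp <- b_end - b_start + 1L
  keep <- n_sp >= params$min_spikes_nb
  b_start <- b_start[keep]; b_end <- b_end[keep]; n_sp <- n_sp[keep]
  if (!length(b_start)) {
    attr(empty, "diagnostics") <- diag
    return(empty)
  }
  n_el <- mapply(function(a, b) length(unique(pooled$electrode[a:b])),
                 b_start, b_end)
  out <- data.frame(start_s = times[b_start], end_s = times[b_end],
                    n_spikes = as.integer(n_sp), n_electrodes = as.integer(n_el),
                    duration_s = times[b_end] - times[b_start])
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diag
  out
}

interval_jaccard <- function(a1, a2, b1, b2) {
  inter <- pmax(0, pmin(a2, b2) - pmax(a1, b1))
  uni <- pmax(a2, b2) - pmin(a1, b1)
  ifelse(uni > 0, inter / uni, as.numeric(a1 == b1 & a2 == b2))
}

#' Score detected events against planted ground truth
#'
#' Greedy one-to-one matching of detected to true intervals by descending
#' Jaccard overlap; a pair counts as a match when its Jaccard index reaches
#' `min_overlap`. With zero detections precision is reported as 1 by
#' convention and flagged.
#'
#' @param detected Data.frame with `start_s`, `end_s` (e.g. from
#'   [detect_network_bursts()]).
#' @param truth Data.frame with `start_s`, `end_s` (e.g.
#'   `truth$network_bursts` from [simulate_recording()]).
#' @param min_overlap Minimum Jaccard index in (0, 1\] (default 0.5).
#' @return A list: `precision`, `recall`, `n_matched`, `n_detected`,
#'   `n_true`, `precision_undefined` (TRUE when there were no detections).
#' @export
match_events <- function(detected, truth, min_overlap = 0.5) {
  stopifnot_scalar_number(min_overlap, "min_overlap",
                          min = .Machine$double.eps, max = 1)
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L) {
    return(list(precision = 1, recall = if (nt == 0L) 1 else 0,
                n_matched = 0L, n_detected = 0L, n_true = nt,
                precision_undefined = TRUE))
  }
  if (nt == 0L) {
    return(list(precision = 0, recall = 1, n_matched = 0L, n_detected = nd,
                n_true = 0L, precision_undefined = FALSE))
  }
  pairs <- expand.grid(d = seq_len(nd), t = seq_len(nt))
  pairs$j <- interval_jaccard(detected$start_s[pairs$d], detected$end_s[pairs$d],
                              truth$start_s[pairs$t], truth$end_s[pairs$t])
  pairs <- pairs[pairs$j >= min_overlap, , drop = FALSE]
  pairs <- pairs[order(-pairs$j), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt); matched <- 0L
  for (i in seq_len(nrow(pairs))) {
    di <- pairs$d[i]; ti <- pairs$t[i]
    if (!used_d[di] && !used_t[ti]) {
      used_d[di] <- TRUE; used_t[ti] <- TRUE; matched <- matched + 1L
    }
  }
  list(precision = matched / nd, recall = matched / nt,
       n_matched = matched, n_detected = nd, n_true = nt,
       precision_undefined = FALSE)
}
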