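#' Simulation parameters for a synthetic MEA recording
#'
#' Parameter set for [simulate_recording()]. The generator superimposes, per
#' electrode, homogeneous-Poisson background firing and synchronized network
#' bursts: burst onsets form a Poisson process (thinned so consecutive onsets
#' are at least two expected burst spans apart, keeping planted events
#' unambiguous), each onset recruits `ceiling(participation * n_electrodes)`
#' electrodes drawn uniformly without replacement, and each recruited
#' electrode emits a Poisson-count cluster of spikes with exponential
#' intra-burst intervals starting at the onset plus Gaussian jitter.
#'
#' Defaults describe one 20-min recording of a mature 64-electrode culture.
#'
#' @param n_electrodes Number of electrodes (default 64, one MEA well).
#' @param duration Recording length in seconds (default 1200 s = 20 min).
#' @param bg_rate Background firing rate per electrode, Hz.
#' @param nb_rate Network-burst onset rate, events per second.
#' @param participation Fraction of electrodes recruited per network burst,
#'   in \[0, 1\].
#' @param onset_jitter_sd Per-electrode Gaussian jitter of burst onset,
#'   seconds.
#' @param spikes_per_burst_mean Expected spikes per participating electrode
#'   per network burst (Poisson, floored at 1).
#' @param intra_burst_isi_mean Mean intra-burst inter-spike interval, seconds
#'   (exponential, truncated below at `refractory_s`).
#' @param refractory_s Refractory floor on intra-burst intervals, seconds.
#' @param inhibition_factor Rate multiplier in \[0, 1\] applied to both
#'   background and network-burst rates inside `inhibition_interval`
#'   (1 = no inhibition).
#' @param inhibition_interval Length-2 numeric `(start_s, end_s)` or `NULL`.
#' @param recovery_interval Optional length-2 numeric: after inhibition the
#'   multiplier ramps linearly from `inhibition_factor` back to 1 over this
#'   interval.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A list of class `mea_sim_params`.
#' @seealso [mea_scenario()] for named presets.
#' @export
sim_params <- function(n_electrodes = 64, duration = 1200,
                       bg_rate = 0.5, nb_rate = 0.05, participation = 0.6,
                       onset_jitter_sd = 0.005, spikes_per_burst_mean = 12,
                       intra_burst_isi_mean = 0.004, refractory_s = 0.001,
                       inhibition_factor = 1, inhibition_interval = NULL,
                       recovery_interval = NULL, seed = 1L) {
  stopifnot_scalar_number(n_electrodes, "n_electrodes", min = 1)
  stopifnot_scalar_number(duration, "duration", min = .Machine$double.eps)
  stopifnot_scalar_number(bg_rate, "bg_rate", min = 0)
  stopifnot_scalar_number(nb_rate, "nb_rate", min = 0)
  stopifnot_scalar_number(participation, "participation", min = 0, max = 1)
  stopifnot_scalar_number(onset_jitter_sd, "onset_jitter_sd", min = 0)
  stopifnot_scalar_number(inhibition_factor, "inhibition_factor",
                          min = 0, max = 1)
  p <- list(n_electrodes = as.integer(n_electrodes), duration = duration,
            bg_rate = bg_rate, nb_rate = nb_rate,
            participation = participation,
            onset_jitter_sd = onset_jitter_sd,
            spikes_per_burst_mean = spikes_per_burst_mean,
            intra_burst_isi_mean = intra_burst_isi_mean,
            refractory_s = refractory_s,
            inhibition_factor = inhibition_factor,
            inhibition_interval = inhibition_interval,
            recovery_interval = recovery_interval,
            seed = as.integer(seed))
  class(p) <- "mea_sim_params"
  p
}

#' Named simulation presets
#'
#' Preset parameter sets spanning the activity regimes seen across in vitro
#' network development: `"asynchronous-tonic"` (uncorrelated tonic firing,
#' no network bursts — an immature culture), `"mature-bursting"` (regular
#' network bursts over moderate background), and `"hypersynchronous"`
#' (frequent, near-global, tightly locked network bursts carrying most
#' spikes). Participation and burst rate increase strictly along that ladder.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [sim_params()].
#' @return An `mea_sim_params` object.
#' @export
mea_scenario <- function(name = c("asynchronous-tonic", "mature-bursting",
                                  "hypersynchronous"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "asynchronous-tonic" = list(bg_rate = 2, nb_rate = 0, participation = 0),
    "mature-bursting" = list(bg_rate = 0.5, nb_rate = 0.05,
                             participation = 0.6, spikes_per_burst_mean = 12,
                             onset_jitter_sd = 0.005,
                             intra_burst_isi_mean = 0.004),
    "hypersynchronous" = list(bg_rate = 0.2, nb_rate = 0.15,
                              participation = 0.95,
                              spikes_per_burst_mean = 20,
                              onset_jitter_sd = 0.003,
                              intra_burst_isi_mean = 0.003))
  do.call(sim_params, utils::modifyList(base, list(...)))
}

# Time-varying rate multiplier: inhibition_factor inside the inhibition
# interval, a linear ramp back to 1 across the recovery interval, 1 elsewhere.
rate_multiplier <- function(t, params) {
  m <- rep(1, length(t))
  iv <- params$inhibition_interval
  if (!is.null(iv) && params$inhibition_factor < 1) {
    m[t >= iv[1] & t < iv[2]] <- params$inhibition_factor
    rv <- params$recovery_interval
    if (!is.null(rv)) {
      in_r <- t >= rv[1] & t < rv[2]
      frac <- (t[in_r] - rv[1]) / (rv[2] - rv[1])
      m[in_r] <- params$inhibition_factor + frac * (1 - params$inhibition_factor)
    }
  }
  m
}

#' Simulate a synthetic MEA recording with planted ground truth
#'
#' Generates spikes under the model described in [sim_params()] and returns
#' both the recording and the ground truth of every planted event, so burst
#' and network-burst detectors can be scored by interval matching.
#'
#' Randomness is hierarchical: every electrode's background train and every
#' event's spikes draw from child streams of `params$seed`, so enlarging the
#' array adds trains without perturbing existing ones. Spikes falling outside
#' `[0, duration)` are clipped. If the expected burst span is large relative
#' to the burst spacing the events may overlap; this raises a warning, not an
#' error.
#'
#' @param params An [sim_params()] object.
#' @return A list with elements `recording` ([mea_recording()]) and `truth`,
#'   a list with `network_bursts` (data.frame `event,start_s,end_s,n_spikes,`
#'   `n_electrodes,electrodes`) and `electrode_bursts` (data.frame
#'   `event,electrode,start_s,end_s,n_spikes`).
#' @examples
#' sim <- simulate_recording(sim_params(n_electrodes = 8, duration = 60,
#'                                      seed = 42))
#' sim$recording
#' nrow(sim$truth$network_bursts)
#' @export
simulate_recording <- function(params) {
  stopifnot(inherits(params, "mea_sim_params"))
  d <- params$duration
  ne <- params$n_electrodes
  ids <- sprintf("E%02d", seq_len(ne))

  expected_span <- params$spikes_per_burst_mean * params$intra_burst_isi_mean
  min_spacing <- 2 * expected_span
  if (params$nb_rate > 0 && min_spacing * params$nb_rate > 0.5) {
    warning("expected burst span is large relative to burst spacing; ",
            "planted events may crowd", call. = FALSE)
  }

  # Background: per-electrode homogeneous Poisson, thinned by the
  # time-varying inhibition multiplier.
  trains <- vector("list", ne)
  names(trains) <- ids
  for (e in seq_len(ne)) {
    trains[[e]] <- with_seed(derive_seed(params$seed, 1L, e), {
      n_bg <- stats::rpois(1, params$bg_rate * d)
      t_bg <- sort(stats::runif(n_bg, 0, d))
      keep <- stats::runif(n_bg) < rate_multiplier(t_bg, params)
      t_bg[keep]
    })
  }

  # Network-burst onsets: Poisson process thinned to a minimum spacing of
  # two expected burst spans, then thinned again by the inhibition
  # multiplier.
  onsets <- with_seed(derive_seed(params$seed, 2L), {
    n_on <- stats::rpois(1, params$nb_rate * d)
    on <- sort(stats::runif(n_on, 0, d))
    if (length(on) > 1 && min_spacing > 0) {
      keep <- rep(TRUE, length(on))
      last <- on[1]
      for (i in seq_along(on)[-1]) {
        if (on[i] - last < min_spacing) keep[i] <- FALSE else last <- on[i]
      }
      on <- on[keep]
    }
    on[stats::runif(length(on)) < rate_multiplier(on, params)]
  })

  n_recruit <- ceiling(params$participation * ne)
  nb_rows <- list()
  eb_rows <- list()
  if (length(onsets) > 0 && n_recruit > 0) {
    for (k in seq_along(onsets)) {
      members <- with_seed(derive_seed(params$seed, 3L, k),
                           sort(sample.int(ne, n_recruit)))
      ev_start <- Inf; ev_end <- -Inf; ev_n <- 0L
      for (e in members) {
        sp <- with_seed(derive_seed(params$seed, 4L, k, e), {
          n_sp <- max(1L, stats::rpois(1, params$spikes_per_burst_mean))
          isis <- if (n_sp > 1) {
            pmax(params$refractory_s,
                 stats::rexp(n_sp - 1, 1 / params$intra_burst_isi_mean))
          } else numeric(0)
          start <- onsets[k] + stats::rnorm(1, 0, params$onset_jitter_sd)
          start + c(0, cumsum(isis))
        })
        sp <- sp[sp >= 0 & sp < d]
        if (length(sp) == 0) next
        trains[[e]] <- c(trains[[e]], sp)
        eb_rows[[length(eb_rows) + 1L]] <- data.frame(
          event = k, electrode = ids[e], start_s = min(sp), end_s = max(sp),
          n_spikes = length(sp), stringsAsFactors = FALSE)
        ev_start <- min(ev_start, min(sp)); ev_end <- max(ev_end, max(sp))
        ev_n <- ev_n + length(sp)
      }
      if (ev_n > 0L) {
        nb_rows[[length(nb_rows) + 1L]] <- data.frame(
          event = k, start_s = ev_start, end_s = ev_end, n_spikes = ev_n,
          n_electrodes = length(members),
          electrodes = paste(ids[members], collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  trains <- lapply(trains, sort)

  empty_nb <- data.frame(event = integer(0), start_s = numeric(0),
                         end_s = numeric(0), n_spikes = integer(0),
                         n_electrodes = integer(0), electrodes = character(0),
                         stringsAsFactors = FALSE)
  empty_eb <- data.frame(event = integer(0), electrode = character(0),
                         start_s = numeric(0), end_s = numeric(0),
                         n_spikes = integer(0), stringsAsFactors = FALSE)
  truth <- list(
    network_bursts = if (length(nb_rows)) do.call(rbind, nb_rows) else empty_nb,
    electrode_bursts = if (length(eb_rows)) do.call(rbind, eb_rows) else empty_eb)

  rec <- suppressWarnings(
    mea_recording(trains, duration = d,
                  metadata = list(simulated = TRUE, seed = params$seed)))
  list(recording = rec, truth = truth)
}

#' Thin spikes inside an interval (chemogenetic-style inhibition)
#'
#' Models the operational effect of silencing on recorded activity: every
#' spike inside `interval` is independently retained with probability
#' `keep_prob`; spikes outside are untouched. This is spike thinning, not a
#' mechanistic membrane model.
#'
#' @param recording An [mea_recording()].
#' @param interval Length-2 numeric `(start_s, end_s)`.
#' @param keep_prob Retention probability in \[0, 1\].
#' @param seed Integer seed for the thinning draws.
#' @return A new [mea_recording()].
#' @export
apply_inhibition <- function(recording, interval, keep_prob, seed = 1L) {
  stopifnot_scalar_number(keep_prob, "keep_prob", min = 0, max = 1)
  stopifnot(length(interval) == 2, interval[2] > interval[1])
  trains <- recording$trains
  for (e in seq_along(trains)) {
    t <- trains[[e]]
    inside <- t >= interval[1] & t < interval[2]
    if (!any(inside)) next
    keep <- with_seed(derive_seed(seed, 5L, e),
                      stats::runif(sum(inside)) < keep_prob)
    drop_idx <- which(inside)[!keep]
    if (length(drop_idx)) trains[[e]] <- t[-drop_idx]
  }
  meta <- recording$metadata
  meta$inhibition <- list(interval = interval, keep_prob = keep_prob)
  mea_recording(trains, duration = recording$duration, metadata = meta)
}
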