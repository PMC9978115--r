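#' Construct an MEA recording
#'
#' A recording bundles the spike trains of one well: a named list of
#' per-electrode spike-time vectors (seconds, sorted strictly ascending), the
#' recording duration, and free-form metadata (condition label, day in vitro,
#' phase label, ...).
#'
#' @param trains Named list of numeric vectors; each element is one
#'   electrode's spike times in seconds. Names are electrode identifiers and
#'   must be unique. Duplicate timestamps within an electrode are collapsed
#'   with a warning (a single electrode cannot fire twice at one instant).
#' @param duration Recording duration in seconds (> 0). If `NULL`, the last
#'   spike time is used and `metadata$duration_inferred` is set.
#' @param metadata Named list of recording-level metadata. Conventional keys:
#'   `condition` (e.g. `"CTRL"`, `"PBS"`, `"DCZ"`), `div` (day in vitro),
#'   `phase` (e.g. `"baseline"`, `"treatment_1"`).
#' @return An object of class `mea_recording`.
#' @examples
#' rec <- mea_recording(list(E1 = c(0.2, 0.5), E2 = 0.3), duration = 1)
#' n_spikes(rec)
#' @export
mea_recording <- function(trains, duration = NULL, metadata = list()) {
  if (is.null(names(trains)) && length(trains) > 0) {
    names(trains) <- paste0("E", seq_along(trains))
  }
  if (anyDuplicated(names(trains))) {
    stop("electrode identifiers must be unique", call. = FALSE)
  }
  trains <- lapply(trains, function(t) {
    t <- as.numeric(t)
    if (any(t < 0)) stop("spike times must be >= 0", call. = FALSE)
    t <- sort(t)
    if (anyDuplicated(t)) {
      warning("duplicate spike timestamps on one electrode collapsed",
              call. = FALSE)
      t <- unique(t)
    }
    t
  })
  last <- if (length(trains)) suppressWarnings(max(vapply(
    trains, function(t) if (length(t)) max(t) else -Inf, numeric(1)))) else -Inf
  if (is.null(duration)) {
    if (!is.finite(last)) {
      stop("duration must be given for a recording with no spikes",
           call. = FALSE)
    }
    duration <- last
    metadata$duration_inferred <- TRUE
  }
  stopifnot_scalar_number(duration, "duration", min = .Machine$double.eps)
  if (is.finite(last) && last > duration) {
    stop("spike times exceed the stated recording duration", call. = FALSE)
  }
  structure(list(trains = trains, duration = duration, metadata = metadata),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d electrodes, %d spikes, %.1f s\n",
              length(x$trains), n_spikes(x), x$duration))
  meta <- x$metadata[setdiff(names(x$metadata), "duration_inferred")]
  if (length(meta)) {
    cat("  metadata:", paste(names(meta), unlist(lapply(meta, format)),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Total spike count of a recording
#' @param recording An [mea_recording()].
#' @return Integer spike count over all electrodes.
#' @export
n_spikes <- function(recording) {
  sum(lengths(recording$trains))
}

#' Read a spike-time table
#'
#' Reads a columnar text file with one row per spike: an electrode identifier
#' column and a spike-time column in seconds (header `electrode,time_s` by
#' default). Times are sorted and deduplicated per electrode.
#'
#' @param path Path to a delimited text file.
#' @param duration Recording duration in seconds; if missing it is inferred
#'   as the last spike time and flagged in the metadata.
#' @param electrode_col,time_col Column names to use.
#' @param sep Field separator.
#' @return An [mea_recording()].
#' @export
read_spike_table <- function(path, duration = NULL,
                             electrode_col = "electrode",
                             time_col = "time_s", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(electrode_col, time_col), names(df))
  if (length(missing_cols)) {
    stop(sprintf("spike table %s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    if (is.null(duration)) {
      stop("empty spike table and no duration given", call. = FALSE)
    }
    return(mea_recording(list(), duration = duration))
  }
  if (any(df[[time_col]] < 0)) {
    stop("negative spike time in ", path, call. = FALSE)
  }
  trains <- split(as.numeric(df[[time_col]]), as.character(df[[electrode_col]]))
  mea_recording(trains, duration = duration)
}

#' Write a recording as a spike-time table
#'
#' Inverse of [read_spike_table()]: one row per spike with columns
#' `electrode,time_s`, electrodes in name order, times ascending.
#'
#' @param recording An [mea_recording()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_spike_table <- function(recording, path) {
  pooled <- flatten_recording(recording, require_spikes = FALSE)
  df <- data.frame(electrode = pooled$electrode, time_s = pooled$time)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pool all electrodes into one flattened spike train
#'
#' Merges every electrode's spikes into a single time-sorted train, keeping
#' electrode provenance. The adaptive network-burst threshold is computed on
#' this flattened train. Cross-electrode ties are kept and ordered stably by
#' electrode identifier.
#'
#' @param recording An [mea_recording()].
#' @param require_spikes Error if the recording has no spikes (default).
#' @return A data.frame of class `mea_pooled` with columns `time` (seconds,
#'   ascending) and `electrode` (character), plus a `duration` attribute.
#' @export
flatten_recording <- function(recording, require_spikes = TRUE) {
  total <- n_spikes(recording)
  if (require_spikes && total == 0L) {
    stop("recording contains no spikes", call. = FALSE)
  }
  ids <- names(recording$trains)
  time <- unlist(recording$trains, use.names = FALSE) %||% numeric(0)
  electrode <- rep(ids, lengths(recording$trains))
  ord <- order(time, electrode)
  out <- data.frame(time = time[ord], electrode = electrode[ord],
                    stringsAsFactors = FALSE)
  attr(out, "duration") <- recording$duration
  class(out) <- c("mea_pooled", "data.frame")
  out
}

#' Define a phase plan
#'
#' An ordered set of labelled half-open time intervals `[start_s, end_s)`
#' used to cut one continuous recording into protocol phases (e.g. a 1-h
#' treatment recording into three 20-min phases).
#'
#' @param label Character vector of phase labels.
#' @param start_s,end_s Numeric vectors of interval bounds in seconds.
#' @return A data.frame of class `mea_phase_plan`.
#' @examples
#' treatment_phase_plan()
#' @export
phase_plan <- function(label, start_s, end_s) {
  stopifnot(length(label) == length(start_s), length(label) == length(end_s))
  if (any(end_s <= start_s)) stop("phase end must exceed start", call. = FALSE)
  ord <- order(start_s)
  label <- as.character(label)[ord]
  start_s <- as.numeric(start_s)[ord]
  end_s <- as.numeric(end_s)[ord]
  if (any(utils::head(end_s, -1) > utils::tail(start_s, -1))) {
    stop("phase intervals overlap", call. = FALSE)
  }
  structure(data.frame(label = label, start_s = start_s, end_s = end_s,
                       stringsAsFactors = FALSE),
            class = c("mea_phase_plan", "data.frame"))
}

#' Standard treatment phase plan: three consecutive 20-min phases
#'
#' The 1-h treatment recording of the experimental protocol is divided
#' offline into three 20-min phases.
#'
#' @param phase_s Phase length in seconds (default 1200 = 20 min).
#' @param labels Phase labels.
#' @return An [phase_plan()] covering `[0, 3 * phase_s)`.
#' @export
treatment_phase_plan <- function(phase_s = 1200,
                                 labels = c("treatment_1", "treatment_2",
                                            "treatment_3")) {
  k <- length(labels)
  phase_plan(labels, start_s = phase_s * (seq_len(k) - 1),
             end_s = phase_s * seq_len(k))
}

#' Cut a recording into protocol phases
#'
#' Each phase gets its own recording: spikes in `[start_s, end_s)` (a spike
#' exactly on a boundary belongs to the later phase), re-zeroed to the phase
#' start, with the phase label stored in the metadata.
#'
#' @param recording An [mea_recording()].
#' @param plan A [phase_plan()]; must lie within the recording duration.
#' @return Named list of [mea_recording()], one per phase.
#' @export
segment_recording <- function(recording, plan) {
  if (!inherits(plan, "mea_phase_plan")) {
    stop("`plan` must be a phase_plan()", call. = FALSE)
  }
  if (max(plan$end_s) > recording$duration + 1e-9) {
    stop("phase plan extends beyond the recording duration", call. = FALSE)
  }
  out <- vector("list", nrow(plan))
  names(out) <- plan$label
  for (i in seq_len(nrow(plan))) {
    a <- plan$start_s[i]; b <- plan$end_s[i]
    trains <- lapply(recording$trains, function(t) t[t >= a & t < b] - a)
    meta <- recording$metadata
    meta$phase <- plan$label[i]
    out[[i]] <- mea_recording(trains, duration = b - a, metadata = meta)
  }
  out
}

#' Write result tables with a fixed schema
#'
#' Writes the standard output tables of the pipeline as CSV with a
#' deterministic column order, so that re-reading returns identical values.
#' Recognised tables: bursts (`electrode,start_s,end_s,n_spikes`), network
#' bursts (`start_s,end_s,n_spikes,n_electrodes`), long-format metrics
#' (`recording_id,metric,value`), comparisons.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written file paths.
#' @export
write_results <- function(tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  schemas <- list(
    bursts = c("electrode", "start_s", "end_s", "n_spikes"),
    network_bursts = c("start_s", "end_s", "n_spikes", "n_electrodes"),
    metrics = c("recording_id", "metric", "value")
  )
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    if (nm %in% names(schemas)) {
      missing_cols <- setdiff(schemas[[nm]], names(df))
      if (length(missing_cols)) {
        stop(sprintf("table '%s' lacks column(s): %s", nm,
                     paste(missing_cols, collapse = ", ")), call. = FALSE)
      }
      df <- df[, c(schemas[[nm]], setdiff(names(df), schemas[[nm]])),
               drop = FALSE]
    }
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths[nm] <- p
  }
  paths
}
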