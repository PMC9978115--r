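#' Build an experiment manifest
#'
#' One row per analysis unit: where the recording comes from (a spike-table
#' CSV path or a simulation preset name understood by [mea_scenario()]),
#' its condition, day in vitro, phase label, and replicate index. The
#' combination (condition, div, phase, replicate) must be unique.
#'
#' @param source Character vector: file paths or preset names.
#' @param condition,phase Character vectors.
#' @param div Integer vector (day in vitro).
#' @param replicate Integer vector.
#' @return Data.frame of class `mea_manifest`.
#' @export
experiment_manifest <- function(source, condition, div, phase, replicate) {
  df <- data.frame(source = as.character(source),
                   condition = as.character(condition),
                   div = as.integer(div), phase = as.character(phase),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  key <- interaction(df$condition, df$div, df$phase, df$replicate, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("(condition, div, phase, replicate) must be unique", call. = FALSE)
  }
  class(df) <- c("mea_manifest", "data.frame")
  df
}

#' Manifest shaped like the chemogenetic-inhibition study
#'
#' A convenience manifest with the study's group sizes — 6 DCZ-treated,
#' 5 PBS-vehicle and 6 untreated control networks (17 analysis units per
#' timepoint) — all simulated, by default at a single baseline timepoint.
#'
#' @param divs Days in vitro to include.
#' @param phases Phase labels to include.
#' @param n_dcz,n_pbs,n_ctrl Networks per condition.
#' @param scenarios Named character vector mapping condition to simulation
#'   preset.
#' @return An [experiment_manifest()].
#' @export
study_manifest <- function(divs = 21, phases = "baseline",
                           n_dcz = 6, n_pbs = 5, n_ctrl = 6,
                           scenarios = c(CTRL = "mature-bursting",
                                         PBS = "mature-bursting",
                                         DCZ = "hypersynchronous")) {
  reps <- c(rep("CTRL", n_ctrl), rep("PBS", n_pbs), rep("DCZ", n_dcz))
  idx <- c(seq_len(n_ctrl), seq_len(n_pbs), seq_len(n_dcz))
  grid <- expand.grid(i = seq_along(reps), div = divs, phase = phases,
                      stringsAsFactors = FALSE)
  experiment_manifest(source = scenarios[reps[grid$i]],
                      condition = reps[grid$i], div = grid$div,
                      phase = grid$phase, replicate = idx[grid$i])
}

load_or_simulate <- function(row, seed, sim_overrides) {
  presets <- c("asynchronous-tonic", "mature-bursting", "hypersynchronous")
  if (row$source %in% presets) {
    row_seed <- derive_seed(seed, as.integer(as.factor(row$condition))[1],
                            row$div, row$replicate,
                            utf8ToInt(substr(row$phase, 1, 1)))
    params <- do.call(mea_scenario,
                      c(list(name = row$source, seed = row_seed),
                        sim_overrides))
    rec <- simulate_recording(params)$recording
  } else {
    rec <- read_spike_table(row$source)
  }
  rec$metadata$condition <- row$condition
  rec$metadata$div <- row$div
  rec$metadata$phase <- row$phase
  rec
}

#' Run the full analysis over an experiment manifest
#'
#' For every manifest row: load or simulate the recording, optionally cut it
#' into protocol phases, detect bursts and network bursts (the adaptive
#' ISI_N threshold is re-estimated per phase), compute all metrics, then run
#' the normality-gated pairwise group comparison per metric and timepoint
#' (div x phase). All randomness derives from the single `seed`.
#'
#' @param manifest An [experiment_manifest()].
#' @param seed Integer master seed for all simulated rows.
#' @param phase_plan Optional [phase_plan()]: when given, every recording is
#'   segmented and each phase becomes its own analysis unit labelled
#'   `"<phase>/<plan label>"`.
#' @param sim_overrides Named list of [sim_params()] overrides applied to
#'   every simulated row (e.g. smaller `duration` for quick runs).
#' @param bp,np Detection parameter objects.
#' @param compare_metrics Metrics to feed the group comparison.
#' @param out_dir Optional output directory; when given, the metric table,
#'   comparison table and run log are written via [write_results()].
#' @param alpha Significance level for the comparisons.
#' @return A list: `metrics` (long data.frame `recording_id,condition,div,`
#'   `phase,replicate,metric,value`), `comparisons` (rows of
#'   [pairwise_compare()] plus `metric,div,phase`), `runlog` (per-recording
#'   provenance), and `paths` when `out_dir` was given.
#' @export
run_experiment <- function(manifest, seed = 1L, phase_plan = NULL,
                           sim_overrides = list(), bp = burst_params(),
                           np = nb_params(),
                           compare_metrics = c("mean_firing_rate",
                                               "burstiness_index",
                                               "coherence_index",
                                               "frac_spikes_in_bursts",
                                               "frac_spikes_in_network_bursts"),
                           out_dir = NULL, alpha = 0.05) {
  stopifnot(inherits(manifest, "mea_manifest"))
  metric_rows <- list()
  runlog <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    rec <- load_or_simulate(row, seed, sim_overrides)
    units <- if (is.null(phase_plan)) {
      stats::setNames(list(rec), row$phase)
    } else {
      segs <- segment_recording(rec, phase_plan)
      stats::setNames(segs, paste(row$phase, names(segs), sep = "/"))
    }
    for (ph in names(units)) {
      rid <- sprintf("%s_div%02d_%s_r%02d", row$condition, row$div, ph,
                     row$replicate)
      met <- compute_metrics(units[[ph]], bp = bp, np = np)
      long <- metrics_long(met, recording_id = rid)
      long$condition <- row$condition
      long$div <- row$div
      long$phase <- ph
      long$replicate <- row$replicate
      metric_rows[[rid]] <- long
      runlog[[rid]] <- list(
        recording_id = rid, source = row$source,
        n_spikes = n_spikes(units[[ph]]), duration_s = units[[ph]]$duration,
        isi_threshold = bp$isi_threshold, min_spikes = bp$min_spikes,
        adaptive_threshold = met$adaptive_threshold,
        threshold_fallback = met$threshold_fallback,
        package_version = as.character(utils::packageVersion("meaburst")))
    }
  }
  metrics <- do.call(rbind, metric_rows)
  rownames(metrics) <- NULL

  comp_rows <- list()
  sub <- metrics[metrics$metric %in% compare_metrics, , drop = FALSE]
  for (key in unique(paste(sub$div, sub$phase, sub$metric, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sl <- sub[sub$div == as.integer(parts[1]) & sub$phase == parts[2] &
                sub$metric == parts[3], , drop = FALSE]
    groups <- split(sl$value, sl$condition)
    groups <- lapply(groups, function(v) v[!is.na(v)])
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) < 2L) next
    res <- tryCatch(pairwise_compare(groups, alpha = alpha),
                    error = function(e) NULL)
    if (is.null(res)) next
    res$metric <- parts[3]
    res$div <- as.integer(parts[1])
    res$phase <- parts[2]
    comp_rows[[key]] <- res
  }
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame()
  rownames(comparisons) <- NULL

  out <- list(metrics = metrics, comparisons = comparisons, runlog = runlog)
  if (!is.null(out_dir)) {
    paths <- write_results(
      list(metrics = metrics[, c("recording_id", "metric", "value",
                                 "condition", "div", "phase", "replicate")],
           comparisons = comparisons), out_dir)
    log_path <- file.path(out_dir, "runlog.json")
    jsonlite::write_json(runlog, log_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$paths <- c(paths, runlog = log_path)
  }
  out
}

#' Per-group mean and standard error of the mean
#'
#' Summarizes a long metric table into per-(condition, div, phase, metric)
#' mean and SEM (`sd / sqrt(n)`; `NA` for a single observation).
#'
#' @param metrics Long data.frame as produced by [run_experiment()].
#' @return Data.frame `condition,div,phase,metric,n,mean,sem`.
#' @export
summarize_metrics <- function(metrics) {
  key <- paste(metrics$condition, metrics$div, metrics$phase, metrics$metric,
               sep = "\r")
  rows <- lapply(unique(key), function(k) {
    sl <- metrics[key == k, , drop = FALSE]
    v <- sl$value[!is.na(sl$value)]
    data.frame(condition = sl$condition[1], div = sl$div[1],
               phase = sl$phase[1], metric = sl$metric[1],
               n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
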