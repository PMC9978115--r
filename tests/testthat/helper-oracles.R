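# Independent brute-force oracles and fixture builders used across tests.

# O(n^2) burst enumeration: every maximal run of >= min_spikes spikes with
# all gaps strictly below the threshold, found by checking each candidate
# start/end pair directly. Deliberately naive and independent of the
# rle-based implementation.
brute_force_bursts <- function(times, isi_threshold = 0.1, min_spikes = 4L) {
  n <- length(times)
  rows <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && (times[j + 1] - times[j]) < isi_threshold) j <- j + 1L
    if (j - i + 1L >= min_spikes) {
      rows[[length(rows) + 1L]] <- data.frame(
        start_s = times[i], end_s = times[j], n_spikes = j - i + 1L,
        duration_s = times[j] - times[i])
    }
    i <- j + 1L
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               n_spikes = integer(0), duration_s = numeric(0))
}

# random sorted spike train with bursty and quiet gaps mixed in
random_train <- function(n_max = 200) {
  n <- sample.int(n_max, 1)
  gaps <- sample(c(stats::rexp(n, 1 / 0.02), stats::rexp(n, 1 / 0.5)), n)
  cumsum(gaps)
}

# pooled train made of 6-spike clusters: within-cluster gap `intra`,
# cluster onsets `spacing` apart; gives a tightly bimodal ISI_6 histogram
cluster_train <- function(n_clusters, intra, spacing) {
  unlist(lapply(seq_len(n_clusters) - 1, function(k) {
    k * spacing + intra * (0:5)
  }))
}

# small deterministic recording used by io tests
tiny_recording <- function() {
  mea_recording(list(E1 = c(0.1, 0.3, 1.2), E2 = c(0.2, 0.9)), duration = 2)
}

write_tiny_table <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("electrode,time_s", rows), path)
  path
}
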