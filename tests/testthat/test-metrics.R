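test_that("recording spike frequency follows f = (spikes - 1) / dt", {
  expect_equal(firing_rate(c(0, 1, 2, 3, 4)), 1)
  expect_equal(firing_rate(c(0, 10)), 0.1)
  expect_true(is.na(firing_rate(5)))
  expect_true(is.na(firing_rate(numeric(0))))

  # Poisson train at 2 Hz: estimated rate within 5%
  set.seed(13)
  t <- cumsum(stats::rexp(2000, 2))
  expect_lt(abs(firing_rate(t) - 2) / 2, 0.05)
})

test_that("instantaneous rate uses a 1 s window stepped by 0.1 s", {
  rec <- mea_recording(list(E1 = seq(0.05, 0.95, by = 0.1)), duration = 1)
  s <- instantaneous_rate(rec)
  expect_equal(attr(s, "width"), 1.0)
  expect_equal(attr(s, "step"), 0.1)
  expect_equal(nrow(s), 1L)       # duration == width: single window at 0
  expect_equal(s$value, 10)       # 10 spikes / (1 electrode * 1 s)

  # uniform lattice spikes give a perfectly flat series
  rec2 <- mea_recording(list(E1 = seq(0.05, 9.95, by = 0.1)), duration = 10)
  s2 <- instantaneous_rate(rec2)
  expect_equal(nrow(s2), 91L)     # starts 0, 0.1, ..., 9.0
  expect_true(all(s2$count == 10))

  # denominator is the fixed count of active electrodes of the recording
  rec3 <- mea_recording(list(A = seq(0.05, 9.95, by = 0.1),
                             B = seq(0.05, 9.95, by = 0.1)), duration = 10)
  expect_equal(attr(instantaneous_rate(rec3), "n_active"), 2L)
  expect_equal(unique(instantaneous_rate(rec3)$value), 10)

  # scale covariance: doubling times, width and step keeps every window
  # count and halves the rate values
  s4 <- instantaneous_rate(
    mea_recording(list(E1 = 2 * seq(0.05, 9.95, by = 0.1)), duration = 20),
    width = 2, step = 0.2)
  expect_equal(s4$count, s2$count)
  expect_equal(s4$value, s2$value / 2)

  # one spike in 20 s is 0.05 Hz, below the 0.1 Hz activity cut
  expect_error(instantaneous_rate(mea_recording(list(E1 = 0.5), duration = 20)),
               "no active electrodes")
})

test_that("burstiness index hits its exact extremes and bounds", {
  # uniform activity on a 20-window grid: f15 = 3/20 = 0.15, BI = 0 exactly
  rec_u <- mea_recording(list(E1 = seq(0.05, 2.85, by = 0.1)), duration = 2.9)
  s_u <- instantaneous_rate(rec_u)
  expect_equal(nrow(s_u), 20L)
  bi_u <- burstiness_index(s_u)
  expect_equal(as.numeric(bi_u), 0)
  expect_equal(attr(bi_u, "f15"), 0.15)

  # all spikes concentrated at one instant: f15 = 1, BI = 1 exactly
  rec_c <- mea_recording(list(E1 = rep(10.05, 1) + 1e-4 * (0:49)),
                         duration = 20)
  bi_c <- burstiness_index(instantaneous_rate(rec_c))
  expect_equal(as.numeric(bi_c), 1)

  # property: f15 in [0.15, 1] and BI in [0, 1] for random series
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(20:200, 1)
    series <- data.frame(window_start = seq_len(n) / 10,
                         count = stats::rpois(n, sample(1:20, 1)),
                         value = 0)
    if (sum(series$count) == 0) next
    bi <- burstiness_index(series)
    expect_gte(attr(bi, "f15"), 0.15)
    expect_lte(attr(bi, "f15"), 1)
    expect_gte(as.numeric(bi), 0)
    expect_lte(as.numeric(bi), 1)
  }

  # zero activity is undefined, not zero
  expect_true(is.na(burstiness_index(data.frame(count = c(0, 0, 0)))))
})

test_that("coherence index is the coefficient of variation of the series", {
  const <- data.frame(value = rep(4, 50))
  expect_equal(coherence_index(const), 0)
  two <- data.frame(value = c(0, 10))
  expect_equal(coherence_index(two), 1)   # mean 5, population SD 5
  expect_true(is.na(coherence_index(data.frame(value = c(0, 0)))))
})

test_that("burst composition statistics follow their definitions", {
  rec <- mea_recording(list(E1 = c(0, 0.05, 0.1, 0.5, 0.55, 0.6),
                            E2 = c(2, 3)), duration = 5)
  bursts <- data.frame(electrode = c("E1", "E1"), start_s = c(0, 0.5),
                       end_s = c(0.1, 0.6), n_spikes = c(3L, 3L))
  nbs <- data.frame(start_s = 0, end_s = 0.6, n_spikes = 6L,
                    n_electrodes = 1L)
  comp <- burst_composition(rec, bursts, nbs)
  expect_equal(comp$mean_ibi, 0.4)
  expect_equal(comp$mean_burst_duration, 0.1)
  expect_equal(comp$frac_spikes_in_bursts, 6 / 8)
  expect_equal(comp$frac_spikes_in_network_bursts, 6 / 8)
  expect_true(is.na(comp$mean_nibi))  # a single network burst has no NIBI

  # all spikes inside one network burst
  rec2 <- mea_recording(list(E1 = seq(0, 0.02, length.out = 8)), duration = 1)
  nb2 <- detect_network_bursts(flatten_recording(rec2), nb_params(),
                               threshold = 0.1)
  comp2 <- burst_composition(rec2, detect_bursts(rec2), nb2)
  expect_equal(comp2$frac_spikes_in_network_bursts, 1)

  # spikes-per-burst histogram matches planted per-event counts exactly
  sim <- simulate_recording(sim_params(n_electrodes = 12, duration = 300,
                                       bg_rate = 0, nb_rate = 0.05,
                                       participation = 1, seed = 6))
  met <- compute_metrics(sim$recording)
  truth_counts <- table(sim$truth$network_bursts$n_spikes)
  expect_equal(met$spikes_per_network_burst, truth_counts, ignore_attr = TRUE)
})

test_that("detection-dependent metrics inherit threshold monotonicity", {
  sim <- simulate_recording(sim_params(n_electrodes = 16, duration = 120,
                                       seed = 14))
  fracs <- vapply(c(0.2, 0.1, 0.05, 0.02), function(thr) {
    met <- compute_metrics(sim$recording,
                           bp = burst_params(isi_threshold = thr))
    met$frac_spikes_in_bursts
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("shift-invariant metrics ignore a common time offset", {
  sim <- simulate_recording(sim_params(n_electrodes = 12, duration = 120,
                                       seed = 23))
  rec <- sim$recording
  shifted <- mea_recording(lapply(rec$trains, function(t) t + 7),
                           duration = rec$duration + 7)
  a <- compute_metrics(rec)
  b <- compute_metrics(shifted)
  for (f in c("mean_firing_rate", "mean_isi", "mean_burst_duration",
              "mean_ibi", "mean_nibi", "frac_spikes_in_bursts",
              "frac_spikes_in_network_bursts", "n_bursts",
              "n_network_bursts", "adaptive_threshold")) {
    expect_equal(a[[f]], b[[f]], info = f)
  }
})
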