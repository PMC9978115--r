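test_that("fixed-threshold burst rule follows the printed definition", {
  bp <- burst_params()
  b <- detect_bursts(c(0, 0.05, 0.10, 0.15), bp)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_spikes, 4L)
  expect_equal(b$duration_s, 0.15)

  # three spikes never form a burst (minimum is four)
  expect_equal(nrow(detect_bursts(c(0, 0.05, 0.10), bp)), 0L)

  # a gap of exactly the threshold splits the run (strict inequality)
  b2 <- detect_bursts(c(0, 0.05, 0.20, 0.25, 0.30, 0.35), bp)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$start_s, 0.20)
  expect_equal(b2$end_s, 0.35)
  expect_equal(b2$n_spikes, 4L)

  expect_equal(nrow(detect_bursts(numeric(0), bp)), 0L)

  # per-electrode detection on a recording keeps provenance
  rec <- mea_recording(list(A = c(0, 0.05, 0.1, 0.15), B = c(5, 6)),
                       duration = 10)
  br <- detect_bursts(rec, bp)
  expect_equal(br$electrode, "A")
})

test_that("burst detector agrees with the brute-force oracle on random trains", {
  set.seed(17)
  bp <- burst_params()
  for (rep in 1:200) {
    t <- random_train(200)
    expect_equal(detect_bursts(t, bp), brute_force_bursts(t),
                 ignore_attr = TRUE)
  }
})

test_that("lowering the ISI threshold never adds spikes to bursts", {
  set.seed(31)
  for (rep in 1:25) {
    t <- random_train(300)
    spikes_in <- vapply(c(0.2, 0.1, 0.05, 0.02), function(thr) {
      sum(detect_bursts(t, burst_params(isi_threshold = thr))$n_spikes)
    }, numeric(1))
    expect_true(all(diff(spikes_in) <= 0))
  }
})

test_that("adaptive threshold centres between the histogram peaks on the log scale", {
  np <- nb_params()
  # clusters spanning 20 ms, 1 s apart: ISI_6 modes near 0.02 and 1.0 s,
  # so the threshold should be near sqrt(0.02 * 1.0) = 0.141 s, within one
  # histogram bin (a factor of 10^0.1)
  d <- adaptive_isi_threshold(cluster_train(80, 0.004, 1.0), np)
  expect_false(d$fallback_used)
  expect_lt(abs(log10(d$threshold) - log10(sqrt(0.02 * 1.0))), 0.1)

  # modes near 1 ms and 50 ms: geometric mean ~7 ms clamps to the 12 ms floor
  d2 <- adaptive_isi_threshold(cluster_train(80, 0.0002, 0.050), np)
  expect_false(d2$fallback_used)
  expect_equal(d2$threshold, 0.012)

  # unimodal sample: fallback threshold, flagged
  set.seed(2)
  uni <- cumsum(stats::rexp(500, 10))
  d3 <- adaptive_isi_threshold(uni, np)
  expect_true(d3$fallback_used)
  expect_equal(d3$threshold, 0.100)

  expect_error(adaptive_isi_threshold(c(0.1, 0.2), np), "fewer")
})

test_that("adaptive threshold stays inside the clamp and scales with time", {
  np <- nb_params()
  set.seed(29)
  for (rep in 1:40) {
    intra <- stats::runif(1, 0.0005, 0.01)
    spacing <- stats::runif(1, 0.2, 3)
    d <- adaptive_isi_threshold(cluster_train(60, intra, spacing), np)
    if (!d$fallback_used) {
      expect_gte(d$threshold, np$threshold_min)
      expect_lte(d$threshold, np$threshold_max)
    }
  }

  # scale covariance: times scaled by c, clamp bounds scaled by c ->
  # threshold scales by c (up to log-bin quantization of one bin width)
  t0 <- cluster_train(80, 0.004, 1.0)
  cc <- 3
  d1 <- adaptive_isi_threshold(t0, np)
  d2 <- adaptive_isi_threshold(t0 * cc,
                               nb_params(threshold_min = 0.012 * cc,
                                         threshold_max = 0.300 * cc))
  expect_lt(abs(log10(d2$threshold / d1$threshold) - log10(cc)), 0.11)
})

test_that("network bursts are maximal unions of sub-threshold ISI_6 blocks", {
  np <- nb_params()
  # six spikes in 10 ms qualify as one network burst
  t6 <- seq(0, 0.010, length.out = 6)
  nb <- detect_network_bursts(t6, np, threshold = 0.1)
  expect_equal(nrow(nb), 1L)
  expect_equal(nb$n_spikes, 6L)

  # five spikes cannot form an ISI_6 window
  expect_equal(nrow(detect_network_bursts(t6[1:5], np, threshold = 0.1)), 0L)

  # two dense events 2 s apart are never merged at any threshold <= 0.3 s
  ev <- seq(0, 0.04, length.out = 12)
  t2 <- c(ev, 2 + ev)
  for (thr in c(0.05, 0.1, 0.3)) {
    nb2 <- detect_network_bursts(t2, np, threshold = thr)
    expect_equal(nrow(nb2), 2L)
    expect_equal(nb2$n_spikes, c(12L, 12L))
  }

  # electrode participation counts distinct contributors
  rec <- mea_recording(list(A = seq(0, 0.02, length.out = 4),
                            B = seq(0.001, 0.021, length.out = 4)),
                       duration = 1)
  nb3 <- detect_network_bursts(flatten_recording(rec), np, threshold = 0.1)
  expect_equal(nb3$n_electrodes, 2L)
})

test_that("event matching scores precision and recall by interval Jaccard", {
  truth <- data.frame(start_s = c(1, 5), end_s = c(2, 6))
  # perfect detections
  m <- match_events(truth, truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  # no detections: recall 0, precision 1 by convention, flagged
  m0 <- match_events(truth[0, ], truth)
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 1)
  expect_true(m0$precision_undefined)
  # a shifted detection with Jaccard 1/3 fails the 0.5 cut
  shifted <- data.frame(start_s = 1.5, end_s = 2.5)
  expect_equal(match_events(shifted, truth, min_overlap = 0.5)$n_matched, 0L)
  expect_equal(match_events(shifted, truth, min_overlap = 0.3)$n_matched, 1L)
})
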