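test_that("spike tables are read sorted, deduplicated, and validated", {
  p <- write_tiny_table(c("E1,0.5", "E1,0.2", "E2,0.3"))
  rec <- read_spike_table(p, duration = 1)
  expect_equal(rec$trains$E1, c(0.2, 0.5))
  expect_equal(rec$trains$E2, 0.3)

  # duplicate timestamps on one electrode collapse with a warning
  p2 <- write_tiny_table(c("E1,0.2", "E1,0.2"))
  expect_warning(rec2 <- read_spike_table(p2, duration = 1), "duplicate")
  expect_equal(rec2$trains$E1, 0.2)

  # header-only file: fine with a duration, error without
  p3 <- write_tiny_table(character(0))
  expect_equal(length(read_spike_table(p3, duration = 5)$trains), 0L)
  expect_error(read_spike_table(p3), "duration")

  # contract failures
  p4 <- tempfile(); writeLines(c("chan,t", "E1,0.2"), p4)
  expect_error(read_spike_table(p4, duration = 1), "lacks column")
  p5 <- write_tiny_table("E1,-0.5")
  expect_error(read_spike_table(p5, duration = 1), "negative")

  # inferred duration = last spike time, flagged
  rec6 <- read_spike_table(p)
  expect_equal(rec6$duration, 0.5)
  expect_true(rec6$metadata$duration_inferred)
})

test_that("flatten merges trains in time order and conserves spike counts", {
  rec <- mea_recording(list(E1 = c(0.1, 0.3), E2 = 0.2), duration = 1)
  pooled <- flatten_recording(rec)
  expect_equal(pooled$time, c(0.1, 0.2, 0.3))
  expect_equal(pooled$electrode, c("E1", "E2", "E1"))

  # single electrode is the identity
  one <- flatten_recording(mea_recording(list(E1 = c(1, 2, 3)), duration = 5))
  expect_equal(one$time, c(1, 2, 3))

  expect_error(flatten_recording(mea_recording(list(), duration = 1)),
               "no spikes")

  # property: pooled train equals concatenate-and-sort for random recordings
  set.seed(11)
  for (rep in 1:20) {
    trains <- lapply(seq_len(sample(2:15, 1)), function(i) {
      sort(stats::runif(sample(0:30, 1), 0, 10))
    })
    names(trains) <- paste0("E", seq_along(trains))
    rec <- mea_recording(trains, duration = 10)
    pooled <- flatten_recording(rec, require_spikes = FALSE)
    expect_equal(nrow(pooled), sum(lengths(trains)))
    expect_equal(pooled$time, sort(unlist(trains, use.names = FALSE)))
  }
})

test_that("phase segmentation is half-open, conservative, and re-zeroed", {
  set.seed(3)
  trains <- lapply(1:4, function(i) sort(stats::runif(200, 0, 3600)))
  names(trains) <- paste0("E", 1:4)
  rec <- mea_recording(trains, duration = 3600)
  phases <- segment_recording(rec, treatment_phase_plan())
  expect_length(phases, 3)
  expect_equal(names(phases), c("treatment_1", "treatment_2", "treatment_3"))
  expect_true(all(vapply(phases, function(p) p$duration, numeric(1)) == 1200))
  expect_equal(sum(vapply(phases, n_spikes, integer(1))), n_spikes(rec))

  # boundary spike belongs to the later phase, times re-zeroed
  rec_b <- mea_recording(list(E1 = c(100, 1200, 2399.9)), duration = 3600)
  ph <- segment_recording(rec_b, treatment_phase_plan())
  expect_equal(ph$treatment_1$trains$E1, 100)
  expect_equal(ph$treatment_2$trains$E1, c(0, 1199.9))
  expect_equal(n_spikes(ph$treatment_3), 0L)

  # single full-span phase is the identity
  full <- segment_recording(rec, phase_plan("all", 0, 3600))
  expect_equal(full$all$trains, rec$trains)

  expect_error(phase_plan(c("a", "b"), c(0, 500), c(600, 1000)), "overlap")
  expect_error(segment_recording(rec, phase_plan("x", 0, 4000)), "beyond")
})

test_that("result tables round-trip through write_results", {
  met <- data.frame(recording_id = "r1",
                    metric = c("mean_firing_rate", "coherence_index"),
                    value = c(1.25, 0.5))
  nb <- data.frame(n_electrodes = 3L, n_spikes = 10L, start_s = 0.5,
                   end_s = 0.7)
  paths <- write_results(list(metrics = met, network_bursts = nb), tempdir())
  back <- read.csv(paths[["metrics"]])
  expect_equal(back$value, met$value)
  expect_equal(back$metric, met$metric)
  # schema: deterministic column order regardless of input order
  expect_equal(names(read.csv(paths[["network_bursts"]])),
               c("start_s", "end_s", "n_spikes", "n_electrodes"))

  # empty table -> header-only file
  p <- write_results(list(metrics = met[0, ]), tempdir())
  expect_equal(nrow(read.csv(p[["metrics"]])), 0L)

  # spike table round trip
  rec <- tiny_recording()
  sp <- file.path(tempdir(), "spikes_rt.csv")
  write_spike_table(rec, sp)
  rec2 <- read_spike_table(sp, duration = rec$duration)
  expect_equal(rec2$trains, rec$trains)
})
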