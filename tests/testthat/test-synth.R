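test_that("fixed seeds give bit-identical recordings", {
  sc <- wave_scenario("fibrillatory", seed = 21)
  art <- artifact_spec(qrs_amplitude = 0.4, baseline_amplitude = 0.2,
                       noise_sd = 0.03)
  a <- simulate_recording(sc, art, duration = 4)
  b <- simulate_recording(sc, art, duration = 4)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("a quiescent scenario with zero artifacts is all-zero", {
  rec <- simulate_recording(wave_scenario("quiescent"), artifact_spec(),
                            duration = 2)
  expect_equal(max(abs(rec$samples)), 0)
  expect_equal(dim(rec$samples), c(64L, 2000L))
})

test_that("planar arrival delays follow the closed-form geometry", {
  v <- 25
  sc <- wave_scenario("planar", conduction_velocity = v, direction = pi / 2,
                      cycle_jitter = 0, seed = 2)
  rec <- simulate_recording(sc, artifact_spec(), duration = 4)
  # one grid unit along the propagation direction = 1/v seconds
  for (sp in c("A", "D", "G")) {
    for (r in 1:7) {
      t1 <- rec$truth$events[[channel_index(sp, r)]]
      t2 <- rec$truth$events[[channel_index(sp, r + 1)]]
      n <- min(length(t1), length(t2))
      expect_equal(t2[1:n] - t1[1:n], rep(1 / v, n), tolerance = 1e-9)
    }
  }
  # same ring, different splines: zero delay for a wave along the rings
  t_a <- rec$truth$events[[channel_index("A", 3)]]
  t_b <- rec$truth$events[[channel_index("B", 3)]]
  expect_equal(t_a, t_b)
})

test_that("focal deflections occur in exactly the active segments", {
  sc <- wave_scenario("focal", active_fraction = 0.5, seed = 6)
  rec <- simulate_recording(sc, artifact_spec(), duration = 20)
  act <- rec$truth$active_segments
  expect_length(act, 5)
  # source-adjacent electrode: all its events lie inside active segments
  d <- chart_distance(build_grid()$channels$x, build_grid()$channels$y,
                      4.5, 4.5)
  near <- which.min(d)
  ev <- rec$truth$events[[near]]
  seg_of <- floor(ev / 2) + 1
  expect_setequal(unique(seg_of), act)
  # active fraction 1 lights every segment; 0 none
  all_on <- simulate_recording(wave_scenario("focal", active_fraction = 1,
                                             seed = 6),
                               artifact_spec(), duration = 8)
  expect_equal(all_on$truth$active_segments, 1:4)
})

test_that("generated arrivals appear in the signal within one sample", {
  sc <- wave_scenario("planar", seed = 4, cycle_jitter = 0)
  rec <- simulate_recording(sc, artifact_spec(), duration = 4)
  fs <- rec$fs
  ch <- channel_index("C", 5)
  for (ev in rec$truth$events[[ch]][1:5]) {
    # biphasic deflection: zero crossing at the event time, extrema at
    # +/- sigma; check signal energy in a +/-40 ms window around events
    idx <- round(ev * fs) + 1
    win <- rec$samples[ch, max(1, idx - 40):min(ncol(rec$samples), idx + 40)]
    expect_gt(max(abs(win)), 0.5)
  }
})

test_that("artifact energy is exactly additive", {
  sc <- wave_scenario("planar", seed = 9)
  art <- artifact_spec(qrs_amplitude = 0.5, baseline_amplitude = 0.3,
                       baseline_hz = 0.3, noise_sd = 0.04)
  clean <- simulate_recording(sc, artifact_spec(), duration = 4)
  dirty <- simulate_recording(sc, art, duration = 4)
  traces <- egflow:::artifact_traces(art, 1000, 4, sc$seed)
  expect_equal(dirty$samples - clean$samples, traces)
})

test_that("non-contact channels carry only far-field and noise", {
  nc <- channel_index(rep("E", 3), 6:8)
  sc <- wave_scenario("planar", seed = 5)
  rec <- simulate_recording(sc, artifact_spec(noncontact_channels = nc),
                            duration = 4)
  expect_false(any(rec$truth$contact[nc]))
  expect_length(rec$truth$events[[nc[1]]], 0)
  # identical far-field on all non-contact channels (zero lag)
  expect_equal(rec$samples[nc[1], ], rec$samples[nc[2], ])
  # far-field has the configured RMS, well below local deflections
  expect_equal(sqrt(mean(rec$samples[nc[1], ]^2)), 0.15, tolerance = 0.01)
  expect_gt(max(abs(rec$samples[1, ])), 0.9)
})

test_that("scenario and artifact validation rejects bad inputs", {
  expect_error(wave_scenario("planar", cycle_length = 0))
  expect_error(wave_scenario("focal", active_fraction = 1.5))
  expect_error(artifact_spec(noise_sd = -1))
  expect_error(simulate_recording(wave_scenario("planar"), artifact_spec(),
                                  fs = 200))
})

test_that("recordings survive a CSV/JSON bundle round-trip", {
  rec <- simulate_recording(wave_scenario("planar", seed = 3),
                            artifact_spec(noise_sd = 0.01), duration = 2)
  dir <- tempfile()
  write_recording_bundle(rec, dir)
  back <- read_recording_bundle(dir)
  expect_equal(unname(back$samples), unname(rec$samples), tolerance = 1e-12)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$position_id, rec$position_id)
})

test_that("cohorts are reproducible and balanced over phenotypes", {
  a <- generate_cohort(8, seed = 4, duration = 12)
  b <- generate_cohort(8, seed = 4, duration = 12)
  expect_identical(a, b)
  expect_equal(vapply(a, `[[`, "", "true_phenotype"),
               rep(c("I", "II", "III", "IV"), 2))
  # source-positive patients carry the extra focal recording
  expect_length(a[[2]]$recordings, 3)
  expect_length(a[[1]]$recordings, 2)
  expect_error(generate_cohort(3))
})
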