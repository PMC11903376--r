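# short synthetic signals for the cross-correlation primitives
mk_pulse_train <- function(n, at, fs = 1000, sigma = 0.008) {
  k <- egflow:::deflection_kernel(fs, sigma)
  egflow:::add_events(numeric(n), at, fs, k)
}

test_that("normalized cross-correlation behaves at its anchors", {
  set.seed(1)
  x <- stats::rnorm(1000)
  expect_equal(xcorr_norm(x, x, 0), 1)
  # sine vs cosine over whole periods: orthogonal at zero lag
  t <- seq(0, 1, length.out = 1000)
  expect_lt(abs(xcorr_norm(sin(2 * pi * 8 * t), cos(2 * pi * 8 * t), 0)),
            0.02)
  # zero-energy window returns 0 without error
  expect_equal(xcorr_norm(numeric(100), stats::rnorm(100), 0), 0)
  expect_error(xcorr_norm(x, x[1:10]))
  expect_error(xcorr_norm(x, x, -1))
  expect_error(xcorr_norm(x, x, 501))
})

test_that("lag scan finds a pure delay exactly", {
  set.seed(2)
  n <- 1200
  base <- mk_pulse_train(n + 100, c(0.1, 0.35, 0.62, 0.9))
  for (k in c(7, 20, 43)) {
    # x delayed by k samples relative to y: y runs ahead of x
    x <- base[1:n]
    y <- base[(1 + k):(n + k)]
    r <- egflow:::xcorr_lags(x, y)
    expect_equal(which.max(r) - 1L, k)
    # brute-force oracle over all lags with the single-lag primitive
    brute <- vapply(0:(n %/% 2), function(dt) xcorr_norm(x, y, dt),
                    numeric(1))
    expect_equal(which.max(brute) - 1L, k)
    expect_equal(max(abs(r - brute)), 0, tolerance = 1e-10)
  }
})

test_that("conduction component honors the physiologic lag window", {
  n <- 2000; fs <- 1000
  x <- mk_pulse_train(n + 100, c(0.2, 0.5, 0.85, 1.3, 1.7))[1:n]
  delayed <- function(ms) {
    k <- round(ms * fs / 1000)
    mk_pulse_train(n + 100, c(0.2, 0.5, 0.85, 1.3, 1.7) + k / fs)[1:n]
  }
  # 20 ms: genuine conduction
  cc <- conduction_component(x, list(delayed(20)), fs)
  expect_gt(cc$RE_cond, 0.9)
  expect_equal(cc$dt_star, 20, tolerance = 1)
  # 0 ms: far-field copy, too fast for conduction
  expect_equal(conduction_component(x, list(x), fs)$RE_cond, 0)
  # 60 ms: too slow
  expect_equal(conduction_component(x, list(delayed(60)), fs)$RE_cond, 0)
  # either electrode may lead: a -20 ms neighbor is conduction too
  lead <- mk_pulse_train(n + 100, c(0.2, 0.5, 0.85, 1.3, 1.7) - 0.02)[1:n]
  expect_gt(conduction_component(x, list(lead), fs)$RE_cond, 0.9)
  expect_error(conduction_component(x, list(), fs))
})

test_that("instantaneous component is conditional on absent conduction", {
  n <- 1000
  set.seed(3)
  x <- stats::rnorm(n)
  nb <- list(x, x + stats::rnorm(n, sd = 0.05))
  expect_equal(instantaneous_component(x, nb, RE_cond = 0.8), 0)
  expect_gt(instantaneous_component(x, nb, RE_cond = 0), 0.95)
  # independent white noise vs structured neighbors stays small
  y <- stats::rnorm(n)
  tr <- mk_pulse_train(n, c(0.2, 0.5, 0.8))
  expect_lt(abs(instantaneous_component(y, list(tr, tr), RE_cond = 0)), 0.3)
})

test_that("contact scoring separates conducting and far-field channels", {
  nc <- c(channel_index(LETTERS[1:8], rep(8, 8)))
  sc <- wave_scenario("planar", seed = 13)
  art <- artifact_spec(noise_sd = 0.03, noncontact_channels = nc)
  rec <- simulate_recording(sc, art, duration = 8)
  nf <- nearfield_score(segment_recording(rec))
  expect_true(all(nf$score[nc] < 0.7))
  expect_true(all(nf$score[-nc] >= 0.7))
  expect_false(any(nf$contact[nc]))
  # conduction and instantaneous ratios are never jointly non-zero
  expect_false(any(nf$RE_cond != 0 & nf$RE_inst != 0))
  # decomposition closes to 1
  expect_equal(nf$RE_cond + nf$RE_inst + nf$RE_frac,
               matrix(1, 64, ncol(nf$mask)))
})

test_that("score threshold boundary: exactly 0.7 is good contact", {
  nf <- structure(
    list(score = c(0.7, 0.699), mask = NULL),
    class = "nearfield_components"
  )
  expect_true(nf$score[1] >= 0.7)
  expect_false(nf$score[2] >= 0.7)
  # through the real path: a channel whose mask hits exactly 7/10
  sc <- wave_scenario("planar", seed = 13)
  rec <- simulate_recording(sc, artifact_spec(noise_sd = 0.02), duration = 8)
  out <- nearfield_score(segment_recording(rec), score_threshold = 0.7)
  expect_equal(out$contact, out$score >= 0.7)
})

test_that("the score is invariant to uniform amplitude scaling", {
  sc <- wave_scenario("fibrillatory", seed = 17)
  rec <- simulate_recording(sc, artifact_spec(noise_sd = 0.02), duration = 6)
  a <- nearfield_score(segment_recording(rec))
  rec$samples <- rec$samples * 7.3
  b <- nearfield_score(segment_recording(rec))
  expect_equal(a$score, b$score)
  expect_equal(a$RE_cond, b$RE_cond, tolerance = 1e-12)
})

test_that("caption mode scores by conduction presence instead", {
  # a silent channel among silent neighbors: near-field under the energy
  # rule (no far-field correlation), poor under the caption rule (no
  # conduction either)
  rec <- simulate_recording(wave_scenario("quiescent"), artifact_spec(),
                            duration = 4)
  seg <- segment_recording(rec)
  energy <- nearfield_score(seg, mode = "energy")
  caption <- nearfield_score(seg, mode = "caption")
  expect_true(all(energy$score == 1))
  expect_true(all(caption$score == 0))
})
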