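# shared fixture builder: simulate -> clean -> segment -> frames -> flow
# for one scenario, with the package defaults used throughout the tests
pipe_recording <- function(kind, seed, duration, active_fraction = 0.5,
                           artifacts = artifact_spec(noise_sd = 0.02),
                           qrs_subtraction = FALSE) {
  sc <- wave_scenario(kind, active_fraction = active_fraction, seed = seed)
  rec <- simulate_recording(sc, artifacts, duration = duration)
  cl <- clean_recording(rec, clean_config(qrs_subtraction = qrs_subtraction))
  segrec <- segment_recording(cl)
  stack <- render_frames(segrec)
  sfm <- segment_flow(stack)
  list(rec = rec, segrec = segrec, sfm = sfm)
}

# integer-shift displacement oracle via circular cross-correlation (FFT);
# independent of the gradient-based flow solver it checks. For b equal to
# a translated by (dx, dy), ifft(fft(b) * Conj(fft(a))) peaks at (dy, dx).
phase_correlation_shift <- function(a, b) {
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  ij <- unname(which(cc == max(cc), arr.ind = TRUE)[1, ])
  n <- nrow(a); p <- ncol(a)
  dy <- ij[1] - 1; dx <- ij[2] - 1
  if (dy > n / 2) dy <- dy - n
  if (dx > p / 2) dx <- dx - p
  c(dx = dx, dy = dy)
}
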