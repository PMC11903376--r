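test_that("biharmonic interpolant reproduces node values exactly", {
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    xy <- cbind(stats::runif(n, 0, 8), stats::runif(n, 0, 8))
    v <- stats::rnorm(n)
    fit <- fit_biharmonic(xy, v)
    expect_lt(max(abs(predict(fit, xy) - v)), 1e-8)
  }
})

test_that("constant node values are reproduced at the nodes", {
  set.seed(2)
  xy <- cbind(stats::runif(8, 0, 8), stats::runif(8, 0, 8))
  fit <- fit_biharmonic(xy, rep(3.5, 8))
  expect_lt(max(abs(predict(fit, xy) - 3.5)), 1e-8)
})

test_that("fit agrees with an independent dense solve", {
  set.seed(3)
  xy <- cbind(stats::runif(10, 0, 8), stats::runif(10, 0, 8))
  v <- stats::rnorm(10)
  fit <- fit_biharmonic(xy, v)
  # direct oracle: build G elementwise with the scalar Green's function
  g1 <- function(r) if (r == 0) 0 else r^2 * (log(r) - 1)
  G <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    G[i, j] <- g1(sqrt(sum((xy[i, ] - xy[j, ])^2)))
  }
  w <- solve(G, v)
  expect_equal(as.numeric(fit$weights), as.numeric(w), tolerance = 1e-10)
  # evaluation at a fresh point
  p <- c(2.2, 6.1)
  oracle <- sum(w * apply(xy, 1, function(q) g1(sqrt(sum((p - q)^2)))))
  expect_equal(predict(fit, matrix(p, 1)), oracle, tolerance = 1e-10)
})

test_that("coincident nodes trigger the ridge fallback with a warning", {
  xy <- rbind(c(1, 1), c(1, 1), c(2, 2), c(3, 1))
  expect_warning(fit_biharmonic(xy, c(1, 1, 2, 3)), "ridge")
  expect_error(fit_biharmonic(rbind(c(1, 1), c(2, 2)), c(1, 2)))
})

test_that("quiescent recordings render identically zero frames", {
  rec <- simulate_recording(wave_scenario("quiescent"), artifact_spec(),
                            duration = 2)
  stack <- render_frames(segment_recording(rec), frame_rate = 25)
  expect_equal(max(abs(stack$frames)), 0)
})

test_that("a single active electrode dominates its own pixel", {
  rec <- simulate_recording(wave_scenario("quiescent"), artifact_spec(),
                            duration = 2)
  ch <- channel_index("D", 4)
  rec$samples[ch, ] <- 1   # constant unit amplitude at one electrode
  stack <- render_frames(segment_recording(rec), frame_rate = 25)
  fr <- stack$frames[, , 10]
  peak <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  ep <- stack$electrode_pixel[ch, ]
  expect_equal(unname(peak["row"]), unname(ep["row"]))
  expect_equal(unname(peak["col"]), unname(ep["col"]))
})

test_that("masking an electrode removes its influence on the field", {
  rec <- simulate_recording(wave_scenario("quiescent"), artifact_spec(),
                            duration = 2)
  ch <- channel_index("D", 4)
  rec$samples[ch, ] <- 1
  segrec <- segment_recording(rec)
  mask <- rep(TRUE, 64); mask[ch] <- FALSE
  with_ch <- render_frames(segrec, frame_rate = 25)
  without_ch <- render_frames(segrec, contact_mask = mask, frame_rate = 25)
  ep <- with_ch$electrode_pixel[ch, ]
  expect_gt(abs(with_ch$frames[ep["row"], ep["col"], 10] -
                without_ch$frames[ep["row"], ep["col"], 10]), 0.5)
  expect_error(render_frames(segrec, contact_mask = rep(FALSE, 64)))
})

test_that("periodic replication keeps the field continuous across the seam", {
  set.seed(8)
  rec <- simulate_recording(wave_scenario("quiescent"), artifact_spec(),
                            duration = 2)
  rec$samples <- matrix(stats::rnorm(64), 64, ncol(rec$samples))
  stack <- render_frames(segment_recording(rec), frame_rate = 25, R = 29)
  fr <- stack$frames[, , 5]
  # columns 1 (x = 1) and 29 (x = 8) are one grid unit apart on the
  # circle, the same spacing as adjacent electrode columns; values of a
  # periodic field evaluated just beyond each edge must agree with the
  # interpolant from the other side. Check the interpolant at x = 0.5 and
  # x = 8.5 (the same physical meridian).
  nodes_x <- build_grid()$channels$x
  vals <- rec$samples[, 1]
  ex <- build_grid()$channels$x; ey <- build_grid()$channels$y
  fit <- fit_biharmonic(cbind(c(ex - 8, ex, ex + 8), c(ey, ey, ey)),
                        rep(vals, 3))
  ys <- seq(1, 8, length.out = 15)
  a <- predict(fit, cbind(rep(0.5, 15), ys))
  b <- predict(fit, cbind(rep(8.5, 15), ys))
  # finite replication of a Green's function that grows as r^2 ln r gives
  # approximate, not machine-exact, periodicity; the residual seam
  # mismatch stays three orders of magnitude below the field scale
  expect_lt(max(abs(a - b)), 5e-3 * stats::sd(vals))
})

test_that("frame count follows duration and frame rate", {
  rec <- simulate_recording(wave_scenario("planar", seed = 1),
                            artifact_spec(), duration = 4)
  stack <- render_frames(segment_recording(rec), frame_rate = 25)
  expect_equal(dim(stack$frames)[3], 100)
  expect_error(render_frames(segment_recording(rec), frame_rate = 33))
})
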