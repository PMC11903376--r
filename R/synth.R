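# Synthetic basket-catheter electrogram generator.
#
# The generator emulates the three wavefront regimes the flow pipeline must
# distinguish -- planar (organized) propagation, intermittent focal sources
# with divergent activation, and fibrillatory conduction built from randomly
# seeded circular wavelets -- on the unwrapped 8 x 8 electrode chart, plus
# the nuisance signals real recordings carry: ventricular far-field (QRS),
# baseline wander, broadband noise, and non-contact electrodes that see only
# far-field.

# run code with a locally-seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable derived sub-seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

#' Describe a wavefront scenario
#'
#' A \code{wave_scenario} defines the ground-truth activation dynamics of a
#' synthetic recording.
#'
#' @param kind one of \code{"planar"} (single repeating plane wave),
#'   \code{"focal"} (point source firing radially during a subset of 2-s
#'   segments, quiescent otherwise), \code{"fibrillatory"} (randomly seeded
#'   circular wavelets), or \code{"quiescent"} (no activation).
#' @param cycle_length activation cycle length in ms (default 180, typical
#'   of atrial fibrillation; use ~800 for sinus rhythm).
#' @param conduction_velocity wavefront speed in grid units per second
#'   (electrode spacing = 1 grid unit). The default 25 gives a 40 ms delay
#'   between neighboring electrodes, inside the physiologic 5-50 ms
#'   conduction window.
#' @param direction planar propagation direction in radians on the chart
#'   (default \code{pi/2}: along the ring axis, which avoids the periodic
#'   seam of the spline axis).
#' @param source_location numeric length-2 continuous (spline, ring) chart
#'   coordinate of the focal source.
#' @param active_fraction fraction of 2-s segments during which a focal
#'   source fires (segments chosen by the scenario RNG).
#' @param chaos_level for \code{"fibrillatory"}: probability that each beat
#'   is a randomly located wavelet rather than a planar front; 0 degenerates
#'   to planar, 1 is fully random.
#' @param cycle_jitter beat-to-beat cycle-length variability as a fraction
#'   of the cycle length (SD of a multiplicative Gaussian perturbation).
#'   Fibrillatory and even organized atrial rhythms are not strictly
#'   periodic; without jitter the neighbor cross-correlation has equal
#'   peaks at every cycle offset and the conduction lag becomes ambiguous.
#' @param seed RNG seed governing all stochastic scenario elements.
#' @return object of class \code{wave_scenario}.
#' @export
wave_scenario <- function(kind = c("planar", "focal", "fibrillatory", "quiescent"),
                          cycle_length = 180,
                          conduction_velocity = 25,
                          direction = pi / 2,
                          source_location = c(4.5, 4.5),
                          active_fraction = 0.5,
                          chaos_level = 1,
                          cycle_jitter = 0.08,
                          seed = 1L) {
  kind <- match.arg(kind)
  if (cycle_length <= 0) stop("cycle_length must be > 0")
  if (active_fraction < 0 || active_fraction > 1) {
    stop("active_fraction must be in [0, 1]")
  }
  if (conduction_velocity <= 0) stop("conduction_velocity must be > 0")
  structure(
    list(kind = kind, cycle_length = cycle_length,
         conduction_velocity = conduction_velocity, direction = direction,
         source_location = source_location,
         active_fraction = active_fraction, chaos_level = chaos_level,
         cycle_jitter = cycle_jitter, seed = as.integer(seed)),
    class = "wave_scenario"
  )
}

#' Describe additive recording artifacts
#'
#' @param qrs_rate ventricular rate, beats per minute.
#' @param qrs_amplitude far-field QRS amplitude in mV. The QRS deflection is
#'   a smooth low-frequency waveform injected identically (zero lag) on all
#'   channels -- the signature the instantaneous-component detector exploits.
#' @param baseline_amplitude,baseline_hz baseline-wander sinusoid amplitude
#'   (mV) and frequency (Hz); the phase is randomized per channel.
#' @param noise_sd white-noise standard deviation in mV.
#' @param noncontact_channels integer channel numbers rendered without local
#'   deflections: they carry only an attenuated, temporally smoothed common
#'   atrial far-field (identical across all non-contact channels), the
#'   ventricular far-field, and noise.
#' @param farfield_rms RMS amplitude (mV) of the common atrial far-field
#'   rendered on non-contact channels.
#' @return object of class \code{artifact_spec}.
#' @export
artifact_spec <- function(qrs_rate = 60, qrs_amplitude = 0,
                          baseline_amplitude = 0, baseline_hz = 0.25,
                          noise_sd = 0, noncontact_channels = integer(0),
                          farfield_rms = 0.15) {
  if (qrs_amplitude < 0 || baseline_amplitude < 0 || noise_sd < 0 ||
      farfield_rms < 0) {
    stop("artifact amplitudes must be >= 0")
  }
  structure(
    list(qrs_rate = qrs_rate, qrs_amplitude = qrs_amplitude,
         baseline_amplitude = baseline_amplitude, baseline_hz = baseline_hz,
         noise_sd = noise_sd,
         noncontact_channels = as.integer(noncontact_channels),
         farfield_rms = farfield_rms),
    class = "artifact_spec"
  )
}

# biphasic derivative-of-Gaussian deflection, unit peak amplitude.
# sigma = 12 ms gives a ~50 ms deflection whose spatial footprint at the
# default conduction velocity (25 grid units/s) is ~0.6 electrode
# spacings -- the wavefront width scale of real atrial activation.
deflection_kernel <- function(fs, sigma = 0.012) {
  half <- ceiling(4 * sigma * fs)
  t <- (-half:half) / fs
  -(t / sigma) * exp(-t^2 / (2 * sigma^2)) / exp(-0.5)
}

# smooth monophasic low-frequency bump for the ventricular far-field
qrs_kernel <- function(fs, sigma = 0.015) {
  half <- ceiling(4 * sigma * fs)
  t <- (-half:half) / fs
  exp(-t^2 / (2 * sigma^2))
}

# add kernel at event times (seconds) into a length-n signal
add_events <- function(sig, events, fs, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  n <- length(sig)
  for (e in events) {
    c0 <- as.integer(round(e * fs)) + 1L
    lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
    if (lo > hi) next
    sig[lo:hi] <- sig[lo:hi] + kernel[(lo - c0 + half + 1L):(hi - c0 + half + 1L)]
  }
  sig
}

# drop arrivals closer than the refractory period to the previous kept one
apply_refractory <- function(times, refractory = 0.08) {
  times <- sort(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

# per-channel arrival times for one scenario; returns list of numeric vectors
# plus the set of active segments (focal only)
scenario_arrivals <- function(scenario, grid, duration) {
  xy <- grid$channels[, c("x", "y")]
  v <- scenario$conduction_velocity
  cl <- scenario$cycle_length / 1000
  events <- replicate(64, numeric(0), simplify = FALSE)
  active_segments <- integer(0)
  n_seg <- floor(duration / 2)

  jit <- scenario$cycle_jitter
  jitter_beats <- function(from, to) {
    # renewal sequence with multiplicative Gaussian cycle-length jitter
    n_max <- ceiling((to - from) / cl * (1 + 4 * jit)) + 4L
    gaps <- cl * pmax(1 + jit * stats::rnorm(n_max), 0.3)
    b <- from + c(0, cumsum(gaps))
    b[b <= to]
  }

  if (scenario$kind == "planar") {
    proj <- xy$x * cos(scenario$direction) + xy$y * sin(scenario$direction)
    delay <- (proj - min(proj)) / v
    beats <- jitter_beats(0.05, duration)
    for (i in 1:64) {
      a <- beats + delay[i]
      events[[i]] <- a[a < duration - 0.02]
    }
  } else if (scenario$kind == "focal") {
    n_active <- round(scenario$active_fraction * n_seg)
    active_segments <- sort(sample.int(n_seg, n_active))
    d <- chart_distance(xy$x, xy$y,
                        scenario$source_location[1], scenario$source_location[2])
    for (s in active_segments) {
      # last beat early enough that the wavefront reaches every electrode
      # before the segment ends: activity stays within active segments
      t0 <- (s - 1) * 2
      beats <- jitter_beats(t0 + 0.03, t0 + 2 - 0.1 - max(d) / v)
      for (i in 1:64) {
        a <- beats + d[i] / v
        events[[i]] <- c(events[[i]], a[a < duration - 0.02])
      }
    }
  } else if (scenario$kind == "fibrillatory") {
    # Poisson-seeded wavelets: beat times from an exponential renewal process
    # at the scenario cycle length; each beat is either a random circular
    # wavelet (probability chaos_level) or a planar front
    beats <- cumsum(stats::rexp(ceiling(2 * duration / cl) + 10, rate = 1 / cl))
    beats <- beats[beats < duration - 0.02]
    proj <- xy$x * cos(scenario$direction) + xy$y * sin(scenario$direction)
    for (b in beats) {
      if (stats::runif(1) < scenario$chaos_level) {
        # several concurrent wavelets; the earliest wavefront activates
        # each electrode (wavefront collision/annihilation), and
        # per-channel jitter models the heterogeneous conduction of
        # fibrillating tissue -- no stable repeating origin exists
        k <- 1L + stats::rpois(1, 1)
        arrs <- vapply(seq_len(k), function(j) {
          origin <- c(stats::runif(1, 0.5, 8.5), stats::runif(1, 1, 8))
          vb <- v * stats::runif(1, 0.7, 1.3)
          chart_distance(xy$x, xy$y, origin[1], origin[2]) / vb
        }, numeric(64))
        arr <- b + apply(arrs, 1, min) + stats::rnorm(64, sd = 0.012)
      } else {
        arr <- b + (proj - min(proj)) / v
      }
      for (i in 1:64) events[[i]] <- c(events[[i]], arr[i])
    }
    events <- lapply(events, function(e) e[e < duration - 0.02])
  } else if (scenario$kind != "quiescent") {
    stop("invalid scenario kind")
  }
  list(events = lapply(events, apply_refractory),
       active_segments = active_segments)
}

# reproducible nuisance traces (QRS far-field, baseline wander, noise);
# a 64 x T matrix independent of the scenario RNG stream
artifact_traces <- function(artifacts, fs, duration, seed) {
  n <- as.integer(round(fs * duration))
  with_seed(derive_seed(seed, 1L), {
    out <- matrix(0, nrow = 64, ncol = n)
    tt <- (seq_len(n) - 1) / fs
    if (artifacts$qrs_amplitude > 0) {
      kq <- artifacts$qrs_amplitude * qrs_kernel(fs)
      beats <- seq(0.25, duration - 0.1, by = 60 / artifacts$qrs_rate)
      qrs <- add_events(numeric(n), beats, fs, kq)
      out <- out + matrix(qrs, nrow = 64, ncol = n, byrow = TRUE)
    }
    if (artifacts$baseline_amplitude > 0) {
      phases <- stats::runif(64, 0, 2 * pi)
      for (i in 1:64) {
        out[i, ] <- out[i, ] + artifacts$baseline_amplitude *
          sin(2 * pi * artifacts$baseline_hz * tt + phases[i])
      }
    }
    if (artifacts$noise_sd > 0) {
      out <- out + matrix(stats::rnorm(64 * n, sd = artifacts$noise_sd),
                          nrow = 64)
    }
    out
  })
}

# Gaussian temporal smoothing by direct convolution
smooth_gauss <- function(x, fs, sigma = 0.015) {
  half <- ceiling(3 * sigma * fs)
  k <- exp(-((-half:half) / fs)^2 / (2 * sigma^2))
  k <- k / sum(k)
  y <- stats::filter(c(rep(x[1], half), x, rep(x[length(x)], half)), k,
                     sides = 2)
  as.numeric(y[(half + 1):(half + length(x))])
}

#' Simulate a 64-channel basket electrogram recording
#'
#' Generates a unipolar recording in which every contacting channel carries
#' a biphasic local deflection (derivative-of-Gaussian, ~10 ms wide, 1 mV
#' peak) at each wavefront arrival time implied by the scenario geometry:
#' planar arrivals are the projection onto the propagation direction divided
#' by velocity, focal arrivals the chart distance from the source divided by
#' velocity (only during the scenario's active segments), and fibrillatory
#' arrivals come from superposed random wavelets. A per-channel 80 ms
#' refractory period suppresses colliding activations. Channels listed in
#' \code{artifacts$noncontact_channels} carry no local deflections -- only
#' the common atrial far-field (a temporally smoothed average of the
#' contacting channels, identical on every non-contact channel), the
#' ventricular far-field, and noise.
#'
#' The ground truth (scenario, per-channel arrival times, contact flags,
#' active segments) is stored in the returned object's \code{truth} field.
#' Fixed seeds give bit-reproducible output.
#'
#' @param scenario a [wave_scenario()].
#' @param artifacts an [artifact_spec()].
#' @param fs sampling rate in Hz (>= 500).
#' @param duration recording length in seconds (study recordings are 60 s).
#' @param rhythm,atrium,position_id recording metadata.
#' @return object of class \code{egm_recording}: list with \code{samples}
#'   (64 x T mV matrix, rows = channels A1..H8), \code{fs}, \code{duration},
#'   metadata, and \code{truth}.
#' @export
simulate_recording <- function(scenario, artifacts = artifact_spec(),
                               fs = 1000, duration = 60,
                               rhythm = "AF", atrium = "LA",
                               position_id = "LA-1") {
  stopifnot(inherits(scenario, "wave_scenario"),
            inherits(artifacts, "artifact_spec"))
  if (fs < 500) stop("fs must be >= 500 Hz for activation-timing resolution")
  grid <- build_grid()
  n <- as.integer(round(fs * duration))
  contact <- !(1:64 %in% artifacts$noncontact_channels)

  arr <- with_seed(scenario$seed, scenario_arrivals(scenario, grid, duration))
  kernel <- deflection_kernel(fs)
  samples <- matrix(0, nrow = 64, ncol = n)
  for (i in 1:64) {
    if (contact[i] && length(arr$events[[i]]) > 0) {
      samples[i, ] <- add_events(samples[i, ], arr$events[[i]], fs, kernel)
    }
  }

  # common atrial far-field seen by non-contact electrodes
  if (any(!contact) && any(contact)) {
    common <- colMeans(samples[contact, , drop = FALSE])
    ff <- smooth_gauss(common, fs)
    r <- sqrt(mean(ff^2))
    if (r > 1e-12) ff <- ff * (artifacts$farfield_rms / r)
    for (i in which(!contact)) samples[i, ] <- ff
  }

  art <- artifact_traces(artifacts, fs, duration, scenario$seed)
  truth <- list(
    scenario = scenario, artifacts = artifacts,
    events = lapply(seq_len(64), function(i)
      if (contact[i]) arr$events[[i]] else numeric(0)),
    contact = contact,
    active_segments = arr$active_segments
  )
  structure(
    list(samples = samples + art, fs = fs, duration = duration,
         rhythm = rhythm, atrium = atrium, position_id = position_id,
         truth = truth),
    class = "egm_recording"
  )
}

#' @export
print.egm_recording <- function(x, ...) {
  cat(sprintf("EGM recording: 64 channels x %d samples (%.0f s @ %g Hz)\n",
              ncol(x$samples), x$duration, x$fs))
  cat(sprintf("rhythm %s, atrium %s, position %s", x$rhythm, x$atrium,
              x$position_id))
  if (!is.null(x$truth)) cat(sprintf(", truth: %s", x$truth$scenario$kind))
  cat("\n")
  invisible(x)
}

#' Write a recording as a CSV/JSON bundle
#'
#' Persists the sample matrix as a CSV (one column per channel, labeled
#' A1..H8) with a JSON sidecar holding sampling metadata and, when present,
#' the ground-truth scenario.
#'
#' @param rec an \code{egm_recording}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_recording_bundle <- function(rec, dir) {
  stopifnot(inherits(rec, "egm_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- build_grid()
  m <- t(rec$samples)
  colnames(m) <- grid$channels$label
  csv <- file.path(dir, "samples.csv")
  utils::write.csv(m, csv, row.names = FALSE)
  meta <- list(fs = rec$fs, duration = rec$duration, rhythm = rec$rhythm,
               atrium = rec$atrium, position_id = rec$position_id)
  if (!is.null(rec$truth)) {
    meta$truth <- list(
      kind = rec$truth$scenario$kind,
      seed = rec$truth$scenario$seed,
      contact = rec$truth$contact,
      active_segments = rec$truth$active_segments
    )
  }
  js <- file.path(dir, "recording.json")
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(samples = csv, meta = js))
}

#' Read a recording written by [write_recording_bundle()]
#'
#' @param dir directory containing \code{samples.csv} and
#'   \code{recording.json}.
#' @return an \code{egm_recording} (without ground-truth event times).
#' @export
read_recording_bundle <- function(dir) {
  m <- utils::read.csv(file.path(dir, "samples.csv"))
  meta <- jsonlite::read_json(file.path(dir, "recording.json"),
                              simplifyVector = TRUE)
  structure(
    list(samples = t(as.matrix(m)), fs = meta$fs, duration = meta$duration,
         rhythm = meta$rhythm, atrium = meta$atrium,
         position_id = meta$position_id, truth = NULL),
    class = "egm_recording"
  )
}
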