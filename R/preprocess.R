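# Electrogram cleaning and 2-s segmentation.
#
# The cleaning chain: zero-phase Butterworth high-pass (baseline wander),
# low-pass (broadband noise), optional mains notch, and ventricular
# far-field cancellation by cross-channel common-mode beat detection with
# average-beat subtraction. The QRS complex is (near-)identical on all
# channels at zero lag, so the cross-channel median isolates it from the
# channel-specific atrial deflections.

#' Cleaning configuration
#'
#' @param highpass_hz high-pass corner frequency in Hz (baseline removal).
#' @param lowpass_hz low-pass corner frequency in Hz (noise removal).
#' @param notch_hz optional mains frequency (50 or 60) for a band-stop
#'   filter; \code{NULL} disables it.
#' @param qrs_subtraction logical; detect and subtract the ventricular
#'   far-field beat via the cross-channel common mode.
#' @return a named list of class \code{clean_config}.
#' @export
clean_config <- function(highpass_hz = 0.5, lowpass_hz = 100,
                         notch_hz = NULL, qrs_subtraction = TRUE) {
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 notch_hz = notch_hz, qrs_subtraction = qrs_subtraction),
            class = "clean_config")
}

# zero-phase filter applied along rows of a channels x samples matrix
filt_rows <- function(m, flt) {
  for (i in seq_len(nrow(m))) m[i, ] <- signal::filtfilt(flt, m[i, ])
  m
}

# detect far-field beat times from the cross-channel common mode and
# subtract the per-channel average beat at each occurrence
subtract_qrs <- function(m, fs) {
  common <- apply(m, 2, stats::median)
  half <- as.integer(round(0.1 * fs))
  a <- abs(common)
  # far-field beats are common to all channels; atrial activity largely
  # cancels in the cross-channel median. Only subtract when the common
  # mode carries real energy relative to the channels themselves.
  ch_rms <- stats::median(sqrt(rowMeans(m^2)))
  if (sqrt(mean(common^2)) < 0.1 * ch_rms) {
    return(list(m = m, beats = integer(0)))
  }
  thr <- max(5 * stats::mad(a), 0.4 * max(a))
  if (!is.finite(thr) || thr <= 0) return(list(m = m, beats = integer(0)))
  cand <- which(a > thr)
  if (length(cand) == 0) return(list(m = m, beats = integer(0)))
  # peak picking with 300 ms dead time
  beats <- integer(0)
  dead <- as.integer(round(0.3 * fs))
  while (length(cand) > 0) {
    p <- cand[which.max(a[cand])]
    beats <- c(beats, p)
    cand <- cand[abs(cand - p) > dead]
  }
  beats <- sort(beats)
  n <- ncol(m)
  full <- beats[beats - half >= 1 & beats + half <= n]
  if (length(full) < 1) return(list(m = m, beats = beats))
  win <- -half:half
  # the far-field beat is (near-)identical on every channel, so the
  # cross-channel median isolates it from channel-specific atrial
  # activity; averaging the median over occurrences gives a clean template
  tmpl <- rowMeans(vapply(full, function(b) common[b + win],
                          numeric(length(win))))
  for (b in beats) {
    lo <- max(1L, b - half); hi <- min(n, b + half)
    ks <- (lo - b + half + 1L):(hi - b + half + 1L)
    m[, lo:hi] <- m[, lo:hi] -
      matrix(tmpl[ks], nrow(m), length(ks), byrow = TRUE)
  }
  list(m = m, beats = beats)
}

#' Clean a unipolar electrogram recording
#'
#' Attenuates baseline wander (high-pass), broadband noise (low-pass),
#' optionally mains interference (notch), and the ventricular far-field
#' (common-mode average-beat subtraction). All filters are applied
#' zero-phase (forward-backward), so deflection timing is preserved.
#'
#' @param rec an \code{egm_recording}.
#' @param config a [clean_config()].
#' @return a cleaned copy of \code{rec} with a \code{processing} element
#'   logging the applied steps and detected far-field beats.
#' @export
clean_recording <- function(rec, config = clean_config()) {
  stopifnot(inherits(rec, "egm_recording"))
  if (is.null(rec$fs) || !is.finite(rec$fs)) stop("sampling rate fs missing")
  if (rec$duration < 2) stop("recording shorter than one 2-s segment")
  m <- rec$samples
  fs <- rec$fs
  log <- list(config = config)

  if (!is.null(config$highpass_hz) && config$highpass_hz > 0) {
    m <- filt_rows(m, signal::butter(4, config$highpass_hz / (fs / 2), "high"))
  }
  if (!is.null(config$lowpass_hz) && config$lowpass_hz < fs / 2) {
    m <- filt_rows(m, signal::butter(4, config$lowpass_hz / (fs / 2), "low"))
  }
  if (!is.null(config$notch_hz)) {
    band <- c(config$notch_hz - 2, config$notch_hz + 2) / (fs / 2)
    m <- filt_rows(m, signal::butter(2, band, "stop"))
  }
  if (isTRUE(config$qrs_subtraction)) {
    qs <- subtract_qrs(m, fs)
    m <- qs$m
    log$qrs_beats <- qs$beats / fs
  }
  out <- rec
  out$samples <- m
  out$processing <- log
  out
}

#' Slice a recording into contiguous 2-s segments
#'
#' Segments are half-open sample windows \code{[k*2s, (k+1)*2s)}; a 60-s
#' recording yields 30 segments, and a trailing partial segment is dropped.
#'
#' @param rec an \code{egm_recording} (cleaned or raw).
#' @param segment_s segment length in seconds (default 2, the unit over
#'   which flow, source activity, and contact are scored).
#' @return object of class \code{segmented_recording}: the recording plus a
#'   \code{segments} data frame (\code{segment}, \code{start}, \code{end} as
#'   1-based inclusive sample indices) and \code{n_segments}.
#' @export
segment_recording <- function(rec, segment_s = 2) {
  stopifnot(inherits(rec, "egm_recording"))
  if (rec$duration < segment_s) stop("recording shorter than one segment")
  len <- as.integer(round(segment_s * rec$fs))
  n_seg <- floor(ncol(rec$samples) / len)
  segments <- data.frame(
    segment = seq_len(n_seg),
    start = (seq_len(n_seg) - 1L) * len + 1L,
    end = seq_len(n_seg) * len
  )
  structure(
    list(samples = rec$samples, fs = rec$fs, duration = rec$duration,
         rhythm = rec$rhythm, atrium = rec$atrium,
         position_id = rec$position_id, truth = rec$truth,
         segments = segments, n_segments = n_seg, segment_s = segment_s),
    class = "segmented_recording"
  )
}

#' @export
print.segmented_recording <- function(x, ...) {
  cat(sprintf("Segmented EGM recording: %d segments of %g s (64 x %d samples)\n",
              x$n_segments, x$segment_s, ncol(x$samples)))
  invisible(x)
}
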