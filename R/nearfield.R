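# Near-field contact scoring.
#
# Per 2-s segment, each channel's signal energy is decomposed into a
# conduction component (the best normalized cross-correlation with a
# neighbor at a physiologic 5-50 ms lag), an instantaneous component (the
# zero-lag correlation with neighbors, evaluated only when no conduction is
# found -- the signature of far-field pickup), and a fractionation
# remainder. A channel-segment is scored near-field (mask = 1) when the
# instantaneous ratio stays below 0.3; the per-channel mean of the mask
# over segments is the summative near-field score, and electrodes scoring
# below 0.7 are treated as having poor tissue contact.

# normalized cross-correlation over all non-negative lags 0..N,
# N = floor(len/2): r[dt+1] = sum_{t=1..N} X[t+dt] Y[t], normalized by the
# windowed energies sqrt(sum X[t+dt]^2 * sum Y[t]^2) over the same windows
xcorr_lags <- function(X, Y) {
  L <- length(X)
  stopifnot(length(Y) == L)
  N <- L %/% 2L
  M <- stats::nextn(2L * N, 2)
  fx <- stats::fft(c(X[seq_len(2L * N)], rep(0, M - 2L * N)))
  fy <- stats::fft(c(Y[seq_len(N)], rep(0, M - N)))
  cc <- Re(stats::fft(fx * Conj(fy), inverse = TRUE)) / M
  num <- cc[seq_len(N + 1L)]                    # lags 0..N
  csx <- cumsum(c(0, X^2))
  ex <- csx[(0:N) + N + 1L] - csx[(0:N) + 1L]    # sum X[t+dt]^2, t = 1..N
  ey <- sum(Y[seq_len(N)]^2)
  den <- sqrt(ex * ey)
  r <- ifelse(den > 1e-300, num / den, 0)
  pmin(pmax(r, -1), 1)
}

#' Normalized cross-correlation at a single lag
#'
#' \code{sum_(t=1..N) X[t+dt] Y[t]} with \code{N = floor(len/2)},
#' normalized by the windowed signal energies over the same index windows,
#' so the result lies in \code{[-1, 1]}. A zero-energy window returns 0.
#'
#' @param X,Y equal-length numeric signals (a channel and a neighbor,
#'   restricted to one segment).
#' @param dt non-negative integer lag in samples, \code{0 <= dt <= N}.
#' @return correlation value in \code{[-1, 1]}.
#' @export
xcorr_norm <- function(X, Y, dt = 0L) {
  L <- length(X)
  if (length(Y) != L) stop("X and Y must have equal length")
  N <- L %/% 2L
  dt <- as.integer(dt)
  if (dt < 0L || dt > N) stop("dt must be in 0..floor(len/2)")
  tt <- seq_len(N)
  num <- sum(X[tt + dt] * Y[tt])
  den <- sqrt(sum(X[tt + dt]^2) * sum(Y[tt]^2))
  if (den <= 1e-300) return(0)
  min(max(num / den, -1), 1)
}

# neighbor index table: rows = channel 1..64, entries in 1..66 where
# 65 = P1 (mean of ring 1) and 66 = P8 (mean of ring 8)
neighbor_indices <- function(grid) {
  lab <- c(grid$channels$label, "P1", "P8")
  t(vapply(grid$channels$label, function(l) {
    match(grid$neighbors[[l]], lab)
  }, integer(4)))
}

#' Conduction component of one channel against its neighbors
#'
#' For each neighbor, the pairwise conduction component is the highest peak
#' of the normalized cross-correlation over lags; because a wavefront may
#' reach either electrode first, both orderings (X delayed against Y, and Y
#' delayed against X) are searched and the overall maximum taken. The
#' component is zeroed unless the best lag falls in the 5-50 ms conduction
#' window (shorter lags are far-field, longer ones too slow for
#' conduction). The channel's conduction ratio is the mean of the non-zero
#' pairwise components, or 0 when every pair is zeroed.
#'
#' @param X numeric signal (one channel, one segment).
#' @param neighbors list of equal-length neighbor signals (including polar
#'   virtual channels where applicable).
#' @param fs sampling rate in Hz (converts the lag grid to ms).
#' @param lag_window conduction window in ms, default \code{c(5, 50)}.
#' @return list with \code{RE_cond} (channel conduction ratio) and
#'   \code{dt_star} (best in-window lag in ms of the strongest non-zero
#'   pair, or \code{NA} when none).
#' @export
conduction_component <- function(X, neighbors, fs, lag_window = c(5, 50)) {
  if (length(neighbors) == 0) stop("no neighbors supplied")
  comps <- numeric(length(neighbors))
  lags <- rep(NA_real_, length(neighbors))
  for (k in seq_along(neighbors)) {
    Y <- neighbors[[k]]
    r1 <- xcorr_lags(X, Y)
    r2 <- xcorr_lags(Y, X)
    r <- pmax(r1, r2)
    best <- which.max(r)
    dt_ms <- (best - 1L) / fs * 1000
    if (dt_ms >= lag_window[1] && dt_ms <= lag_window[2]) {
      comps[k] <- r[best]
      lags[k] <- dt_ms
    }
  }
  nz <- comps != 0
  if (any(nz)) {
    list(RE_cond = mean(comps[nz]), dt_star = lags[nz][which.max(comps[nz])],
         pairwise = comps)
  } else {
    list(RE_cond = 0, dt_star = NA_real_, pairwise = comps)
  }
}

#' Instantaneous (far-field) component of one channel
#'
#' Defined only in the absence of conduction: when \code{RE_cond != 0} the
#' instantaneous ratio is 0; otherwise it is the mean over all neighbors of
#' the normalized correlation at zero lag.
#'
#' @param X numeric signal (one channel, one segment).
#' @param neighbors list of equal-length neighbor signals.
#' @param RE_cond the channel's conduction ratio from
#'   [conduction_component()].
#' @return the instantaneous energy ratio.
#' @export
instantaneous_component <- function(X, neighbors, RE_cond = 0) {
  if (RE_cond != 0) return(0)
  mean(vapply(neighbors, function(Y) xcorr_norm(X, Y, 0L), numeric(1)))
}

#' Near-field contact scoring of a segmented recording
#'
#' Computes, for every channel and 2-s segment, the conduction and
#' instantaneous energy ratios against the four neighbors (with the polar
#' virtual channels P1/P8 as the missing ring neighbors), the binary
#' near-field mask (1 iff the instantaneous ratio is below
#' \code{inst_threshold}), the per-channel summative score (mean of the
#' mask over segments), and the contact flag (score at or above
#' \code{score_threshold}).
#'
#' \code{mode = "caption"} applies the alternative rule that scores a
#' channel-segment near-field only when it shows a positive cross-
#' correlation peak with at least one neighbor at a 5-50 ms shift
#' (\code{RE_cond > 0}); under the default \code{"energy"} rule a channel
#' with neither conduction nor far-field correlation still counts as
#' near-field.
#'
#' @param segrec a \code{segmented_recording}.
#' @param grid a \code{basket_grid}.
#' @param inst_threshold instantaneous-ratio cutoff for the mask
#'   (default 0.3).
#' @param score_threshold summative-score cutoff for good contact
#'   (default 0.7; contact is poor strictly below it).
#' @param mode \code{"energy"} (default) or \code{"caption"}.
#' @return object of class \code{nearfield_components}: matrices
#'   \code{RE_cond}, \code{RE_inst}, \code{RE_frac}, \code{dt_star},
#'   \code{mask} (all 64 x n_segments), vector \code{score} (length 64),
#'   logical \code{contact}, and the thresholds used.
#' @export
nearfield_score <- function(segrec, grid = build_grid(),
                            inst_threshold = 0.3, score_threshold = 0.7,
                            mode = c("energy", "caption")) {
  stopifnot(inherits(segrec, "segmented_recording"))
  mode <- match.arg(mode)
  if (segrec$n_segments < 1) stop("need >= 1 segment")
  nbr <- neighbor_indices(grid)
  ring1 <- which(grid$channels$ring == 1L)
  ring8 <- which(grid$channels$ring == 8L)
  n_seg <- segrec$n_segments

  RE_cond <- matrix(0, 64, n_seg)
  RE_inst <- matrix(0, 64, n_seg)
  dt_star <- matrix(NA_real_, 64, n_seg)

  for (s in seq_len(n_seg)) {
    idx <- segrec$segments$start[s]:segrec$segments$end[s]
    seg <- segrec$samples[, idx, drop = FALSE]
    sig <- rbind(seg, colMeans(seg[ring1, , drop = FALSE]),
                 colMeans(seg[ring8, , drop = FALSE]))
    for (i in 1:64) {
      nb <- lapply(nbr[i, ], function(j) sig[j, ])
      cc <- conduction_component(sig[i, ], nb, segrec$fs)
      RE_cond[i, s] <- cc$RE_cond
      dt_star[i, s] <- cc$dt_star
      RE_inst[i, s] <- instantaneous_component(sig[i, ], nb, cc$RE_cond)
    }
  }
  mask <- if (mode == "energy") {
    (RE_inst < inst_threshold) * 1L
  } else {
    (RE_cond > 0) * 1L
  }
  score <- rowMeans(mask)
  structure(
    list(RE_cond = RE_cond, RE_inst = RE_inst,
         RE_frac = 1 - RE_cond - RE_inst, dt_star = dt_star,
         mask = mask, score = score, contact = score >= score_threshold,
         inst_threshold = inst_threshold, score_threshold = score_threshold,
         mode = mode),
    class = "nearfield_components"
  )
}

#' @export
print.nearfield_components <- function(x, ...) {
  cat(sprintf("Near-field components: 64 channels x %d segments (%s rule)\n",
              ncol(x$mask), x$mode))
  cat(sprintf("%d electrodes with good contact (score >= %.2g)\n",
              sum(x$contact), x$score_threshold))
  invisible(x)
}

#' Tabulate near-field results
#'
#' @param nf a \code{nearfield_components}.
#' @param grid a \code{basket_grid}.
#' @return list of two data frames: \code{by_segment} (channel, segment,
#'   RE_cond, RE_inst, mask) and \code{summary} (channel, score, contact).
#' @export
nearfield_table <- function(nf, grid = build_grid()) {
  stopifnot(inherits(nf, "nearfield_components"))
  n_seg <- ncol(nf$mask)
  by_segment <- data.frame(
    channel = rep(grid$channels$label, times = n_seg),
    segment = rep(seq_len(n_seg), each = 64),
    RE_cond = as.vector(nf$RE_cond),
    RE_inst = as.vector(nf$RE_inst),
    mask = as.vector(nf$mask)
  )
  summary <- data.frame(
    channel = grid$channels$label,
    score = nf$score,
    contact = nf$contact
  )
  list(by_segment = by_segment, summary = summary)
}
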