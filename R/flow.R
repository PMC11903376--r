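# Horn-Schunck optical flow on interpolated frame stacks, and its summary
# into per-2-s-segment mean flow vectors at the electrode positions (the
# EGF Segment Map). The per-electrode temporal mean is taken over raw
# vectors, so opposing instantaneous flows cancel: the modulus of the mean
# vector is the local flow-consistency measure that EGFC averages.

# 3x3 neighborhood mean with the classic Horn-Schunck weights
# (1/6 edge, 1/12 diagonal), replicated boundaries
hs_average <- function(m) {
  n <- nrow(m); p <- ncol(m)
  up    <- m[c(1, 1:(n - 1)), , drop = FALSE]
  down  <- m[c(2:n, n), , drop = FALSE]
  left  <- m[, c(1, 1:(p - 1)), drop = FALSE]
  right <- m[, c(2:p, p), drop = FALSE]
  ul <- up[, c(1, 1:(p - 1)), drop = FALSE]
  ur <- up[, c(2:p, p), drop = FALSE]
  dl <- down[, c(1, 1:(p - 1)), drop = FALSE]
  dr <- down[, c(2:p, p), drop = FALSE]
  (up + down + left + right) / 6 + (ul + ur + dl + dr) / 12
}

# central spatial differences (replicated boundary), forward temporal
hs_gradients <- function(a, b) {
  m <- (a + b) / 2
  n <- nrow(m); p <- ncol(m)
  Ix <- (m[, c(2:p, p), drop = FALSE] - m[, c(1, 1:(p - 1)), drop = FALSE]) / 2
  Iy <- (m[c(2:n, n), , drop = FALSE] - m[c(1, 1:(n - 1)), , drop = FALSE]) / 2
  list(Ix = Ix, Iy = Iy, It = b - a)
}

#' Flow-estimation parameters
#'
#' @param alpha Horn-Schunck smoothness weight (regularization; default
#'   0.5, at which the iteration converges within the default budget on
#'   the amplitude scale of interpolated electrogram frames); larger
#'   values give smoother, smaller-magnitude fields.
#' @param n_iter number of fixed-point iterations.
#' @return list of class \code{flow_params}.
#' @export
flow_params <- function(alpha = 0.5, n_iter = 100) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (n_iter < 1) stop("n_iter must be >= 1")
  structure(list(alpha = alpha, n_iter = n_iter), class = "flow_params")
}

#' Horn-Schunck optical flow between two frames
#'
#' Classic global-smoothness variational flow: iterates
#' \code{u <- ubar - Ix (Ix ubar + Iy vbar + It) / (alpha^2 + Ix^2 + Iy^2)}
#' (and symmetrically for \code{v}), where \code{ubar, vbar} are local
#' neighborhood means. Spatial gradients are central differences of the
#' frame-pair average; the temporal gradient is the forward difference.
#'
#' @param frame_a,frame_b numeric matrices of identical shape (rows = y,
#'   columns = x).
#' @param params a [flow_params()].
#' @param u0,v0 optional initial fields (warm start); default zero.
#' @param use_compiled run the iteration loop in compiled code (identical
#'   arithmetic; the pure-R path is kept as a cross-check).
#' @return list with \code{u} (flow along x / columns) and \code{v} (flow
#'   along y / rows), in pixels per frame.
#' @useDynLib egflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @export
horn_schunck <- function(frame_a, frame_b, params = flow_params(),
                         u0 = NULL, v0 = NULL, use_compiled = TRUE) {
  if (!all(dim(frame_a) == dim(frame_b))) stop("frame shape mismatch")
  g <- hs_gradients(frame_a, frame_b)
  u <- if (is.null(u0)) frame_a * 0 else u0
  v <- if (is.null(v0)) frame_a * 0 else v0
  if (use_compiled) {
    return(.hs_iterate_cpp(g$Ix, g$Iy, g$It, params$alpha, params$n_iter,
                           u, v))
  }
  denom <- params$alpha^2 + g$Ix^2 + g$Iy^2
  for (k in seq_len(params$n_iter)) {
    ubar <- hs_average(u)
    vbar <- hs_average(v)
    t <- (g$Ix * ubar + g$Iy * vbar + g$It) / denom
    u <- ubar - g$Ix * t
    v <- vbar - g$Iy * t
  }
  list(u = u, v = v)
}

#' Summarize flow into per-segment mean vectors at electrodes
#'
#' Runs Horn-Schunck over every consecutive frame pair, samples the
#' instantaneous flow at each contacting electrode's pixel, and averages
#' the raw vectors over each 2-s segment's frames. Vectors are returned in
#' grid units per second (pixel displacement times pixel spacing times
#' frame rate). Consecutive pairs are warm-started from the previous
#' solution, which accelerates convergence without changing the fixed
#' point being approximated.
#'
#' @param stack a \code{frame_stack} from [render_frames()].
#' @param grid a \code{basket_grid}.
#' @param contact_mask logical length-64 vector; defaults to the mask the
#'   stack was rendered with. Non-contact electrodes get \code{NA} vectors.
#' @param params a [flow_params()].
#' @return object of class \code{segment_flow}: matrices \code{u}, \code{v},
#'   \code{modulus} (64 x n_segments, grid units/s; \code{NA} where
#'   non-contact), \code{contact_mask}, \code{n_segments}.
#' @export
segment_flow <- function(stack, grid = build_grid(), contact_mask = NULL,
                         params = flow_params()) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(contact_mask)) contact_mask <- stack$contact_mask
  if (!any(contact_mask)) stop("empty contact mask")
  F_n <- dim(stack$frames)[3]
  if (F_n < 2) stop("need >= 2 frames")
  fpseg <- as.integer(round(stack$segment_s * stack$frame_rate))
  n_seg <- nrow(stack$segments)
  if (F_n < fpseg) stop("need >= 2 frames per segment")

  epr <- stack$electrode_pixel[, "row"]
  epc <- stack$electrode_pixel[, "col"]
  eidx <- cbind(epr, epc)
  scale <- stack$pixel_spacing * stack$frame_rate

  usum <- matrix(0, 64, n_seg)
  vsum <- matrix(0, 64, n_seg)
  cnt <- integer(n_seg)
  u <- NULL; v <- NULL
  seg_prev <- 1L
  for (f in seq_len(F_n - 1)) {
    seg <- (f - 1) %/% fpseg + 1L
    if (seg > n_seg) break
    if (seg != seg_prev) {
      # segments are independent analysis units: do not let a previous
      # segment's field seed (and so bias) the next one
      u <- NULL; v <- NULL
      seg_prev <- seg
    }
    fl <- horn_schunck(stack$frames[, , f], stack$frames[, , f + 1],
                       params, u0 = u, v0 = v)
    u <- fl$u; v <- fl$v
    usum[, seg] <- usum[, seg] + u[eidx]
    vsum[, seg] <- vsum[, seg] + v[eidx]
    cnt[seg] <- cnt[seg] + 1L
  }
  keep <- cnt > 0
  um <- sweep(usum[, keep, drop = FALSE], 2, cnt[keep], "/") * scale
  vm <- sweep(vsum[, keep, drop = FALSE], 2, cnt[keep], "/") * scale
  um[!contact_mask, ] <- NA_real_
  vm[!contact_mask, ] <- NA_real_
  structure(
    list(u = um, v = vm, modulus = sqrt(um^2 + vm^2),
         contact_mask = contact_mask, n_segments = sum(keep),
         segment_s = stack$segment_s),
    class = "segment_flow"
  )
}

#' @export
print.segment_flow <- function(x, ...) {
  cat(sprintf("EGF segment flow map: 64 electrodes x %d segments (%d contacting)\n",
              x$n_segments, sum(x$contact_mask)))
  cat(sprintf("mean vector modulus %.3g grid units/s\n",
              mean(x$modulus, na.rm = TRUE)))
  invisible(x)
}

#' Serialize a segment flow map as a tidy table
#'
#' @param sfm a \code{segment_flow}.
#' @param grid a \code{basket_grid}.
#' @return data frame with columns \code{electrode}, \code{segment},
#'   \code{u}, \code{v}, \code{modulus} (contacting electrodes only).
#' @export
segment_flow_table <- function(sfm, grid = build_grid()) {
  stopifnot(inherits(sfm, "segment_flow"))
  idx <- which(sfm$contact_mask)
  do.call(rbind, lapply(seq_len(sfm$n_segments), function(s) {
    data.frame(
      electrode = grid$channels$label[idx],
      segment = s,
      u = sfm$u[idx, s], v = sfm$v[idx, s],
      modulus = sfm$modulus[idx, s]
    )
  }))
}
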