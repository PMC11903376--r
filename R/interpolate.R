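# Biharmonic (Green's function) spline interpolation of electrode
# potentials onto a regular chart raster, one frame per downsampled time
# point. The interpolant is f(x) = sum_j w_j g(|x - x_j|) with
# g(r) = r^2 (ln r - 1) and g(0) = 0, the biharmonic Green's function in
# two dimensions; the weights solve G w = v at the nodes, so the surface
# passes exactly through the supplied electrode values.

green_biharmonic <- function(r) {
  out <- r * 0
  nz <- r > 0
  out[nz] <- r[nz]^2 * (log(r[nz]) - 1)
  out
}

# pairwise Green's matrix between point sets (n x 2, m x 2)
green_matrix <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  green_biharmonic(sqrt(dx^2 + dy^2))
}

#' Fit a biharmonic spline through scattered nodes
#'
#' Solves \code{G w = v} where \code{G_ij = g(|x_i - x_j|)},
#' \code{g(r) = r^2 (ln r - 1)}, \code{g(0) = 0}. Coincident or nearly
#' coincident nodes make the system singular; in that case a small ridge is
#' added to the diagonal and a warning is raised.
#'
#' @param node_xy numeric matrix (n x 2) of node coordinates, n >= 3.
#' @param values numeric vector of length n, or an n x m matrix to fit m
#'   independent surfaces through the same nodes (one factorization).
#' @return object of class \code{biharmonic_fit} with elements \code{nodes}
#'   and \code{weights}.
#' @export
fit_biharmonic <- function(node_xy, values) {
  node_xy <- as.matrix(node_xy)
  if (nrow(node_xy) < 3) stop("need >= 3 nodes")
  values <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(values) != nrow(node_xy)) stop("values/nodes length mismatch")
  G <- green_matrix(node_xy, node_xy)
  w <- tryCatch(
    solve(G, values),
    error = function(e) {
      warning("ill-conditioned biharmonic system; applying ridge jitter")
      solve(G + diag(1e-8 * max(abs(G)), nrow(G)), values)
    }
  )
  structure(list(nodes = node_xy, weights = w), class = "biharmonic_fit")
}

#' Evaluate a biharmonic spline fit
#'
#' @param object a \code{biharmonic_fit}.
#' @param xy numeric matrix (m x 2) of evaluation points.
#' @param ... unused.
#' @return numeric vector (or matrix, for multi-surface fits) of
#'   interpolated values.
#' @export
predict.biharmonic_fit <- function(object, xy, ...) {
  xy <- as.matrix(xy)
  out <- green_matrix(xy, object$nodes) %*% object$weights
  if (ncol(out) == 1) as.numeric(out) else out
}

# raster coordinates: resolution R over [1, 8] on both chart axes.
# With (R - 1) divisible by 7 the electrode positions land exactly on
# raster pixels.
raster_axis <- function(R) seq(1, 8, length.out = R)

#' Render interpolated field frames from a segmented recording
#'
#' Downsamples each channel to the frame rate by windowed (block) averaging,
#' then interpolates every frame's 64 (or fewer, when non-contact electrodes
#' are masked) electrode amplitudes onto an \code{R x R} raster over the
#' chart \code{[1,8] x [1,8]} with the biharmonic spline. The circular
#' spline axis is honored by replicating the nodes at x - 8 and x + 8 and
#' evaluating only the central copy.
#'
#' @param segrec a \code{segmented_recording}.
#' @param grid a \code{basket_grid}.
#' @param contact_mask logical vector of length 64 (\code{TRUE} = electrode
#'   included); \code{NULL} includes all electrodes.
#' @param frame_rate frames per second; must divide \code{fs}.
#' @param R raster resolution per axis (default 29: 0.25 grid-unit pixels,
#'   4x oversampling of the electrode lattice, electrodes on pixel centers).
#' @param periodic replicate nodes across the circular spline axis.
#' @param xpad_units extra chart width rendered beyond each spline-axis
#'   edge (grid units). The flow solver has no notion of the circular
#'   seam; padding the raster with the periodic continuation of the field
#'   gives it proper context there, and without it spurious divergence
#'   appears along the seam meridian.
#' @return object of class \code{frame_stack}: \code{frames} array
#'   (R x Rx x F, rows = ring axis y, columns = spline axis x including
#'   the periodic padding), \code{frame_rate}, \code{pixel_spacing} (grid
#'   units per pixel), \code{electrode_pixel} (64 x 2 matrix of [row, col]
#'   pixel indices), and the segment table carried over from \code{segrec}.
#' @export
render_frames <- function(segrec, grid = build_grid(), contact_mask = NULL,
                          frame_rate = 50, R = 29, periodic = TRUE,
                          xpad_units = 2) {
  stopifnot(inherits(segrec, "segmented_recording"))
  fs <- segrec$fs
  if (fs %% frame_rate != 0) stop("frame_rate must divide fs")
  if (R < 8) stop("raster resolution R must be >= 8")
  if (is.null(contact_mask)) contact_mask <- rep(TRUE, 64)
  if (!any(contact_mask)) stop("all channels masked")
  block <- fs %/% frame_rate
  n_use <- (ncol(segrec$samples) %/% block) * block
  F_n <- n_use %/% block

  # block-average downsampling: channels x frames
  v <- segrec$samples[, seq_len(n_use), drop = FALSE]
  dim(v) <- c(64, block, F_n)
  v <- apply(v, c(1, 3), mean)

  ex <- grid$channels$x[contact_mask]
  ey <- grid$channels$y[contact_mask]
  vals <- v[contact_mask, , drop = FALSE]
  if (periodic) {
    nodes <- cbind(c(ex - 8, ex, ex + 8), c(ey, ey, ey))
    vals <- rbind(vals, vals, vals)  # same electrode order in each copy
  } else {
    nodes <- cbind(ex, ey)
  }
  fit <- fit_biharmonic(nodes, vals)

  step <- 7 / (R - 1)
  pad <- if (periodic) as.integer(round(xpad_units / step)) else 0L
  ax_y <- raster_axis(R)
  ax_x <- seq(1 - pad * step, 8 + pad * step, by = step)
  Rx <- length(ax_x)
  eval_xy <- cbind(rep(ax_x, each = R), rep(ax_y, times = Rx))  # y fastest
  fr <- predict(fit, eval_xy)                                   # (R*Rx) x F
  frames <- array(fr, dim = c(R, Rx, F_n))                      # [y, x, f]

  epix <- cbind(
    row = as.integer(round((grid$channels$y - 1) / step)) + 1L,
    col = as.integer(round((grid$channels$x - 1) / step)) + 1L + pad
  )
  structure(
    list(frames = frames, frame_rate = frame_rate, R = R,
         pixel_spacing = step, electrode_pixel = epix,
         contact_mask = contact_mask, segments = segrec$segments,
         segment_s = segrec$segment_s, fs = fs),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("Frame stack: %d frames of %d x %d @ %g fps (pixel = %.3g grid units)\n",
              dim(x$frames)[3], dim(x$frames)[1], dim(x$frames)[2],
              x$frame_rate, x$pixel_spacing))
  invisible(x)
}
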