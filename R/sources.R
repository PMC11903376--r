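# Focal-source detection: a source is an origin of divergent flow in the
# segment flow maps. Per segment, candidate origins are local maxima of the
# flow-field divergence on the 8 x 8 electrode lattice that exceed a
# divergence threshold and show outward (radially positive) flow in most
# surrounding lattice directions; candidates are merged across segments
# into sources, and source activity (SAC) is the percentage of segments in
# which the source is active.

# fill NA lattice vectors from the mean of available 4-neighbors
# (periodic in the spline axis), iterated to propagate inwards
fill_missing_lattice <- function(m) {
  for (it in 1:25) {
    if (!anyNA(m)) break
    nas <- which(is.na(m), arr.ind = TRUE)
    for (r in seq_len(nrow(nas))) {
      s <- nas[r, 1]; g <- nas[r, 2]
      vals <- c(
        m[(s - 2) %% 8 + 1, g], m[s %% 8 + 1, g],
        if (g > 1) m[s, g - 1] else NA, if (g < 8) m[s, g + 1] else NA
      )
      if (any(!is.na(vals))) m[s, g] <- mean(vals, na.rm = TRUE)
    }
  }
  m[is.na(m)] <- 0
  m
}

#' Divergence of a lattice flow field
#'
#' Computes \code{du/dx + dv/dy} on the 8 x 8 electrode lattice by central
#' differences, periodic across the spline axis (x) and one-sided at the
#' ring boundaries (y). Vectors missing at non-contact electrodes are first
#' filled from neighbor means.
#'
#' @param u,v 8 x 8 matrices indexed \code{[spline, ring]}: the x (spline
#'   axis) and y (ring axis) flow components in grid units/s; \code{NA}
#'   marks missing electrodes.
#' @return 8 x 8 divergence matrix (per grid unit).
#' @export
divergence_field <- function(u, v) {
  stopifnot(all(dim(u) == c(8, 8)), all(dim(v) == c(8, 8)))
  if (sum(!is.na(u)) < 9) stop("fewer than 3 x 3 valid vectors")
  u <- fill_missing_lattice(u)
  v <- fill_missing_lattice(v)
  dudx <- (u[c(2:8, 1), ] - u[c(8, 1:7), ]) / 2          # periodic splines
  dvdy <- v
  dvdy[, 2:7] <- (v[, 3:8] - v[, 1:6]) / 2               # central interior
  dvdy[, 1] <- v[, 2] - v[, 1]                            # one-sided rings
  dvdy[, 8] <- v[, 8] - v[, 7]
  dudx + dvdy
}

# segment-flow matrices (64 x n_seg) reshaped to [spline, ring] lattices
lattice_from_channels <- function(x) {
  matrix(x, nrow = 8, ncol = 8, byrow = TRUE)  # channel = 8*(spline-1)+ring
}

# candidate origins in one segment: local divergence maxima with
# sufficient outward angular coverage
segment_candidates <- function(u8, v8, tau_div, tau_cov) {
  uf <- fill_missing_lattice(u8)
  vf <- fill_missing_lattice(v8)
  dv <- divergence_field(u8, v8)
  dirs <- expand.grid(dx = -1:1, dy = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0), ]
  out <- NULL
  for (s in 1:8) {
    for (g in 1:8) {
      if (dv[s, g] <= tau_div) next
      is_max <- TRUE
      n_out <- 0L; n_avail <- 0L
      for (d in seq_len(nrow(dirs))) {
        ss <- (s + dirs$dx[d] - 1) %% 8 + 1
        gg <- g + dirs$dy[d]
        if (gg < 1 || gg > 8) next
        if (dv[ss, gg] > dv[s, g]) is_max <- FALSE
        n_avail <- n_avail + 1L
        rad <- uf[ss, gg] * dirs$dx[d] + vf[ss, gg] * dirs$dy[d]
        if (rad > 0) n_out <- n_out + 1L
      }
      if (!is_max || n_avail == 0) next
      if (n_out / n_avail < tau_cov) next
      # sub-lattice refinement: focus-of-expansion least squares. For a
      # divergent field the rays p + t*v of the surrounding vectors
      # intersect at the origin of flow; minimize the squared normal
      # distance sum_i w_i ((x - p_i) . n_i)^2 with n_i the unit normal of
      # v_i, weighted by speed. Exact for an ideal radial field, and
      # independent of which lattice cell happens to win the local
      # maximum. Falls back to the peak cell when ill-conditioned.
      A <- matrix(0, 2, 2); b <- c(0, 0); wtot <- 0
      for (dx in -2:2) {
        for (dy in -2:2) {
          if (dx^2 + dy^2 > 2.5^2) next
          ss <- (s + dx - 1) %% 8 + 1
          gg <- g + dy
          if (gg < 1 || gg > 8) next
          sp <- sqrt(uf[ss, gg]^2 + vf[ss, gg]^2)
          if (sp < 1e-9) next
          nvec <- c(-vf[ss, gg], uf[ss, gg]) / sp
          p <- c(s + dx, g + dy)      # local (unwrapped) coordinates
          A <- A + sp * (nvec %o% nvec)
          b <- b + sp * nvec * sum(nvec * p)
          wtot <- wtot + sp
        }
      }
      loc <- c(s, g)
      if (wtot > 0) {
        d2 <- A[1, 1] * A[2, 2] - A[1, 2]^2
        if (is.finite(d2) && d2 > 1e-6 * wtot^2) {
          x <- solve(A, b)
          if (sqrt((x[1] - s)^2 + (x[2] - g)^2) <= 1.5) loc <- x
        }
      }
      loc[1] <- (loc[1] - 1) %% 8 + 1
      loc[2] <- min(max(loc[2], 1), 8)
      out <- rbind(out, c(loc[1], loc[2], dv[s, g]))
    }
  }
  out
}

# label a continuous chart location by its two nearest electrodes
nearest_pair_label <- function(loc, grid) {
  d <- chart_distance(grid$channels$x, grid$channels$y, loc[1], loc[2])
  i <- order(d)[1:2]
  paste(grid$channels$label[i], collapse = "-")
}

#' Detect sources in a recording's segment flow maps
#'
#' Per segment, candidate origins are lattice cells whose divergence
#' exceeds \code{tau_div}, is a local maximum over the 8 surrounding cells,
#' and whose surrounding vectors point outward (positive radial component)
#' in at least a fraction \code{tau_cov} of the available directions.
#' Candidates closer than \code{merge_radius} (in electrode spacings, on
#' the periodic chart) are merged into a single source across segments;
#' each source's activity (SAC) is 100 times the fraction of segments with
#' an assigned candidate.
#'
#' @param sfm a \code{segment_flow}.
#' @param grid a \code{basket_grid}.
#' @param tau_div divergence threshold (grid units/s per grid unit),
#'   calibrated on the synthetic generator so that organized planar
#'   propagation produces no spurious active sources while focal firing
#'   (whose divergence peaks are an order of magnitude higher) is kept.
#' @param tau_cov outward angular-coverage threshold (fraction of
#'   surrounding directions).
#' @param merge_radius cross-segment merge distance in electrode spacings.
#' @param recording_id label carried into the sources.
#' @return list of \code{egf_source} objects, each with \code{location}
#'   (continuous (spline, ring) chart coordinate), \code{label} (nearest
#'   electrode pair, e.g. \code{"C5-C6"}), \code{active} (logical per
#'   segment), \code{SAC} (percent), \code{recording_id}.
#' @export
detect_sources <- function(sfm, grid = build_grid(), tau_div = 6,
                           tau_cov = 0.875, merge_radius = 1.0,
                           recording_id = NA_character_) {
  stopifnot(inherits(sfm, "segment_flow"))
  n_seg <- sfm$n_segments
  cand_loc <- NULL
  cand_seg <- integer(0)
  for (s in seq_len(n_seg)) {
    u8 <- lattice_from_channels(sfm$u[, s])
    v8 <- lattice_from_channels(sfm$v[, s])
    if (all(is.na(u8)) || all(u8 == 0, na.rm = TRUE)) next
    cand <- segment_candidates(u8, v8, tau_div, tau_cov)
    if (is.null(cand)) next
    cand_loc <- rbind(cand_loc, cand[, 1:2, drop = FALSE])
    cand_seg <- c(cand_seg, rep(s, nrow(cand)))
  }
  if (is.null(cand_loc)) return(list())

  # single-linkage clustering: candidates within merge_radius of any other
  # cluster member belong to the same source (union-find)
  n <- nrow(cand_loc)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (chart_distance(cand_loc[i, 1], cand_loc[i, 2],
                         cand_loc[j, 1], cand_loc[j, 2]) <= merge_radius) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(r) {
    idx <- which(roots == r)
    # cluster center: mean location with the spline axis averaged on the
    # circle (offsets relative to the first member)
    x0 <- cand_loc[idx[1], 1]
    dx <- ((cand_loc[idx, 1] - x0 + 4) %% 8) - 4
    loc <- c((x0 + mean(dx) - 1) %% 8 + 1, mean(cand_loc[idx, 2]))
    active <- seq_len(n_seg) %in% cand_seg[idx]
    structure(
      list(location = loc, label = nearest_pair_label(loc, grid),
           active = active, SAC = 100 * mean(active),
           recording_id = recording_id),
      class = "egf_source"
    )
  })
}

#' Is a source clinically significant?
#'
#' @param source an \code{egf_source} (or a bare SAC percentage).
#' @param threshold SAC threshold in percent (default 25; significance is
#'   SAC at or above the threshold).
#' @return logical.
#' @export
classify_significance <- function(source, threshold = 25) {
  sac <- if (inherits(source, "egf_source")) source$SAC else as.numeric(source)
  sac >= threshold
}

#' @export
print.egf_source <- function(x, ...) {
  cat(sprintf("EGF source at %s (chart %.2f, %.2f): SAC %.0f%%%s\n",
              x$label, x$location[1], x$location[2], x$SAC,
              if (classify_significance(x)) " [significant]" else ""))
  invisible(x)
}
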