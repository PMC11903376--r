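# Basket-catheter electrode geometry: 8 splines (A-H) x 8 rings (1-8),
# unwrapped onto a 2-D chart whose spline axis is circular.

#' Build the canonical 64-electrode basket grid
#'
#' Constructs the 8 splines x 8 rings electrode layout used throughout the
#' package. Channels are numbered \code{1..64} with \code{A1 = 1},
#' \code{A8 = 8}, \code{B1 = 9}, ..., \code{H8 = 64}. Each physical
#' electrode has exactly four neighbors: the same ring on the two adjacent
#' splines (the spline axis is circular, so spline A adjoins spline H) and
#' the two adjacent rings on the same spline. At the poles of the basket,
#' two artificial polar electrodes stand in for the missing ring: \code{P1}
#' (the mean signal of all ring-1 electrodes) is a neighbor of every ring-1
#' electrode and \code{P8} (mean of ring 8) of every ring-8 electrode.
#'
#' Electrode chart coordinates place spline index on the x axis (periodic
#' with period 8) and ring index on the y axis, with unit spacing on both
#' axes. This flat chart, not the true 3-D basket shape, is the domain for
#' interpolation and flow estimation.
#'
#' @return An object of class \code{basket_grid}: a list with
#'   \item{channels}{data frame with columns \code{channel}, \code{spline},
#'     \code{ring}, \code{label}, \code{x}, \code{y}}
#'   \item{neighbors}{named list, one character vector of four neighbor
#'     labels per channel label (polar neighbors are \code{"P1"}/\code{"P8"})}
#'   \item{n_splines, n_rings}{both 8}
#' @examples
#' grid <- build_grid()
#' grid$neighbors[["C4"]]   # B4, D4, C3, C5
#' grid$neighbors[["A1"]]   # H1, B1, P1, A2
#' @export
build_grid <- function() {
  splines <- LETTERS[1:8]
  channels <- data.frame(
    channel = 1:64,
    spline  = rep(splines, each = 8),
    ring    = rep(1:8, times = 8),
    stringsAsFactors = FALSE
  )
  channels$label <- paste0(channels$spline, channels$ring)
  channels$x <- rep(1:8, each = 8)   # spline index, periodic axis
  channels$y <- channels$ring

  neighbors <- vector("list", 64)
  names(neighbors) <- channels$label
  for (i in 1:64) {
    s <- (channels$channel[i] - 1L) %/% 8L + 1L
    r <- channels$ring[i]
    left  <- splines[(s - 2L) %% 8L + 1L]
    right <- splines[s %% 8L + 1L]
    below <- if (r == 1L) "P1" else paste0(splines[s], r - 1L)
    above <- if (r == 8L) "P8" else paste0(splines[s], r + 1L)
    neighbors[[i]] <- c(paste0(left, r), paste0(right, r), below, above)
  }

  structure(
    list(channels = channels, neighbors = neighbors,
         n_splines = 8L, n_rings = 8L),
    class = "basket_grid"
  )
}

#' Map a channel number to its (spline, ring) position
#'
#' The channel numbering convention is \code{channel = 8 * (spline_index -
#' 1) + ring} with spline A having index 1, so \code{unwrap(1)} is A1 and
#' \code{unwrap(64)} is H8.
#'
#' @param channel integer vector of channel numbers in \code{1..64}.
#' @return data frame with columns \code{spline} (factor-free character,
#'   "A".."H") and \code{ring} (integer 1..8).
#' @seealso [channel_index()] for the inverse mapping.
#' @export
unwrap <- function(channel) {
  channel <- as.integer(channel)
  if (any(is.na(channel)) || any(channel < 1L) || any(channel > 64L)) {
    stop("channel must be in 1..64")
  }
  data.frame(
    spline = LETTERS[(channel - 1L) %/% 8L + 1L],
    ring   = (channel - 1L) %% 8L + 1L,
    stringsAsFactors = FALSE
  )
}

#' Map (spline, ring) to the channel number
#'
#' @param spline character vector of spline letters "A".."H" (or integer
#'   spline indices 1..8).
#' @param ring integer ring numbers 1..8.
#' @return integer channel numbers in 1..64.
#' @export
channel_index <- function(spline, ring) {
  if (is.character(spline)) spline <- match(toupper(spline), LETTERS[1:8])
  spline <- as.integer(spline)
  ring <- as.integer(ring)
  if (any(is.na(spline)) || any(spline < 1L) || any(spline > 8L)) {
    stop("spline must be A..H (or 1..8)")
  }
  if (any(is.na(ring)) || any(ring < 1L) || any(ring > 8L)) {
    stop("ring must be in 1..8")
  }
  8L * (spline - 1L) + ring
}

#' Shortest distance on the electrode chart
#'
#' Euclidean distance between chart points, treating the spline (x) axis as
#' periodic with period 8 and the ring (y) axis as bounded.
#'
#' @param x1,y1,x2,y2 chart coordinates (spline axis x, ring axis y).
#' @return numeric distances.
#' @export
chart_distance <- function(x1, y1, x2, y2) {
  dx <- abs(x1 - x2) %% 8
  dx <- pmin(dx, 8 - dx)
  sqrt(dx^2 + (y1 - y2)^2)
}

#' Export the grid definition as JSON
#'
#' Writes one record per channel with its number, spline, ring and the four
#' neighbor labels.
#'
#' @param grid a \code{basket_grid}.
#' @param path output file path; if \code{NULL}, the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
grid_to_json <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "basket_grid"))
  recs <- lapply(seq_len(nrow(grid$channels)), function(i) {
    list(
      channel  = grid$channels$channel[i],
      spline   = grid$channels$spline[i],
      ring     = grid$channels$ring[i],
      neighbors = grid$neighbors[[grid$channels$label[i]]]
    )
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' @export
print.basket_grid <- function(x, ...) {
  cat("Basket electrode grid: 8 splines (A-H, circular) x 8 rings (1-8)\n")
  cat("64 channels, 4 neighbors each; polar virtual electrodes P1, P8\n")
  invisible(x)
}
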