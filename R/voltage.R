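# Healthy-voltage quantification from bipolar voltage-map images.
#
# Clinical voltage maps render amplitudes above 0.5 mV purple, below
# 0.1 mV grey, and intermediate amplitudes on a blue-to-red spectrum; the
# percentage of high-voltage (healthy) surface is recovered by classifying
# pixels into those color classes.

#' Default color-classification palette
#'
#' Hue/saturation/value range rules (hue in degrees 0-360, s and v in
#' 0-1) for the four pixel classes. The exact clinical color scale is
#' system-dependent; these defaults match common electroanatomic maps and
#' the synthetic images from [simulate_voltage_image()].
#'
#' @param purple_hue hue range classed as purple (high voltage).
#' @param max_grey_sat saturation below which a mid-value pixel is grey.
#' @param min_color_sat saturation at or above which a pixel counts as
#'   colored.
#' @param background_value value above which a desaturated pixel is
#'   background (white); pixels darker than \code{min_value} are also
#'   background.
#' @param min_value,grey_value value bounds for the grey class.
#' @return named list of palette rules.
#' @export
voltage_palette <- function(purple_hue = c(255, 315), max_grey_sat = 0.15,
                            min_color_sat = 0.25,
                            background_value = 0.95, min_value = 0.05,
                            grey_value = c(0.2, 0.85)) {
  list(purple_hue = purple_hue, max_grey_sat = max_grey_sat,
       min_color_sat = min_color_sat, background_value = background_value,
       min_value = min_value, grey_value = grey_value)
}

#' Classify voltage-map pixels by color
#'
#' @param image an RGB array (\code{h x w x 3}, values in \code{[0, 1]})
#'   or a path to a PNG file.
#' @param palette palette rules from [voltage_palette()].
#' @return list with \code{counts} (named integer vector: purple, grey,
#'   intermediate, background) and \code{class_map} (character matrix).
#' @export
classify_pixels <- function(image, palette = voltage_palette()) {
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) == 2) {
    image <- array(rep(image, 3), dim = c(dim(image), 3))
  }
  if (length(dim(image)) != 3 || dim(image)[3] < 3 || prod(dim(image)) == 0) {
    stop("unreadable image: need a non-empty h x w x 3 RGB array")
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hue <- hsv[1, ] * 360; sat <- hsv[2, ]; val <- hsv[3, ]

  cls <- rep("intermediate", h * w)
  bg <- (val >= palette$background_value & sat < palette$max_grey_sat) |
    val <= palette$min_value
  grey <- !bg & sat < palette$max_grey_sat &
    val >= palette$grey_value[1] & val <= palette$grey_value[2]
  purple <- !bg & !grey & sat >= palette$min_color_sat &
    hue >= palette$purple_hue[1] & hue <= palette$purple_hue[2]
  low_sat <- !bg & !grey & !purple & sat < palette$min_color_sat
  cls[bg | low_sat] <- "background"
  cls[grey] <- "grey"
  cls[purple] <- "purple"

  counts <- c(purple = sum(cls == "purple"), grey = sum(cls == "grey"),
              intermediate = sum(cls == "intermediate"),
              background = sum(cls == "background"))
  list(counts = counts, class_map = matrix(cls, h, w))
}

#' Healthy-voltage percentage from pixel counts
#'
#' Default (\code{rule = "proportion"}): \code{100 * purple / (purple +
#' intermediate)} -- purple as a share of the mapped, non-scar surface, a
#' true surface-area percentage. \code{rule = "ratio"} is the literal
#' purple-to-other-colors quotient \code{100 * purple / intermediate}.
#' \code{include_grey} adds scar (grey) pixels to the denominator under
#' either rule.
#'
#' @param counts named vector from [classify_pixels()].
#' @param rule \code{"proportion"} (default) or \code{"ratio"}.
#' @param include_grey count grey (scar) pixels in the denominator.
#' @return percentage (may exceed 100 under \code{"ratio"}).
#' @export
healthy_percent <- function(counts, rule = c("proportion", "ratio"),
                            include_grey = FALSE) {
  rule <- match.arg(rule)
  p <- counts[["purple"]]
  denom <- counts[["intermediate"]] +
    (if (include_grey) counts[["grey"]] else 0) +
    (if (rule == "proportion") p else 0)
  if (denom == 0) {
    if (p == 0) stop("no colored pixels: healthy percentage undefined")
    stop("zero denominator under rule '", rule, "'")
  }
  100 * p / denom
}

#' Quantify a voltage-map image
#'
#' Classifies pixels and reports the healthy-voltage percentage under both
#' denominator rules.
#'
#' @param image RGB array or PNG path.
#' @param palette palette rules.
#' @param include_grey count grey pixels in the denominators.
#' @return object of class \code{voltage_image_result} with \code{counts},
#'   \code{healthy_percent} (proportion rule), \code{alt_ratio} (literal
#'   ratio rule), and \code{colored} (number of non-background pixels).
#'   When the image contains no colored pixels both percentages are
#'   \code{NA} and \code{undefined} is \code{TRUE}.
#' @export
quantify_voltage_image <- function(image, palette = voltage_palette(),
                                   include_grey = FALSE) {
  cp <- classify_pixels(image, palette)
  colored <- sum(cp$counts[c("purple", "grey", "intermediate")])
  undefined <- colored == 0
  hp <- if (undefined) NA_real_ else {
    tryCatch(healthy_percent(cp$counts, "proportion", include_grey),
             error = function(e) NA_real_)
  }
  ar <- if (undefined) NA_real_ else {
    tryCatch(healthy_percent(cp$counts, "ratio", include_grey),
             error = function(e) NA_real_)
  }
  structure(
    list(counts = cp$counts, healthy_percent = hp, alt_ratio = ar,
         colored = colored, undefined = undefined),
    class = "voltage_image_result"
  )
}

#' @export
print.voltage_image_result <- function(x, ...) {
  cat("Voltage-map quantification\n")
  cat(sprintf("  pixels: purple %d, grey %d, intermediate %d, background %d\n",
              x$counts[["purple"]], x$counts[["grey"]],
              x$counts[["intermediate"]], x$counts[["background"]]))
  if (x$undefined) {
    cat("  no colored pixels: healthy percentage undefined\n")
  } else {
    cat(sprintf("  healthy voltage: %.1f%% (proportion rule), %.1f%% (ratio rule)\n",
                x$healthy_percent, x$alt_ratio))
  }
  invisible(x)
}
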