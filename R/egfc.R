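# Electrographic flow consistency (EGFC): the mean modulus of the
# temporally averaged flow vectors across contacting basket electrodes,
# in arbitrary units. Recording values are aggregated with equal weight
# up the hierarchy recording -> position -> atrium -> patient.

#' EGFC of one recording
#'
#' The mean, over all (contacting electrode, segment) pairs, of the segment
#' flow-vector modulus, scaled by the arbitrary-units constant
#' \code{kappa}. Electrodes with poor contact must be excluded (their
#' near-zero vectors would bias EGFC low), which is why the segment flow
#' map carries the contact mask.
#'
#' @param sfm a \code{segment_flow}.
#' @param contact_mask optional logical length-64 override of the map's
#'   contact mask.
#' @param kappa global scale constant (arbitrary units; default 1).
#' @return EGFC value (non-negative scalar).
#' @export
recording_egfc <- function(sfm, contact_mask = NULL, kappa = 1) {
  stopifnot(inherits(sfm, "segment_flow"))
  if (is.null(contact_mask)) contact_mask <- sfm$contact_mask
  if (!any(contact_mask)) stop("no contacting electrodes")
  kappa * mean(sfm$modulus[contact_mask, , drop = FALSE], na.rm = TRUE)
}

#' Aggregate recording EGFCs to position, atrium and patient means
#'
#' Unweighted means at each level: recordings within a position, positions
#' within an atrium, atria within a patient. Equal weighting of positions
#' prevents atria mapped at more positions from dominating. A patient with
#' a single mapped atrium gets that atrium's value, flagged
#' \code{single_atrium}.
#'
#' @param df data frame with columns \code{patient}, \code{atrium}
#'   (\code{"LA"}/\code{"RA"}), \code{position}, \code{egfc} (one row per
#'   recording), and optionally \code{rhythm}.
#' @return list of data frames \code{by_position}, \code{by_atrium},
#'   \code{by_patient} (the latter with a \code{single_atrium} flag).
#' @export
aggregate_egfc <- function(df) {
  need <- c("patient", "atrium", "position", "egfc")
  if (!all(need %in% names(df))) {
    stop("df must have columns patient, atrium, position, egfc")
  }
  by_position <- stats::aggregate(
    egfc ~ patient + atrium + position, data = df, FUN = mean)
  by_atrium <- stats::aggregate(
    egfc ~ patient + atrium, data = by_position, FUN = mean)
  by_patient <- stats::aggregate(egfc ~ patient, data = by_atrium, FUN = mean)
  n_atria <- stats::aggregate(atrium ~ patient, data = by_atrium,
                              FUN = function(a) length(unique(a)))
  names(n_atria)[2] <- "n_atria"
  by_patient <- merge(by_patient, n_atria, by = "patient")
  by_patient$single_atrium <- by_patient$n_atria < 2
  by_patient$n_atria <- NULL
  list(by_position = by_position, by_atrium = by_atrium,
       by_patient = by_patient)
}

#' Convert a sinus-rhythm EGFC to the AF scale
#'
#' Applies the linear SR-to-AF conversion \code{slope * egfc_sr +
#' intercept}. The coefficients come from a separately published
#' calibration and are not bundled with this package, so they must be
#' supplied explicitly; without them SR values cannot be placed on the AF
#' scale and the function refuses.
#'
#' @param egfc_sr EGFC measured in sinus rhythm.
#' @param slope,intercept conversion coefficients.
#' @return converted value, with attribute \code{converted = TRUE}.
#' @export
sr_to_af <- function(egfc_sr, slope = NULL, intercept = NULL) {
  if (is.null(slope) || is.null(intercept)) {
    stop("SR-to-AF conversion coefficients are not configured; supply ",
         "`slope` and `intercept` (they are not distributed with this ",
         "package)")
  }
  out <- slope * egfc_sr + intercept
  attr(out, "converted") <- TRUE
  out
}
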