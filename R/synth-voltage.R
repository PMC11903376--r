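# Synthetic bipolar voltage-map images for the color-quantification stage.

#' Simulate a bipolar voltage-map image
#'
#' Renders an RGB image mimicking a clinical bipolar voltage map: a roughly
#' elliptical map region on a white background whose pixels are colored
#' purple (high voltage, > 0.5 mV), grey (scar, < 0.1 mV), or an
#' intermediate blue-to-red spectrum, in the requested proportions of the
#' map area. Pixel class assignment is spatially clustered (smoothed random
#' field) so the image has contiguous color regions rather than salt-and-
#' pepper noise.
#'
#' @param high_voltage_fraction proportion of map pixels rendered purple.
#' @param grey_fraction proportion of map pixels rendered grey.
#' @param size image side length in pixels (square image).
#' @param seed RNG seed.
#' @return an \code{height x width x 3} RGB array in \code{[0, 1]} with
#'   attribute \code{truth} holding the exact generated class counts.
#' @export
simulate_voltage_image <- function(high_voltage_fraction = 0.4,
                                   grey_fraction = 0.1,
                                   size = 120, seed = 1L) {
  if (high_voltage_fraction < 0 || grey_fraction < 0 ||
      high_voltage_fraction + grey_fraction > 1) {
    stop("fractions must be >= 0 and sum to <= 1")
  }
  with_seed(derive_seed(seed, 7L), {
    h <- size; w <- size
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    inmap <- ((yy - cy) / (0.42 * h))^2 + ((xx - cx) / (0.45 * w))^2 <= 1

    # clustered class field: rank a smoothed random surface, then cut at the
    # requested quantiles so class proportions are exact
    z <- matrix(stats::rnorm(h * w), h, w)
    k <- stats::dnorm(seq(-2, 2, length.out = 9)); k <- k / sum(k)
    for (i in seq_len(h)) z[i, ] <- stats::filter(z[i, ], k, sides = 2, circular = TRUE)
    for (j in seq_len(w)) z[, j] <- stats::filter(z[, j], k, sides = 2, circular = TRUE)
    n_map <- sum(inmap)
    r <- rank(z[inmap], ties.method = "first")
    n_purple <- round(high_voltage_fraction * n_map)
    n_grey <- round(grey_fraction * n_map)
    cls <- rep("intermediate", n_map)
    cls[r <= n_purple] <- "purple"
    cls[r > n_purple & r <= n_purple + n_grey] <- "grey"

    img <- array(1, dim = c(h, w, 3))  # white background
    rgbm <- matrix(1, nrow = n_map, ncol = 3)
    is_p <- cls == "purple"; is_g <- cls == "grey"; is_i <- cls == "intermediate"
    rgbm[is_p, ] <- matrix(rep(c(0.55, 0.10, 0.85), each = sum(is_p)),
                           ncol = 3)
    rgbm[is_g, ] <- 0.5
    if (any(is_i)) {
      # blue (high end of intermediate) to red (low voltage) hue ramp
      hdeg <- stats::runif(sum(is_i), 0, 240)
      hsv_cols <- grDevices::hsv(h = hdeg / 360, s = 1, v = 0.95)
      rgbm[is_i, ] <- t(grDevices::col2rgb(hsv_cols) / 255)
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inmap] <- rgbm[, ch]
      img[, , ch] <- plane
    }
    attr(img, "truth") <- list(
      purple = n_purple, grey = n_grey,
      intermediate = n_map - n_purple - n_grey,
      background = h * w - n_map
    )
    img
  })
}

#' Generate a synthetic patient cohort with planted phenotypes
#'
#' Builds per-patient recording prescriptions whose pipeline output should
#' recover a planted Type I-IV phenotype. High-EGFC patients (Types I, II)
#' receive organized planar recordings; low-EGFC patients (Types III, IV)
#' fibrillatory ones. Source-positive patients (Types II, III) additionally
#' carry one focal-source recording with the given active fraction.
#' Phenotypes are assigned cyclically I, II, III, IV, so any multiple of
#' four patients is balanced. Outcomes (freedom from AF at follow-up) are
#' drawn from per-phenotype rates mirroring the registry gradient.
#'
#' @param n_patients number of patients (>= 4).
#' @param seed RNG seed; fixed seed gives an identical cohort.
#' @param duration per-recording duration in seconds.
#' @param active_fraction focal-source activity for source-positive patients.
#' @return list of patient prescriptions; each has \code{patient_id},
#'   \code{af_type}, \code{procedure}, \code{true_phenotype},
#'   \code{outcome}, and \code{recordings}, a list of
#'   \code{(scenario, artifacts, rhythm, atrium, position_id)} entries ready
#'   for [simulate_recording()].
#' @export
generate_cohort <- function(n_patients, seed = 1L, duration = 60,
                            active_fraction = 0.5) {
  if (n_patients < 4) stop("n_patients must be >= 4")
  phenos <- rep_len(c("I", "II", "III", "IV"), n_patients)
  ffaf_rate <- c(I = 1.0, II = 0.86, III = 0.43, IV = 0.25)
  with_seed(derive_seed(seed, 13L), {
    lapply(seq_len(n_patients), function(i) {
      ph <- phenos[i]
      high <- ph %in% c("I", "II")
      has_source <- ph %in% c("II", "III")
      base_kind <- if (high) "planar" else "fibrillatory"
      mk <- function(k, seed_k, atrium, pos) {
        list(
          scenario = wave_scenario(
            kind = k, seed = derive_seed(seed, 100L * i + seed_k),
            active_fraction = active_fraction
          ),
          artifacts = artifact_spec(noise_sd = 0.02),
          rhythm = "AF", atrium = atrium, position_id = pos
        )
      }
      recs <- list(mk(base_kind, 1L, "LA", "LA-1"),
                   mk(base_kind, 2L, "RA", "RA-1"))
      if (has_source) recs <- c(recs, list(mk("focal", 3L, "LA", "LA-2")))
      list(
        patient_id = sprintf("SYN-%02d", i),
        af_type = sample(c("PAF", "PeAF", "LS-PeAF"), 1,
                         prob = c(0.36, 0.56, 0.08)),
        procedure = sample(c("de novo", "redo"), 1, prob = c(0.64, 0.36)),
        true_phenotype = ph,
        outcome = if (stats::runif(1) < ffaf_rate[[ph]]) "FFAF" else "recurrence",
        duration = duration,
        recordings = recs
      )
    })
  })
}
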