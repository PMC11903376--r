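# Type I-IV phenotyping: the quadrants of (significant source present?) x
# (patient EGFC at or above the cohort median?).

#' Assign a Type I-IV phenotype
#'
#' Type I: no significant source and EGFC at or above the cohort median.
#' Type II: significant source and EGFC at or above the median.
#' Type III: significant source and EGFC below the median.
#' Type IV: no significant source and EGFC below the median.
#' A source is significant when its SAC reaches \code{sac_threshold}; a
#' patient "has sources" when any recording's source does.
#'
#' @param patient_egfc the patient's overall mean EGFC (AF scale).
#' @param max_sac the maximum SAC (percent) over all sources in all of the
#'   patient's pre-ablation recordings; 0 or \code{-Inf} when none.
#' @param cohort_median median of all patients' overall EGFC.
#' @param sac_threshold SAC significance cutoff in percent (default 25).
#' @return one of \code{"I", "II", "III", "IV"}.
#' @export
classify_phenotype <- function(patient_egfc, max_sac, cohort_median,
                               sac_threshold = 25) {
  has_source <- max_sac >= sac_threshold
  high <- patient_egfc >= cohort_median
  if (!has_source && high) "I"
  else if (has_source && high) "II"
  else if (has_source && !high) "III"
  else "IV"
}

#' Phenotype a cohort of patients
#'
#' Computes the cohort EGFC median (even patient counts take the midpoint
#' of the two central values), assigns each patient a phenotype, and
#' tabulates counts and outcomes per phenotype.
#'
#' @param patients data frame with columns \code{patient}, \code{egfc},
#'   \code{max_sac}, and optionally \code{af_type}, \code{procedure},
#'   \code{outcome} (\code{"FFAF"}, \code{"recurrence"}, \code{"LTFU"}).
#' @param sac_threshold SAC significance cutoff (percent).
#' @return list with \code{median} (cohort EGFC median), \code{patients}
#'   (input plus a \code{phenotype} column), and \code{table} (one row per
#'   phenotype: n, and when available de novo / paroxysmal / FFAF counts).
#' @export
cohort_phenotypes <- function(patients, sac_threshold = 25) {
  if (nrow(patients) < 2) stop("need >= 2 patients")
  med <- stats::median(patients$egfc)
  patients$phenotype <- vapply(seq_len(nrow(patients)), function(i) {
    classify_phenotype(patients$egfc[i], patients$max_sac[i], med,
                       sac_threshold)
  }, character(1))
  types <- c("I", "II", "III", "IV")
  tab <- data.frame(
    phenotype = types,
    n = vapply(types, function(t) sum(patients$phenotype == t), integer(1))
  )
  if ("egfc" %in% names(patients)) {
    tab$egfc_mean <- vapply(types, function(t) {
      v <- patients$egfc[patients$phenotype == t]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  if ("procedure" %in% names(patients)) {
    tab$de_novo <- vapply(types, function(t) {
      sum(patients$procedure[patients$phenotype == t] == "de novo")
    }, integer(1))
  }
  if ("af_type" %in% names(patients)) {
    tab$paroxysmal <- vapply(types, function(t) {
      sum(patients$af_type[patients$phenotype == t] == "PAF")
    }, integer(1))
  }
  if ("outcome" %in% names(patients)) {
    tab$completed_fu <- vapply(types, function(t) {
      sum(patients$outcome[patients$phenotype == t] != "LTFU")
    }, integer(1))
    tab$ffaf <- vapply(types, function(t) {
      sum(patients$outcome[patients$phenotype == t] == "FFAF")
    }, integer(1))
  }
  list(median = med, patients = patients, table = tab)
}
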