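# Registry statistical toolkit: one-tailed pooled two-proportion z-tests,
# one-tailed independent t-tests from summary statistics, and least-squares
# regression with the F-test of the slope. The one-tailed direction is the
# direction of the observed difference.

#' One-tailed two-proportion z-test (pooled, no continuity correction)
#'
#' \code{z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))} with the pooled
#' proportion \code{p = (k1 + k2) / (n1 + n2)}; the one-tailed p-value is
#' the upper-tail normal probability of \code{|z|}.
#'
#' @param k1,n1 successes and size of group 1.
#' @param k2,n2 successes and size of group 2.
#' @return object of class \code{stat_result} with \code{statistic} (z),
#'   \code{p_one_tailed}, and \code{inputs}.
#' @export
two_prop_z <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("degenerate groups: n1 and n2 must be >= 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("need 0 <= k <= n")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  structure(
    list(statistic = z, df = NA_real_,
         p_one_tailed = stats::pnorm(abs(z), lower.tail = FALSE),
         inputs = list(k1 = k1, n1 = n1, k2 = k2, n2 = n2)),
    class = "stat_result"
  )
}

#' One-tailed independent t-test from summary statistics
#'
#' Pooled-variance t with \code{df = n1 + n2 - 2} by default;
#' \code{welch = TRUE} uses the Welch-Satterthwaite form instead.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @param welch use Welch's unequal-variance t.
#' @return object of class \code{stat_result} with \code{statistic} (t),
#'   \code{df}, \code{p_one_tailed}, \code{inputs}. Zero pooled variance
#'   with equal means gives p = 0.5; with unequal means p = 0 and the
#'   result is flagged \code{degenerate}.
#' @export
t_test_from_summary <- function(m1, sd1, n1, m2, sd2, n2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("need n1, n2 >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0")
  degenerate <- FALSE
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    df <- if (se2 == 0) n1 + n2 - 2 else {
      se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    }
    se <- sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  if (se == 0) {
    if (m1 == m2) {
      t <- 0; p <- 0.5
    } else {
      t <- sign(m1 - m2) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    t <- (m1 - m2) / se
    p <- stats::pt(abs(t), df, lower.tail = FALSE)
  }
  structure(
    list(statistic = t, df = df, p_one_tailed = p, degenerate = degenerate,
         inputs = list(m1 = m1, sd1 = sd1, n1 = n1,
                       m2 = m2, sd2 = sd2, n2 = n2, welch = welch)),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  lab <- if (is.na(x$df)) "z" else sprintf("t(df = %.3g)", x$df)
  cat(sprintf("%s = %.4g, one-tailed p = %.4g\n", lab, x$statistic,
              x$p_one_tailed))
  invisible(x)
}

#' Least-squares linear regression with slope F-test
#'
#' @param x,y numeric vectors (>= 3 points; \code{x} non-constant).
#' @return object of class \code{regression_result}: \code{slope},
#'   \code{intercept}, \code{r}, \code{r_squared}, \code{F_p} (p-value of
#'   the F-test of the slope).
#' @export
linreg <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need >= 3 points")
  if (stats::var(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  f <- sm$fstatistic
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = unname(sign(stats::coef(fit)[2])) * sqrt(sm$r.squared),
         r_squared = sm$r.squared,
         F_p = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("y = %.4g x + %.4g; r = %.3f, r^2 = %.3f, F-test p = %.3g\n",
              x$slope, x$intercept, x$r, x$r_squared, x$F_p))
  invisible(x)
}

#' Recompute every registry group comparison from the printed tables
#'
#' Loads the bundled fixture of cohort counts and summary statistics (the
#' registry's printed contingency tables) and recomputes each comparison's
#' one-tailed p-value with [two_prop_z()] or [t_test_from_summary()].
#'
#' @param fixture path to a comparisons JSON file; default the bundled one.
#' @param tsv optional path to also write the report as TSV.
#' @return data frame with one row per comparison: \code{name},
#'   \code{test}, the input counts/moments echoed, \code{statistic},
#'   \code{p} (computed), \code{printed_p}, and \code{core} (whether the
#'   comparison is one of the seven that reproduce the printed value at 3
#'   decimal places).
#' @export
registry_report <- function(fixture = NULL, tsv = NULL) {
  if (is.null(fixture)) {
    fixture <- system.file("extdata", "registry_comparisons.json",
                           package = "egflow")
  }
  comp <- jsonlite::read_json(fixture, simplifyVector = FALSE)
  rows <- lapply(comp, function(cc) {
    if (cc$test == "two_prop_z") {
      res <- two_prop_z(cc$k1, cc$n1, cc$k2, cc$n2)
      data.frame(
        name = cc$name, test = cc$test,
        inputs = sprintf("%d/%d vs %d/%d", cc$k1, cc$n1, cc$k2, cc$n2),
        statistic = res$statistic, p = res$p_one_tailed,
        printed_p = cc$printed_p, core = isTRUE(cc$core),
        note = if (is.null(cc$note)) "" else cc$note
      )
    } else {
      res <- t_test_from_summary(cc$m1, cc$sd1, cc$n1, cc$m2, cc$sd2, cc$n2)
      data.frame(
        name = cc$name, test = cc$test,
        inputs = sprintf("%.2g+/-%.2g (n=%d) vs %.2g+/-%.2g (n=%d)",
                         cc$m1, cc$sd1, cc$n1, cc$m2, cc$sd2, cc$n2),
        statistic = res$statistic, p = res$p_one_tailed,
        printed_p = cc$printed_p, core = isTRUE(cc$core),
        note = if (is.null(cc$note)) "" else cc$note
      )
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(tsv)) {
    utils::write.table(out, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
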