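#' Repeated standard deviation (RSD)
#'
#' Pooled within-patient standard deviation of repeated anteversion
#' measurements,
#' \deqn{RSD = \sqrt{ \frac{\sum_{j=1}^{c} \sum_{i=1}^{n_j} (X_{ij} -
#'   \bar X_j)^2}{\sum_{j=1}^{c} (n_j - 1)} },}
#' where \eqn{X_{ij}} is the i-th measurement of patient j, \eqn{\bar
#' X_j} the patient mean and \eqn{n_j} the number of measurements of
#' patient j. Lower RSD means higher precision. Patients with a single
#' measurement contribute nothing to numerator or denominator and are
#' skipped; their count is returned as attribute \code{n_singleton}.
#' With a single patient the RSD reduces to the ordinary sample SD.
#'
#' @param values numeric vector of measurements (degrees).
#' @param patients vector of the same length identifying the patient of
#'   each measurement.
#' @return the RSD in the units of \code{values}, with attribute
#'   \code{n_singleton}.
#' @export
repeated_sd <- function(values, patients) {
  check_num(values, "values")
  if (length(patients) != length(values))
    stop("'patients' must match 'values' in length", call. = FALSE)
  patients <- as.character(patients)
  nj <- table(patients)
  den <- sum(nj - 1L)
  if (den < 1)
    stop("RSD undefined: every patient has a single measurement", call. = FALSE)
  num <- sum(tapply(values, patients, function(x) sum((x - mean(x))^2)))
  out <- sqrt(num / den)
  attr(out, "n_singleton") <- sum(nj == 1L)
  out
}

#' Significant-change threshold (2 x RSD)
#'
#' Twice the repeated standard deviation: a change in measured
#' anteversion between serial radiographs exceeding this threshold is
#' taken as a real change in cup orientation (approximately the 95%
#' band of the measurement error), flagging possible cup migration or
#' loosening.
#'
#' @param rsd a non-negative RSD, in degrees.
#' @return \code{2 * rsd}, same units.
#' @export
change_threshold <- function(rsd) {
  check_num(rsd, "rsd", 1)
  if (rsd < 0) stop("rsd must be non-negative", call. = FALSE)
  2 * as.numeric(rsd)
}

#' Paired observer agreement
#'
#' Two-sided paired t-test on the differences between two observers'
#' (or two sessions') measurements of the same films. When the
#' differences have zero variance the test statistic is undefined; the
#' mean difference is still reported and the result flagged degenerate
#' rather than fabricating a p-value.
#'
#' @param obs1,obs2 numeric vectors of paired measurements (degrees),
#'   equal length >= 2.
#' @return object of class \code{observer_agreement}: \code{mean_diff}
#'   (obs1 - obs2), \code{t}, \code{df}, \code{p_value},
#'   \code{degenerate}.
#' @export
observer_agreement <- function(obs1, obs2) {
  check_num(obs1, "obs1"); check_num(obs2, "obs2")
  if (length(obs1) != length(obs2))
    stop("paired observations must have equal length", call. = FALSE)
  if (length(obs1) < 2)
    stop("at least 2 pairs are required", call. = FALSE)
  d <- obs1 - obs2
  if (stats::sd(d) == 0) {
    out <- list(mean_diff = mean(d), t = NA_real_, df = length(d) - 1L,
                p_value = NA_real_, degenerate = TRUE)
  } else {
    tt <- stats::t.test(obs1, obs2, paired = TRUE)
    out <- list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value,
                degenerate = FALSE)
  }
  structure(out, class = "observer_agreement")
}

#' @export
print.observer_agreement <- function(x, ...) {
  cat("<observer_agreement> paired t-test\n")
  cat(sprintf("  mean difference (obs1 - obs2): %.4f deg\n", x$mean_diff))
  if (x$degenerate) {
    cat("  differences have zero variance; t statistic undefined\n")
  } else {
    cat(sprintf("  t = %.4f, df = %d, p = %.3f\n", x$t, x$df, x$p_value))
  }
  invisible(x)
}
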