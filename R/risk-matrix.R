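#' Score the likelihood of NO2 exposure from shift occupancy
#'
#' Bands the fraction of the work shift that staff spend at a location into
#' an ordinal likelihood score. Under the default profile: below 25% of the
#' shift scores 1 ("Unlikely"), 25--75% scores 2 ("Likely"), and above 75%
#' scores 3 ("Very likely"). The middle band is closed on both ends, so an
#' occupancy fraction of exactly 0.25 or 0.75 scores 2.
#'
#' @param occupancy_fraction numeric vector of shift fractions in `[0, 1]`.
#' @param profile a risk profile; see [default_risk_profile()].
#' @return integer vector of likelihood scores.
#' @examples
#' classify_likelihood(c(0.10, 0.50, 0.80))
#' @export
classify_likelihood <- function(occupancy_fraction, profile = default_risk_profile()) {
  classify_band(occupancy_fraction, profile$likelihood, "occupancy fraction")
}

#' Score the severity of NO2 exposure from concentration
#'
#' Bands an indoor NO2 concentration (ug/m3) into an ordinal severity score
#' reflecting the health effects associated with each exposure band. Under
#' the default profile: below 500 ug/m3 scores 1 (minor effect), 500--2000
#' scores 2 (moderate effect), above 2000 scores 3 (major effect). Both
#' edges of the middle band belong to it: exactly 500 or 2000 scores 2.
#'
#' @param concentration numeric vector of NO2 concentrations (ug/m3), `>= 0`.
#' @inheritParams classify_likelihood
#' @return integer vector of severity scores.
#' @examples
#' classify_severity(c(240, 827.27, 2100))
#' @export
classify_severity <- function(concentration, profile = default_risk_profile()) {
  classify_band(concentration, profile$severity, "concentration")
}

classify_band <- function(x, bands, what) {
  if (!is.numeric(x)) abort_domain(sprintf("%s must be numeric", what))
  if (anyNA(x)) abort_domain(sprintf("%s contains missing values", what))
  lo <- min(bands$lower)
  hi <- max(bands$upper)
  if (any(x < lo | x > hi)) {
    abort_domain(sprintf(
      "%s outside the profile domain [%g, %g]: %s",
      what, lo, hi, paste(format(x[x < lo | x > hi]), collapse = ", ")
    ))
  }
  out <- rep(NA_integer_, length(x))
  for (i in seq_len(nrow(bands))) {
    above <- if (bands$lower_closed[i]) x >= bands$lower[i] else x > bands$lower[i]
    below <- if (bands$upper_closed[i]) x <= bands$upper[i] else x < bands$upper[i]
    out[above & below] <- bands$score[i]
  }
  # domain edges always belong to the outermost bands
  out[x == lo] <- bands$score[which.min(bands$lower)]
  out[x == hi & is.na(out)] <- bands$score[which.max(bands$upper)]
  out
}

#' Compute risk factors from likelihood and severity scores
#'
#' The risk factor is the product of the likelihood and severity scores,
#' looked up in the risk matrix and categorized per the profile's legend.
#' Under the default 3 x 3 profile the reachable risk factors are
#' {1, 2, 3, 4, 6, 9}: 1--2 low (green), 3--4 moderate (yellow), 6 high
#' (bright_red), 9 very high (deep_red).
#'
#' @param likelihood integer vector of likelihood scores from the profile.
#' @param severity integer vector of severity scores from the profile
#'   (recycled against `likelihood` if either has length one).
#' @inheritParams classify_likelihood
#' @return a tibble with columns `likelihood`, `severity`, `risk_factor`,
#'   `category`, `color`.
#' @examples
#' compute_risk_factor(2, 3) # RF 6, high risk, bright red
#' compute_risk_factor(c(1, 3), c(1, 3))
#' @export
compute_risk_factor <- function(likelihood, severity, profile = default_risk_profile()) {
  n <- max(length(likelihood), length(severity))
  likelihood <- rep_len(as.integer(likelihood), n)
  severity <- rep_len(as.integer(severity), n)
  if (anyNA(likelihood) || !all(likelihood %in% profile$likelihood$score)) {
    abort_domain(sprintf(
      "likelihood score must be one of {%s}",
      paste(profile$likelihood$score, collapse = ",")
    ))
  }
  if (anyNA(severity) || !all(severity %in% profile$severity$score)) {
    abort_domain(sprintf(
      "severity score must be one of {%s}",
      paste(profile$severity$score, collapse = ",")
    ))
  }
  rf <- likelihood * severity
  idx <- match(rf, profile$categories$risk_factor)
  tibble::tibble(
    likelihood = likelihood,
    severity = severity,
    risk_factor = rf,
    category = profile$categories$category[idx],
    color = profile$categories$color[idx]
  )
}

#' Assess the NO2 risk of a single location
#'
#' Composes the two banding operations: the concentration is banded into a
#' severity score, the shift occupancy fraction into a likelihood score, and
#' the two are multiplied in the risk matrix.
#'
#' @param concentration numeric vector of NO2 concentrations (ug/m3).
#' @param occupancy_fraction numeric vector of shift fractions in `[0, 1]`.
#' @inheritParams classify_likelihood
#' @return a tibble as from [compute_risk_factor()], with the inputs
#'   prepended as columns `concentration` and `occupancy_fraction`.
#' @examples
#' assess_location(827.27, 0.80) # RF 6: high risk
#' @export
assess_location <- function(concentration, occupancy_fraction,
                            profile = default_risk_profile()) {
  n <- max(length(concentration), length(occupancy_fraction))
  concentration <- rep_len(concentration, n)
  occupancy_fraction <- rep_len(occupancy_fraction, n)
  score <- compute_risk_factor(
    classify_likelihood(occupancy_fraction, profile),
    classify_severity(concentration, profile),
    profile
  )
  dplyr::bind_cols(
    tibble::tibble(
      concentration = concentration,
      occupancy_fraction = occupancy_fraction
    ),
    score
  )
}

#' Convert an externally reported mean concentration to a risk-factor pair
#'
#' Studies that report only a mean NO2 concentration, without occupancy
#' data, are scored by banding the mean into a severity score and pairing it
#' with both plausible likelihood assumptions: exposure either between 25%
#' and 75% of the shift (likelihood 2) or above 75% (likelihood 3). A mean
#' above 2000 ug/m3 therefore yields the risk-factor pair (6, 9); a mean
#' below 500 yields (2, 3).
#'
#' @param mean_concentration numeric vector of mean NO2 concentrations
#'   (ug/m3), `>= 0`.
#' @inheritParams classify_likelihood
#' @return a tibble with one row per input: `mean_concentration`,
#'   `severity`, `rf_likely`, `category_likely`, `rf_very_likely`,
#'   `category_very_likely`.
#' @examples
#' external_study_rf(c(300, 2100))
#' @export
external_study_rf <- function(mean_concentration, profile = default_risk_profile()) {
  s <- classify_severity(mean_concentration, profile)
  likely <- compute_risk_factor(2L, s, profile)
  very_likely <- compute_risk_factor(3L, s, profile)
  tibble::tibble(
    mean_concentration = rep_len(mean_concentration, length(s)),
    severity = s,
    rf_likely = likely$risk_factor,
    category_likely = likely$category,
    rf_very_likely = very_likely$risk_factor,
    category_very_likely = very_likely$category
  )
}
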