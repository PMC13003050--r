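#' Traffic congestion categories
#'
#' Road classes by vehicle speed, as used to stratify the hospitals:
#' heavy traffic (HT, 0--20 km/h), moderate (MT, 20--40 km/h), low
#' (LT, above 40 km/h), and on-sea road (OS, a sea-front road that also
#' carries low congestion). The ordinal rank is the congestion coding used
#' in rank correlations: HT = 3 > MT = 2 > LT = OS = 1.
#'
#' @return a tibble with columns `code`, `speed_class`, `ordinal_rank`.
#' @examples
#' traffic_categories()
#' @export
traffic_categories <- function() {
  tibble::tibble(
    code = c("HT", "MT", "LT", "OS"),
    speed_class = c(
      "0-20 km/h", "20-40 km/h", "above 40 km/h",
      "on-sea road, above 40 km/h"
    ),
    ordinal_rank = c(3L, 2L, 1L, 1L)
  )
}

# NIOSH 6014 personal-pump sampling envelope (L/min)
FLOW_MIN <- 0.2
FLOW_MAX <- 1.0

#' Compute an NO2 concentration from a raw sampling record
#'
#' Converts the mass of NO2 collected in a bubbler to a concentration by
#' normalizing to the volume of air drawn through it:
#' `concentration = collected_mass / (flow_rate * duration / 1000)` ug/m3,
#' with the flow in L/min and the duration in minutes (1000 L = 1 m3).
#' No desorption or collection-efficiency factor is applied.
#'
#' @param collected_mass numeric, NO2 mass collected (ug), `>= 0`.
#' @param flow_rate numeric, pump flow rate (L/min); must lie in the
#'   sampling envelope 0.2--1.0 L/min.
#' @param duration numeric, sampling duration (minutes), `> 0`.
#' @return numeric vector of concentrations (ug/m3).
#' @examples
#' concentration_from_sample(36, 0.5, 360) # 0.18 m3 sampled -> 200 ug/m3
#' @export
concentration_from_sample <- function(collected_mass, flow_rate, duration) {
  if (anyNA(collected_mass) || any(collected_mass < 0)) {
    abort_domain("collected_mass must be >= 0")
  }
  if (anyNA(duration) || any(duration <= 0)) {
    abort_domain("duration must be > 0 minutes")
  }
  if (anyNA(flow_rate) || any(flow_rate < FLOW_MIN | flow_rate > FLOW_MAX)) {
    abort_domain(
      sprintf(
        "flow_rate outside the NIOSH 6014 sampling envelope [%.1f, %.1f] L/min",
        FLOW_MIN, FLOW_MAX
      ),
      class = "no2risk_qc_error"
    )
  }
  collected_mass / (flow_rate * duration / 1000)
}

#' Convert minutes present to an occupancy fraction
#'
#' The likelihood denominator is the 6-hour morning shift (08:00--14:00)
#' during which sampling takes place.
#'
#' @param minutes_present numeric, minutes spent at the location.
#' @param shift_minutes numeric, shift length in minutes (default 360).
#' @return numeric fraction of the shift in `[0, 1]`.
#' @export
occupancy_from_minutes <- function(minutes_present, shift_minutes = 360) {
  if (any(shift_minutes <= 0)) abort_domain("shift_minutes must be > 0")
  if (anyNA(minutes_present) || any(minutes_present < 0) ||
      any(minutes_present > shift_minutes)) {
    abort_domain("minutes_present must lie in [0, shift_minutes]")
  }
  minutes_present / shift_minutes
}

MEASUREMENT_COLS <- c(
  "hospital_id", "traffic", "season", "location_label",
  "occupancy_fraction", "concentration", "n_staff"
)
RAW_SAMPLE_COLS <- c("collected_mass", "flow_rate", "duration")

#' Read a measurement campaign from CSV
#'
#' The schema is one row per sampled indoor location-shift, UTF-8,
#' comma-delimited, dot decimal, with columns `hospital_id`, `traffic`
#' (HT/MT/LT/OS), `season` (hot/cold), `location_label`,
#' `occupancy_fraction` (fraction of shift in `[0, 1]`), `concentration`
#' (ug/m3) and optionally `n_staff`. Raw sampling rows are supported by the
#' alternate columns `collected_mass` (ug), `flow_rate` (L/min) and
#' `duration` (min) in place of `concentration`; exactly one of the two
#' forms must be present per row, and raw rows are converted with
#' [concentration_from_sample()].
#'
#' Every row is validated; invalid rows are dropped from the returned
#' tibble and reported, with row number, field and reason, in the `"qc"`
#' attribute (see [qc_report()]) and as a warning.
#'
#' @param path path to a CSV file.
#' @return a tibble of validated measurements with columns
#'   `hospital_id`, `traffic`, `season`, `location_label`,
#'   `occupancy_fraction`, `concentration`, `n_staff`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) abort_domain(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  has_raw <- all(RAW_SAMPLE_COLS %in% names(df))
  required <- setdiff(MEASUREMENT_COLS, c("n_staff", if (has_raw) "concentration"))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_domain(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      class = "no2risk_schema_error"
    )
  }
  validate_measurements(df)
}

# Row-wise validation shared by read_measurements() and callers holding an
# in-memory table. Returns the valid rows; rejects go in attr(, "qc").
validate_measurements <- function(df) {
  df <- tibble::as_tibble(df)
  n <- nrow(df)
  qc <- list()
  reject <- function(row, field, reason) {
    qc[[length(qc) + 1]] <<- tibble::tibble(row = row, field = field, reason = reason)
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  has_conc_col <- "concentration" %in% names(df)
  has_raw_col <- all(RAW_SAMPLE_COLS %in% names(df))
  out <- tibble::tibble(
    hospital_id = as.character(df$hospital_id),
    traffic = as.character(df$traffic),
    season = as.character(df$season),
    location_label = as.character(df$location_label),
    occupancy_fraction = num(df$occupancy_fraction),
    concentration = if (has_conc_col) num(df$concentration) else rep(NA_real_, n),
    n_staff = if ("n_staff" %in% names(df)) {
      suppressWarnings(as.integer(df$n_staff))
    } else {
      rep(NA_integer_, n)
    }
  )
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    raw_given <- has_raw_col && !all(is.na(num(unlist(df[i, RAW_SAMPLE_COLS]))))
    conc_given <- has_conc_col && !is.na(df$concentration[i]) && df$concentration[i] != ""
    if (raw_given && conc_given) {
      reject(i, "concentration", "both concentration and raw sampling fields given")
      ok[i] <- FALSE
      next
    }
    if (!raw_given && !conc_given) {
      reject(i, "concentration", "neither concentration nor raw sampling fields given")
      ok[i] <- FALSE
      next
    }
    if (raw_given) {
      mass <- num(df$collected_mass[i]); flow <- num(df$flow_rate[i]); dur <- num(df$duration[i])
      conv <- tryCatch(concentration_from_sample(mass, flow, dur), error = function(e) e)
      if (inherits(conv, "error")) {
        reject(i, "flow_rate", conditionMessage(conv))
        ok[i] <- FALSE
        next
      }
      out$concentration[i] <- conv
    } else if (is.na(out$concentration[i])) {
      reject(i, "concentration", "unparseable numeric")
      ok[i] <- FALSE
      next
    }
    if (is.na(out$occupancy_fraction[i])) {
      reject(i, "occupancy_fraction", "unparseable numeric")
      ok[i] <- FALSE
    } else if (out$occupancy_fraction[i] < 0 || out$occupancy_fraction[i] > 1) {
      reject(i, "occupancy_fraction", "outside [0, 1]")
      ok[i] <- FALSE
    }
    if (!is.na(out$concentration[i]) && out$concentration[i] < 0) {
      reject(i, "concentration", "negative concentration")
      ok[i] <- FALSE
    }
    if (!out$season[i] %in% c("hot", "cold")) {
      reject(i, "season", "season must be 'hot' or 'cold'")
      ok[i] <- FALSE
    }
    if (!out$traffic[i] %in% traffic_categories()$code) {
      reject(i, "traffic", "traffic must be one of HT, MT, LT, OS")
      ok[i] <- FALSE
    }
    if (("n_staff" %in% names(df)) && !is.na(df$n_staff[i]) && df$n_staff[i] != "" &&
        (is.na(out$n_staff[i]) || out$n_staff[i] < 0)) {
      reject(i, "n_staff", "n_staff must be a non-negative integer")
      ok[i] <- FALSE
    }
  }
  qc_tbl <- if (length(qc) > 0) dplyr::bind_rows(qc) else
    tibble::tibble(row = integer(), field = character(), reason = character())
  res <- out[ok, ]
  attr(res, "qc") <- qc_tbl
  if (nrow(qc_tbl) > 0) {
    rlang::warn(sprintf(
      "%d row(s) rejected during validation; see qc_report()", length(unique(qc_tbl$row))
    ))
  }
  res
}

#' Retrieve or write the QC report of a validated measurement table
#'
#' @param measurements a tibble returned by [read_measurements()].
#' @param path for `write_qc_report()`, output path; the report is written
#'   as JSON lines, one object `{row, field, reason}` per rejected field.
#' @return `qc_report()` returns a tibble with columns `row`, `field`,
#'   `reason` (zero rows if everything validated).
#' @export
qc_report <- function(measurements) {
  attr(measurements, "qc") %||%
    tibble::tibble(row = integer(), field = character(), reason = character())
}

#' @rdname qc_report
#' @export
write_qc_report <- function(measurements, path) {
  qc <- qc_report(measurements)
  lines <- vapply(seq_len(nrow(qc)), function(i) {
    jsonlite::toJSON(as.list(qc[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a measurement campaign to CSV
#'
#' Writes the standard measurement schema; an absent `n_staff` is emitted
#' as an empty field and round-trips to absent. `read_measurements()` of
#' the written file reproduces the input exactly.
#'
#' @param measurements a valid measurement tibble.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  out <- measurements[, MEASUREMENT_COLS]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
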