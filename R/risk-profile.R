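#' Risk-matrix profiles
#'
#' A risk profile defines the likelihood bands (occupancy fraction of the
#' work shift), the severity bands (NO2 concentration in ug/m3), and the
#' mapping from risk factor (likelihood x severity) to a named category and
#' report color. Band definitions are data, not code: the engine accepts any
#' N x M profile whose bands partition their domains, though only the
#' default 3 x 3 profile ships with the package.
#'
#' The default profile bands occupancy as `< 25%` (score 1, "Unlikely"),
#' `25--75%` (score 2, "Likely"), `> 75%` (score 3, "Very likely"), and
#' concentration as `< 500` (score 1, minor effect), `500--2000` (score 2,
#' moderate effect), `> 2000` ug/m3 (score 3, major effect). Risk factors
#' map to categories: 1--2 low (green), 3--4 moderate (yellow), 6 high
#' (bright_red), 9 very high (deep_red).
#'
#' @param path path to a YAML profile file.
#' @return an object of class `no2_risk_profile`: a list with tibbles
#'   `likelihood` and `severity` (columns `score`, `lower`, `upper`,
#'   `lower_closed`, `upper_closed`, `description`), a tibble `categories`
#'   (`risk_factor`, `category`, `color`), and a character vector `aliases`
#'   mapping accepted alternative category labels to canonical ones.
#' @examples
#' prof <- default_risk_profile()
#' prof$severity
#' @export
read_risk_profile <- function(path) {
  raw <- yaml::read_yaml(path)
  band_tbl <- function(x, axis) {
    tb <- purrr::map_dfr(x, function(b) {
      tibble::tibble(
        score = as.integer(b$score),
        lower = as.numeric(b$lower),
        upper = as.numeric(b$upper),
        lower_closed = isTRUE(b$lower_closed),
        upper_closed = isTRUE(b$upper_closed),
        description = as.character(b$description %||% "")
      )
    })
    validate_bands(tb, axis)
    tb
  }
  likelihood <- band_tbl(raw$likelihood, "likelihood")
  severity <- band_tbl(raw$severity, "severity")
  categories <- purrr::map_dfr(raw$categories, function(cc) {
    tibble::tibble(
      risk_factor = as.integer(unlist(cc$rf)),
      category = as.character(cc$category),
      color = as.character(cc$color)
    )
  })
  aliases <- unlist(raw$aliases %||% list())
  profile <- structure(
    list(
      name = raw$name %||% "unnamed",
      likelihood = likelihood,
      severity = severity,
      categories = categories,
      aliases = aliases
    ),
    class = "no2_risk_profile"
  )
  validate_categories(profile)
  profile
}

#' @rdname read_risk_profile
#' @export
default_risk_profile <- function() {
  read_risk_profile(
    system.file("extdata", "no2_matrix.yaml", package = "no2risk", mustWork = TRUE)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Bands must tile the domain: sorted, adjacent bands share an edge with
# exactly one side closed, scores strictly increasing with the band.
validate_bands <- function(tb, axis) {
  if (nrow(tb) < 1) abort_domain(sprintf("profile has no %s bands", axis))
  tb <- tb[order(tb$lower), ]
  if (any(diff(tb$score) <= 0)) {
    abort_domain(sprintf("%s scores must strictly increase with the band", axis))
  }
  if (any(tb$upper < tb$lower)) {
    abort_domain(sprintf("%s band has upper < lower", axis))
  }
  if (nrow(tb) > 1) {
    for (i in seq_len(nrow(tb) - 1)) {
      if (tb$upper[i] != tb$lower[i + 1]) {
        abort_domain(sprintf("%s bands leave a gap or overlap at %g", axis, tb$upper[i]))
      }
      if (tb$upper_closed[i] == tb$lower_closed[i + 1]) {
        abort_domain(sprintf(
          "%s bands must close exactly one side of the shared edge %g",
          axis, tb$upper[i]
        ))
      }
    }
  }
  invisible(tb)
}

validate_categories <- function(profile) {
  reachable <- sort(unique(as.integer(
    outer(profile$likelihood$score, profile$severity$score)
  )))
  missing <- setdiff(reachable, profile$categories$risk_factor)
  if (length(missing) > 0) {
    abort_domain(paste0(
      "profile categories do not cover reachable risk factors: ",
      paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(profile$categories$risk_factor)) {
    abort_domain("a risk factor maps to more than one category")
  }
  invisible(profile)
}

#' @export
print.no2_risk_profile <- function(x, ...) {
  cat(sprintf(
    "<no2_risk_profile '%s'> %d likelihood x %d severity bands\n",
    x$name, nrow(x$likelihood), nrow(x$severity)
  ))
  cat("Likelihood bands (occupancy fraction of shift):\n")
  print(x$likelihood, ...)
  cat("Severity bands (NO2 ug/m3):\n")
  print(x$severity, ...)
  cat("Categories:\n")
  print(x$categories, ...)
  invisible(x)
}

#' Canonicalize a risk category label
#'
#' Maps accepted aliases (e.g. "medium") onto the profile's canonical
#' category labels (e.g. "moderate").
#'
#' @param label character vector of category labels.
#' @param profile a risk profile; see [default_risk_profile()].
#' @return character vector of canonical labels.
#' @export
canonical_category <- function(label, profile = default_risk_profile()) {
  out <- as.character(label)
  hit <- out %in% names(profile$aliases)
  out[hit] <- unname(profile$aliases[out[hit]])
  unknown <- setdiff(out, profile$categories$category)
  if (length(unknown) > 0) {
    abort_domain(paste0("unknown risk category: ", paste(unknown, collapse = ", ")))
  }
  out
}
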