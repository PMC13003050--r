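#' The default measurement-campaign design
#'
#' The study design covers four public hospitals, one per traffic-congestion
#' category of its main street — heavy (HTH), moderate (MTH), low (LTH) and
#' on-sea road (OSH) — each sampled in hot and cold months. Each
#' (hospital, season) cell carries the published per-cell sample size and
#' summary statistics (mean, SD, min, max of indoor NO2 in ug/m3) that the
#' synthetic generator is calibrated to; the eight cells total 76
#' measurements: 22 HTH, 18 MTH, 14 OSH, 22 LTH.
#'
#' @return `default_scenario()`: a tibble with one row per
#'   (hospital, season) cell and columns `hospital_id`, `traffic`, `season`,
#'   `n`, `mean`, `sd`, `min`, `max`.
#' @examples
#' default_scenario()
#' sum(default_scenario()$n) # 76
#' @export
default_scenario <- function() {
  tibble::tibble(
    hospital_id = rep(c("HTH", "MTH", "OSH", "LTH"), each = 2),
    traffic = rep(c("HT", "MT", "OS", "LT"), each = 2),
    season = rep(c("hot", "cold"), times = 4),
    n = c(11L, 11L, 9L, 9L, 7L, 7L, 11L, 11L),
    mean = c(827.27, 528.18, 471.11, 363.33, 367.14, 242.86, 292.73, 240.00),
    sd = c(39.27, 32.50, 6.01, 5.00, 49.90, 38.61, 22.40, 18.44),
    min = c(770, 490, 460, 360, 270, 170, 270, 220),
    max = c(930, 600, 480, 370, 410, 270, 330, 270)
  )
}

# Canonical indoor working areas sampled in the hospitals, and the default
# occupancy rule: continuous-care clinical areas occupy staff for most of
# the shift (> 75%), administrative/pharmacy/laboratory areas about half.
CANONICAL_LABELS <- c(
  "clinic", "administrative office", "pharmacy", "patient room",
  "emergency room", "intensive care unit", "operation room", "laboratory"
)

#' @rdname default_scenario
#' @return `default_occupancy_rule()`: a named numeric vector mapping each
#'   canonical location label to the occupancy fraction assigned to it.
#' @export
default_occupancy_rule <- function() {
  c(
    "clinic" = 0.9, "patient room" = 0.9, "emergency room" = 0.9,
    "intensive care unit" = 0.9, "operation room" = 0.9,
    "administrative office" = 0.5, "pharmacy" = 0.5, "laboratory" = 0.5
  )
}

#' @rdname default_scenario
#' @param seed integer seed controlling all randomness of campaigns
#'   generated from the design.
#' @return `default_study_design()`: an object of class
#'   `no2_campaign_config` bundling the scenario table, the seed, and the
#'   occupancy rule.
#' @export
default_study_design <- function(seed = 1L) {
  campaign_config(default_scenario(), seed = seed)
}

#' Build a campaign configuration
#'
#' @param scenario a scenario tibble as from [default_scenario()].
#' @param seed integer seed.
#' @param occupancy_rule named numeric vector mapping location labels to
#'   occupancy fractions.
#' @return an object of class `no2_campaign_config`.
#' @export
campaign_config <- function(scenario, seed = 1L,
                            occupancy_rule = default_occupancy_rule()) {
  scenario <- tibble::as_tibble(scenario)
  stopifnot(all(c("hospital_id", "traffic", "season", "n", "mean", "sd", "min", "max")
                %in% names(scenario)))
  if (anyDuplicated(scenario[, c("hospital_id", "season")])) {
    abort_domain("scenario rows must cover each (hospital, season) at most once")
  }
  if (any(scenario$min > scenario$mean | scenario$mean > scenario$max)) {
    abort_domain("scenario rows must satisfy min <= mean <= max")
  }
  if (any(scenario$sd <= 0) || any(scenario$n < 2)) {
    abort_domain("scenario rows must have sd > 0 and n >= 2")
  }
  structure(
    list(scenario = scenario, seed = as.integer(seed), occupancy_rule = occupancy_rule),
    class = "no2_campaign_config"
  )
}

# ---- truncated normal machinery ------------------------------------------

# Mean and SD of a normal(mu, sigma) truncated to [lower, upper], from the
# closed form, with the normalizing mass computed from whichever tail
# avoids cancellation.
tnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- if (a > 0) {
    stats::pnorm(a, lower.tail = FALSE) - stats::pnorm(b, lower.tail = FALSE)
  } else {
    stats::pnorm(b) - stats::pnorm(a)
  }
  if (!is.finite(z) || z <= 0) {
    abort_domain("truncated-normal mass underflow; parameters too far outside the interval")
  }
  h <- function(x) ifelse(is.finite(x), x * stats::dnorm(x), 0)
  r1 <- (stats::dnorm(a) - stats::dnorm(b)) / z
  r2 <- (h(a) - h(b)) / z
  m <- mu + sigma * r1
  v <- sigma^2 * (1 + r2 - r1^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

# cache: calibration is deterministic, so repeated campaign generation
# reuses solved parameters
.calib_cache <- new.env(parent = emptyenv())

#' Calibrate a truncated normal to target moments
#'
#' Finds parent-normal parameters `(mu, sigma)` such that the normal
#' truncated to `[lower, upper]` has the requested mean and SD. Without the
#' calibration, drawing from a normal with the target moments and rejecting
#' outside the interval biases the realized mean toward the interval's
#' centre (about 5 ug/m3 for the heaviest-traffic hot-month cell) and
#' shrinks the SD.
#'
#' On a bounded interval the attainable SD has a supremum — the
#' large-`sigma` limit of the family is an exponentially tilted uniform on
#' `[lower, upper]`, so no truncated normal exceeds
#' `(upper - lower) / sqrt(12)`. A target SD beyond what is attainable at
#' the target mean raises a calibration error by default;
#' `on_infeasible = "nearest"` instead matches the mean exactly and takes
#' the SD as close to the target as the family allows, reporting the
#' attained value.
#'
#' @param target_mean,target_sd the moments the truncated distribution must
#'   have (`target_sd > 0`; `lower <= target_mean <= upper`).
#' @param lower,upper truncation interval; either may be infinite.
#' @param on_infeasible `"error"` (default) or `"nearest"`.
#' @param tol relative tolerance on the matched moments (default 1e-9).
#' @return a list with `mu`, `sigma`, `attained_mean`, `attained_sd`,
#'   `feasible` (logical).
#' @examples
#' calibrate_truncated_normal(827.27, 39.27, 770, 930)
#' @export
calibrate_truncated_normal <- function(target_mean, target_sd, lower, upper,
                                       on_infeasible = c("error", "nearest"),
                                       tol = 1e-9) {
  on_infeasible <- match.arg(on_infeasible)
  if (!(lower < upper)) abort_domain("lower must be < upper")
  if (target_sd <= 0) abort_domain("target_sd must be > 0")
  if (target_mean < lower || target_mean > upper) {
    abort_domain("target_mean must lie within [lower, upper]")
  }
  key <- paste(target_mean, target_sd, lower, upper, on_infeasible, sep = "|")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])

  if (!is.finite(lower) && !is.finite(upper)) {
    res <- list(mu = target_mean, sigma = target_sd,
                attained_mean = target_mean, attained_sd = target_sd,
                feasible = TRUE)
    .calib_cache[[key]] <- res
    return(res)
  }
  both_finite <- is.finite(lower) && is.finite(upper)
  if (both_finite && (target_mean == lower || target_mean == upper)) {
    abort_domain("target_mean on the interval boundary is not attainable",
                 class = "no2risk_calibration_error")
  }

  # inner solve: mu matching the target mean at a given sigma
  # (the truncated mean is strictly increasing in mu)
  solve_mu <- function(sigma) {
    f <- function(mu) tnorm_moments(mu, sigma, lower, upper)$mean - target_mean
    span <- if (both_finite) (upper - lower) else 10 * target_sd
    lo0 <- (if (is.finite(lower)) lower else target_mean) - span - 3 * sigma
    hi0 <- (if (is.finite(upper)) upper else target_mean) + span + 3 * sigma
    stats::uniroot(f, c(lo0, hi0), extendInt = "upX",
                   tol = tol * max(abs(target_mean), 1))$root
  }
  sd_at <- function(sigma) {
    mu <- solve_mu(sigma)
    c(mu = mu, sd = tnorm_moments(mu, sigma, lower, upper)$sd)
  }

  # Outer solve over sigma (the attained SD increases with sigma toward a
  # supremum: the exponentially tilted uniform on a bounded interval, or a
  # tilted-exponential limit for one-sided truncation). Expand sigma
  # gradually from the target: heavily tilted parents push the interval so
  # deep into a tail that the normal CDF underflows, so a failed or stalled
  # evaluation marks the family's practical boundary.
  sd_at_safe <- function(sigma) {
    tryCatch(sd_at(sigma), error = function(e) c(mu = NA_real_, sd = NA_real_))
  }
  cap <- if (both_finite) 5 * (upper - lower) else Inf
  sig <- max(target_sd, 1e-12)
  last_good <- NULL
  bracket_hi <- NA_real_
  for (i in 1:60) {
    cur <- sd_at_safe(min(sig, cap))
    if (is.na(cur[["sd"]])) break
    last_good <- c(sigma = min(sig, cap), cur)
    if (cur[["sd"]] >= target_sd) {
      bracket_hi <- min(sig, cap)
      break
    }
    if (sig >= cap) break
    sig <- 2 * sig
  }
  if (is.null(last_good)) {
    abort_domain("truncated-normal calibration failed to evaluate",
                 class = "no2risk_calibration_error")
  }
  feasible <- !is.na(bracket_hi)
  if (!feasible && on_infeasible == "error") {
    abort_domain(
      sprintf(
        paste0("target_sd %.4g exceeds the maximum SD attainable by a truncated ",
               "normal on [%g, %g] with mean %.4g (about %.4g)"),
        target_sd, lower, upper, target_mean, last_good[["sd"]]
      ),
      class = "no2risk_calibration_error"
    )
  }
  if (!feasible) {
    sigma <- last_good[["sigma"]]
    mu <- last_good[["mu"]]
  } else {
    g <- function(s) sd_at(s)[["sd"]] - target_sd
    sigma <- stats::uniroot(g, c(0.5 * target_sd, bracket_hi),
                            tol = tol * target_sd)$root
    mu <- solve_mu(sigma)
  }
  mm <- tnorm_moments(mu, sigma, lower, upper)
  res <- list(mu = mu, sigma = sigma,
              attained_mean = mm$mean, attained_sd = mm$sd,
              feasible = feasible)
  .calib_cache[[key]] <- res
  res
}

# Inverse-CDF sampler. When the interval sits in a far tail of the parent
# (heavily tilted calibrations), CDF values collapse to 1 in double
# precision, so the quantile transform is done in whichever tail keeps the
# probabilities representable. Draws are clamped to the interval so that
# floating error at the extremes can never leak a value outside [lo, hi].
rtnorm <- function(n, mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  if (is.finite(a) && a > 0) {
    u <- stats::runif(n, stats::pnorm(b, lower.tail = FALSE),
                      stats::pnorm(a, lower.tail = FALSE))
    x <- mu + sigma * stats::qnorm(u, lower.tail = FALSE)
  } else if (is.finite(b) && b < 0) {
    u <- stats::runif(n, stats::pnorm(a), stats::pnorm(b))
    x <- mu + sigma * stats::qnorm(u)
  } else {
    u <- stats::runif(n, stats::pnorm(a), stats::pnorm(b))
    x <- mu + sigma * stats::qnorm(u)
  }
  pmin(pmax(x, lower), upper)
}

# Deterministic per-cell substream: draws for a cell depend only on
# (seed, hospital, season), never on the order of scenario rows. The seed
# is spread over the 31-bit range with a Lehmer step (exact in doubles,
# since 2^31 * 48271 < 2^53) before adding a positional hash of the key.
cell_seed <- function(seed, hospital_id, season) {
  key <- utf8ToInt(paste(hospital_id, season, sep = "/"))
  h <- sum(key * seq_along(key))
  s <- ((as.numeric(seed) %% 2147483647) * 48271) %% 2147483647
  as.integer((s + h) %% 2147483647)
}

# label sequence for n locations: cycle the canonical labels, numbering
# repeats ("clinic", ..., "clinic 2", ...)
location_labels <- function(n) {
  base <- CANONICAL_LABELS[((seq_len(n) - 1) %% length(CANONICAL_LABELS)) + 1]
  cyc <- ((seq_len(n) - 1) %/% length(CANONICAL_LABELS)) + 1
  ifelse(cyc == 1, base, paste(base, cyc))
}

base_label <- function(label) sub(" \\d+$", "", label)

#' Generate a synthetic measurement campaign
#'
#' Draws, for each scenario cell, exactly `n` concentrations from the
#' truncated normal calibrated to the cell's printed mean and SD on
#' `[min, max]` (mean matched exactly; SD as close as the family allows —
#' see [calibrate_truncated_normal()]), attaches location labels and
#' occupancy fractions per the configured occupancy rule, and returns the
#' standard measurement table. Output is reproducible bit-exactly for a
#' fixed seed, via per-cell substreams keyed by (seed, hospital, season).
#'
#' @param config an `no2_campaign_config`, e.g. [default_study_design()].
#' @return a measurement tibble (see [read_measurements()] for the schema).
#' @examples
#' camp <- generate_campaign(default_study_design(seed = 42))
#' nrow(camp) # 76
#' @export
generate_campaign <- function(config) {
  stopifnot(inherits(config, "no2_campaign_config"))
  sc <- config$scenario
  sc <- sc[order(sc$hospital_id, sc$season), ] # draw order must not matter
  purrr::map_dfr(seq_len(nrow(sc)), function(i) {
    row <- sc[i, ]
    cal <- calibrate_truncated_normal(row$mean, row$sd, row$min, row$max,
                                      on_infeasible = "nearest")
    labels <- location_labels(row$n)
    occ <- unname(config$occupancy_rule[base_label(labels)])
    if (anyNA(occ)) abort_domain("occupancy rule does not cover a generated label")
    withr::with_seed(
      cell_seed(config$seed, row$hospital_id, row$season),
      tibble::tibble(
        hospital_id = row$hospital_id,
        traffic = row$traffic,
        season = row$season,
        location_label = labels,
        occupancy_fraction = occ,
        concentration = rtnorm(row$n, cal$mu, cal$sigma, row$min, row$max),
        n_staff = NA_integer_
      )
    )
  })
}

# ---- deterministic risk-table fixtures -----------------------------------

# Per-cell reconstruction parameters: number of locations, the
# concentration band the cell's locations occupy, and how many locations
# are continuous-care clinical areas (occupancy > 75% of the shift).
# The heavy-traffic cold-month band starts at 500 (not the campaign
# scenario's printed minimum of 490) so that every location bands to
# severity 2 and the cell's reported high-risk share is reproducible.
FIXTURE_CELLS <- list(
  "HTH.hot"  = list(n = 11L, lo = 770, hi = 930, clinical = 8L),
  "HTH.cold" = list(n = 11L, lo = 500, hi = 600, clinical = 7L),
  "MTH.hot"  = list(n = 9L,  lo = 460, hi = 480, clinical = 7L),
  "MTH.cold" = list(n = 9L,  lo = 360, hi = 370, clinical = 7L),
  "OSH.hot"  = list(n = 7L,  lo = 270, hi = 410, clinical = 4L),
  "OSH.cold" = list(n = 7L,  lo = 170, hi = 270, clinical = 4L),
  "LTH.hot"  = list(n = 11L, lo = 270, hi = 330, clinical = 6L),
  "LTH.cold" = list(n = 11L, lo = 220, hi = 270, clinical = 6L)
)

CLINICAL_POOL <- c(
  "emergency room", "intensive care unit", "operation room",
  "clinic 1", "clinic 2", "patient room 1", "patient room 2", "patient room 3"
)
SUPPORT_POOL <- c(
  "administrative office 1", "administrative office 2",
  "pharmacy 1", "pharmacy 2", "laboratory"
)

#' Deterministic per-cell risk-table fixtures
#'
#' `build_risk_fixture()` returns a reconstructed location table for one
#' (hospital, season) cell: a fixed set of location labels with
#' concentrations evenly spaced across the cell's concentration band and
#' occupancy fractions of 0.9 for continuous-care clinical areas and 0.5
#' for administrative, pharmacy and laboratory areas. Per-location
#' occupancy was not published, so these tables are reconstructions
#' constrained by the published per-cell risk-category shares (high risk in
#' 72.7% / 63.6% of heavy-traffic locations in hot / cold months; moderate
#' risk in 77.8% / 57.1% / 54.5% of moderate-traffic / on-sea / low-traffic
#' locations, identical across seasons), which scoring them reproduces
#' exactly. The function is pure: identical output on every call.
#'
#' @param hospital_id one of `"HTH"`, `"MTH"`, `"OSH"`, `"LTH"`.
#' @param season `"hot"` or `"cold"`.
#' @return a measurement tibble for the requested cell.
#' @examples
#' build_risk_fixture("HTH", "hot")
#' @export
build_risk_fixture <- function(hospital_id, season) {
  key <- paste(hospital_id, season, sep = ".")
  cell <- FIXTURE_CELLS[[key]]
  if (is.null(cell)) {
    abort_domain(sprintf("unknown study cell: %s %s", hospital_id, season))
  }
  traffic <- c(HTH = "HT", MTH = "MT", OSH = "OS", LTH = "LT")[[hospital_id]]
  labels <- c(CLINICAL_POOL[seq_len(cell$clinical)],
              SUPPORT_POOL[seq_len(cell$n - cell$clinical)])
  occ <- c(rep(0.9, cell$clinical), rep(0.5, cell$n - cell$clinical))
  tibble::tibble(
    hospital_id = hospital_id,
    traffic = traffic,
    season = season,
    location_label = labels,
    occupancy_fraction = occ,
    concentration = round(seq(cell$lo, cell$hi, length.out = cell$n), 2),
    n_staff = 2L + (seq_len(cell$n) - 1L) %% 4L
  )
}

#' @rdname build_risk_fixture
#' @return `risk_fixtures()`: all eight cells bound into one 76-row tibble.
#' @export
risk_fixtures <- function() {
  cells <- expand.grid(
    hospital_id = c("HTH", "MTH", "OSH", "LTH"),
    season = c("hot", "cold"),
    stringsAsFactors = FALSE
  )
  cells <- cells[order(match(cells$hospital_id, c("HTH", "MTH", "OSH", "LTH")),
                       match(cells$season, c("hot", "cold"))), ]
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    build_risk_fixture(cells$hospital_id[i], cells$season[i])
  })
}
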