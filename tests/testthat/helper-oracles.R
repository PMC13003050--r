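# Truncated-normal moments by numeric integration: independent of the
# closed-form expressions used inside the package.
tn_moments_int <- function(mu, sigma, lower, upper) {
  f <- function(x) stats::dnorm(x, mu, sigma)
  z <- stats::integrate(f, lower, upper)$value
  m <- stats::integrate(function(x) x * f(x), lower, upper)$value / z
  v <- stats::integrate(function(x) (x - m)^2 * f(x), lower, upper)$value / z
  list(mean = m, sd = sqrt(v))
}

# small valid measurement table used by I/O tests
tiny_campaign <- function() {
  tibble::tibble(
    hospital_id = c("HTH", "LTH"),
    traffic = c("HT", "LT"),
    season = c("hot", "cold"),
    location_label = c("clinic", "laboratory"),
    occupancy_fraction = c(0.8, 0.5),
    concentration = c(827.27, 240),
    n_staff = c(3L, NA_integer_)
  )
}
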