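test_that("likelihood banding follows the occupancy bands, middle band closed", {
  cases <- list(
    list(0.80, 3L), list(0.50, 2L), list(0.75, 2L), list(0.10, 1L),
    list(0.25, 2L), list(0.249999, 1L), list(0.750001, 3L),
    list(0, 1L), list(1, 3L)
  )
  for (cs in cases) {
    expect_identical(classify_likelihood(cs[[1]]), cs[[2]],
                     label = sprintf("occupancy %g", cs[[1]]))
  }
  expect_error(classify_likelihood(1.3), class = "no2risk_domain_error")
  expect_error(classify_likelihood(-0.1), class = "no2risk_domain_error")
})

test_that("severity banding follows the concentration bands, middle band closed", {
  cases <- list(
    list(827.27, 2L), list(240.0, 1L), list(2100.0, 3L), list(500.0, 2L),
    list(2000.0, 2L), list(499.999, 1L), list(2000.001, 3L), list(0, 1L)
  )
  for (cs in cases) {
    expect_identical(classify_severity(cs[[1]]), cs[[2]],
                     label = sprintf("concentration %g", cs[[1]]))
  }
  expect_error(classify_severity(-1), class = "no2risk_domain_error")
})

test_that("risk factors multiply scores and categorize per the color legend", {
  got <- compute_risk_factor(c(2, 1, 3, 3), c(3, 1, 3, 1))
  expect_equal(got$risk_factor, c(6L, 1L, 9L, 3L))
  expect_equal(got$category, c("high", "low", "very_high", "moderate"))
  expect_equal(got$color, c("bright_red", "green", "deep_red", "yellow"))
  expect_error(compute_risk_factor(0, 2), class = "no2risk_domain_error")
  expect_error(compute_risk_factor(2, 4), class = "no2risk_domain_error")
})

test_that("reachable risk factors are exactly {1,2,3,4,6,9}", {
  # independent enumeration oracle: all 9 products of the two score sets
  oracle <- as.integer(sort(unique(as.vector(outer(1:3, 1:3)))))
  expect_identical(oracle, c(1L, 2L, 3L, 4L, 6L, 9L))
  grid <- expand.grid(l = 1:3, s = 1:3)
  got <- compute_risk_factor(grid$l, grid$s)
  expect_setequal(unique(got$risk_factor), oracle)
  expect_false(any(got$risk_factor %in% c(5L, 7L, 8L)))
})

test_that("assessment composes the classifiers and is monotone in both inputs", {
  one <- assess_location(827.27, 0.80)
  expect_equal(one$risk_factor, 6L)
  expect_equal(one$category, "high")
  expect_equal(assess_location(471.11, 0.50)$risk_factor, 2L)
  expect_equal(assess_location(2100.0, 0.90)$risk_factor, 9L)
  # equals the explicit composition
  conc <- c(10, 499, 500, 900, 2000, 2001, 5000)
  occ <- c(0, 0.2, 0.25, 0.5, 0.75, 0.8, 1)
  grid <- expand.grid(conc = conc, occ = occ)
  got <- assess_location(grid$conc, grid$occ)
  expect_equal(
    got$risk_factor,
    compute_risk_factor(classify_likelihood(grid$occ),
                        classify_severity(grid$conc))$risk_factor
  )
  # monotone non-decreasing in concentration at fixed occupancy, and vice versa
  for (o in occ) {
    rf <- assess_location(sort(conc), rep(o, length(conc)))$risk_factor
    expect_true(all(diff(rf) >= 0), label = sprintf("occupancy fixed at %g", o))
  }
  for (cc in conc) {
    rf <- assess_location(rep(cc, length(occ)), sort(occ))$risk_factor
    expect_true(all(diff(rf) >= 0), label = sprintf("concentration fixed at %g", cc))
  }
})

test_that("category is a function of the risk factor alone and recategorizing is idempotent", {
  grid <- expand.grid(l = 1:3, s = 1:3)
  got <- compute_risk_factor(grid$l, grid$s)
  legend <- c("1" = "low", "2" = "low", "3" = "moderate", "4" = "moderate",
              "6" = "high", "9" = "very_high")
  expect_equal(got$category, unname(legend[as.character(got$risk_factor)]))
  expect_identical(canonical_category(got$category), got$category)
  expect_identical(canonical_category("medium"), "moderate")
  expect_error(canonical_category("extreme"), class = "no2risk_domain_error")
})

test_that("external-study means convert to a likelihood-2/3 risk-factor pair", {
  got <- external_study_rf(c(2100, 300, 1000))
  expect_equal(got$rf_likely, c(6L, 2L, 4L))
  expect_equal(got$rf_very_likely, c(9L, 3L, 6L))
  expect_equal(got$category_likely, c("high", "low", "moderate"))
  # both members share the severity and the L=3 member never scores lower
  sweep <- external_study_rf(seq(0, 3000, by = 50))
  expect_true(all(sweep$rf_likely == 2L * sweep$severity))
  expect_true(all(sweep$rf_very_likely == 3L * sweep$severity))
  expect_true(all(sweep$rf_very_likely >= sweep$rf_likely))
  expect_error(external_study_rf(-5), class = "no2risk_domain_error")
})

test_that("band definitions are config: profiles validate and reproduce defaults", {
  prof <- default_risk_profile()
  expect_s3_class(prof, "no2_risk_profile")
  expect_equal(nrow(prof$likelihood), 3)
  expect_equal(nrow(prof$severity), 3)
  # a profile with a gap between bands is rejected
  broken <- file.path(tempdir(), "broken_profile.yaml")
  writeLines(c(
    "name: broken",
    "likelihood:",
    "  - {score: 1, lower: 0.0, upper: 0.2, lower_closed: true, upper_closed: false}",
    "  - {score: 2, lower: 0.25, upper: 1.0, lower_closed: true, upper_closed: true}",
    "severity:",
    "  - {score: 1, lower: 0.0, upper: .inf, lower_closed: true, upper_closed: false}",
    "categories:",
    "  - {category: low, color: green, rf: [1, 2]}"
  ), broken)
  expect_error(read_risk_profile(broken), class = "no2risk_domain_error")
  # a profile whose categories miss a reachable product is rejected
  nocov <- file.path(tempdir(), "nocov_profile.yaml")
  writeLines(c(
    "name: nocov",
    "likelihood:",
    "  - {score: 1, lower: 0.0, upper: 0.5, lower_closed: true, upper_closed: false}",
    "  - {score: 2, lower: 0.5, upper: 1.0, lower_closed: true, upper_closed: true}",
    "severity:",
    "  - {score: 1, lower: 0.0, upper: .inf, lower_closed: true, upper_closed: false}",
    "categories:",
    "  - {category: low, color: green, rf: [1]}"
  ), nocov)
  expect_error(read_risk_profile(nocov), class = "no2risk_domain_error")
})
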