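test_that("the default scenario reproduces the published study design", {
  sc <- default_scenario()
  expect_equal(nrow(sc), 8)
  expect_equal(sum(sc$n), 76)
  hth_hot <- sc[sc$hospital_id == "HTH" & sc$season == "hot", ]
  expect_equal(hth_hot$mean, 827.27)
  expect_equal(hth_hot$sd, 39.27)
  expect_equal(c(hth_hot$min, hth_hot$max), c(770, 930))
  expect_equal(sc$n[sc$hospital_id == "OSH"], c(7L, 7L))
  expect_true(all(sc$min <= sc$mean & sc$mean <= sc$max))
})

test_that("truncated-normal calibration matches target moments (integration oracle)", {
  # no truncation: identity
  cal0 <- calibrate_truncated_normal(10, 2, -Inf, Inf)
  expect_equal(c(cal0$mu, cal0$sigma), c(10, 2))
  # bounds symmetric about the mean: the parent mean is the target mean
  cal1 <- calibrate_truncated_normal(100, 10, 60, 140)
  expect_equal(cal1$mu, 100, tolerance = 1e-8)
  o1 <- tn_moments_int(cal1$mu, cal1$sigma, 60, 140)
  expect_equal(o1$mean, 100, tolerance = 1e-6)
  expect_equal(o1$sd, 10, tolerance = 1e-6)
  # heaviest-traffic hot-month cell: lower truncation cuts more mass, so
  # the parent mean must sit below the target
  cal2 <- calibrate_truncated_normal(827.27, 39.27, 770, 930)
  expect_true(cal2$feasible)
  expect_lt(cal2$mu, 827.27)
  o2 <- tn_moments_int(cal2$mu, cal2$sigma, 770, 930)
  expect_equal(o2$mean, 827.27, tolerance = 1e-6)
  expect_equal(o2$sd, 39.27, tolerance = 1e-6)
  # one-sided truncation is always feasible
  cal3 <- calibrate_truncated_normal(5, 4, 0, Inf)
  o3 <- tn_moments_int(cal3$mu, cal3$sigma, 0, Inf)
  expect_equal(o3$mean, 5, tolerance = 1e-6)
  expect_equal(o3$sd, 4, tolerance = 1e-6)
})

test_that("an unattainable SD raises a calibration error; 'nearest' keeps the mean", {
  # no distribution on [360, 370] with mean 363.33 has SD 5; the truncated
  # normal family tops out below the uniform-limit bound (370-360)/sqrt(12)
  expect_error(
    calibrate_truncated_normal(363.33, 5, 360, 370),
    class = "no2risk_calibration_error"
  )
  near <- calibrate_truncated_normal(363.33, 5, 360, 370, on_infeasible = "nearest")
  expect_false(near$feasible)
  expect_equal(near$attained_mean, 363.33, tolerance = 1e-6)
  expect_lt(near$attained_sd, 5)
  expect_gt(near$attained_sd, 0)
  # domain errors
  expect_error(calibrate_truncated_normal(50, 5, 60, 140), class = "no2risk_domain_error")
  expect_error(calibrate_truncated_normal(100, -1, 60, 140), class = "no2risk_domain_error")
})

test_that("campaigns have the designed size and respect every cell's bounds", {
  sc <- default_scenario()
  for (seed in c(1, 17, 4242)) {
    camp <- generate_campaign(default_study_design(seed = seed))
    expect_equal(nrow(camp), 76)
    counts <- table(camp$hospital_id)
    expect_equal(as.integer(counts[c("HTH", "MTH", "OSH", "LTH")]),
                 c(22L, 18L, 14L, 22L))
    for (i in seq_len(nrow(sc))) {
      v <- camp$concentration[camp$hospital_id == sc$hospital_id[i] &
                                camp$season == sc$season[i]]
      expect_length(v, sc$n[i])
      expect_true(all(v >= sc$min[i] & v <= sc$max[i]),
                  label = sprintf("%s %s draws within [min, max], seed %d",
                                  sc$hospital_id[i], sc$season[i], seed))
    }
  }
})

test_that("generation is reproducible and invariant to scenario row order", {
  a <- generate_campaign(default_study_design(seed = 99))
  b <- generate_campaign(default_study_design(seed = 99))
  expect_identical(a, b)
  shuffled <- campaign_config(default_scenario()[c(5, 2, 8, 1, 6, 3, 7, 4), ],
                              seed = 99)
  d <- generate_campaign(shuffled)
  expect_identical(a, d)
  expect_false(identical(a, generate_campaign(default_study_design(seed = 100))))
})

test_that("replicate-averaged sample moments recover the calibrated cell moments", {
  # feasible cell (HTH hot): grand mean of sample means within 3 SE of the
  # printed mean, and grand mean of sample variances within 3 SE of the
  # printed variance (sample variance is unbiased for the attained variance)
  reps <- 300
  stats <- vapply(seq_len(reps), function(s) {
    camp <- generate_campaign(default_study_design(seed = 20000 + s))
    v <- camp$concentration[camp$hospital_id == "HTH" & camp$season == "hot"]
    c(mean(v), var(v))
  }, numeric(2))
  m <- stats[1, ]; v <- stats[2, ]
  expect_lt(abs(mean(m) - 827.27), 3 * sd(m) / sqrt(reps))
  expect_lt(abs(mean(v) - 39.27^2), 3 * sd(v) / sqrt(reps))
  # infeasible-SD cell (MTH cold): the mean is still matched exactly
  m2 <- vapply(seq_len(reps), function(s) {
    camp <- generate_campaign(default_study_design(seed = 20000 + s))
    mean(camp$concentration[camp$hospital_id == "MTH" & camp$season == "cold"])
  }, numeric(1))
  expect_lt(abs(mean(m2) - 363.33), 3 * sd(m2) / sqrt(reps))
})

test_that("occupancy follows the configured rule by location label", {
  camp <- generate_campaign(default_study_design(seed = 5))
  rule <- default_occupancy_rule()
  base <- sub(" \\d+$", "", camp$location_label)
  expect_equal(camp$occupancy_fraction, unname(rule[base]))
})

test_that("risk fixtures are pure, label-complete, and score to the reported ranges", {
  f1 <- build_risk_fixture("HTH", "hot")
  f2 <- build_risk_fixture("HTH", "hot")
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 11)
  expect_error(build_risk_fixture("HTH", "spring"), class = "no2risk_domain_error")
  expect_error(build_risk_fixture("XYZ", "hot"), class = "no2risk_domain_error")

  hth_hot <- run_assessment(build_risk_fixture("HTH", "hot"))
  expect_true(all(hth_hot$risk_factor %in% c(4L, 6L)))
  expect_true(all(hth_hot$concentration >= 770 & hth_hot$concentration <= 930))
  hth_cold <- run_assessment(build_risk_fixture("HTH", "cold"))
  expect_true(all(hth_cold$risk_factor %in% c(4L, 6L)))
  mth_hot <- run_assessment(build_risk_fixture("MTH", "hot"))
  expect_true(all(mth_hot$risk_factor %in% c(2L, 3L)))
  osh_hot <- run_assessment(build_risk_fixture("OSH", "hot"))
  expect_equal(sum(osh_hot$category == "moderate"), 4)
  expect_equal(nrow(osh_hot), 7)
})

test_that("the shipped fixture CSV is exactly the fixture builder's output", {
  path <- system.file("extdata", "risk_fixtures.csv", package = "no2risk")
  shipped <- read_measurements(path)
  expect_equal(tibble::as_tibble(shipped), risk_fixtures(), ignore_attr = TRUE)
})
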