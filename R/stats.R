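#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# one-row result tibble shared by every test in the battery;
# significance is always decided as p <= alpha
stat_result <- function(test, groups, statistic, p_value, alpha,
                        estimate = NA_real_) {
  tibble::tibble(
    test = test,
    groups = groups,
    statistic = as.numeric(statistic),
    estimate = as.numeric(estimate),
    p_value = as.numeric(p_value),
    significant = p_value <= alpha,
    alpha = alpha
  )
}

#' Summarize a campaign by (hospital, season) cell
#'
#' One row per cell with the count, arithmetic mean, sample SD (n-1
#' denominator), and observed minimum and maximum of the NO2 concentration
#' — the summary-table analogue of the campaign.
#'
#' @param measurements a measurement tibble (see [read_measurements()]).
#' @return a tibble with columns `hospital_id`, `season`, `n`, `mean`,
#'   `sd`, `min`, `max`.
#' @export
summarize_by_group <- function(measurements) {
  if (nrow(measurements) == 0) abort_domain("no measurements to summarize")
  out <- measurements |>
    dplyr::group_by(.data$hospital_id, .data$season) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$concentration),
      sd = stats::sd(.data$concentration),
      min = min(.data$concentration),
      max = max(.data$concentration),
      .groups = "drop"
    )
  if (any(out$n < 2)) {
    abort_domain("a (hospital, season) group has fewer than 2 measurements; SD undefined")
  }
  out
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample's own mean and SD. A non-significant result is read as
#' "consistent with normality". Because the reference parameters are
#' estimated from the same sample, the p-value is approximate
#' (anti-conservative relative to a Lilliefors correction); this mirrors
#' the plain KS-Z usage the assessment reproduces.
#'
#' @param values numeric vector, `length >= 3`, non-degenerate.
#' @param alpha significance cut-off (default 0.05).
#' @return a one-row result tibble: `test`, `groups`, `statistic`,
#'   `estimate`, `p_value`, `significant`, `alpha`.
#' @export
ks_normality <- function(values, alpha = 0.05) {
  if (length(values) < 3) abort_domain("KS normality test needs n >= 3")
  if (stats::sd(values) == 0) abort_domain("degenerate (zero-variance) input")
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values))
  )
  stat_result("ks_normality", "", kt$statistic, kt$p.value, alpha)
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA of `values` across the levels of
#' `groups`.
#'
#' @param values numeric vector.
#' @param groups vector of group labels, same length as `values`; at least
#'   two groups with at least two values each.
#' @param alpha significance cut-off (default 0.05).
#' @return a one-row result tibble (statistic is the F ratio).
#' @export
anova_oneway <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) abort_domain("ANOVA needs at least 2 groups")
  if (any(table(groups) < 2)) abort_domain("every ANOVA group needs n >= 2")
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  stat_result(
    "anova_oneway", paste(levels(droplevels(groups)), collapse = "/"),
    ft$statistic, ft$p.value, alpha
  )
}

#' Fisher LSD post-hoc pairwise comparisons
#'
#' Uncorrected pairwise t-tests between all group pairs, using the pooled
#' error term (mean square within) and residual degrees of freedom of the
#' one-way ANOVA, as Fisher's least-significant-difference procedure
#' prescribes. No multiplicity correction is applied — that is the
#' procedure's definition.
#'
#' @inheritParams anova_oneway
#' @return a tibble with one row per unordered pair: `test`, `groups`
#'   (`"A vs B"`), `statistic` (t), `estimate` (mean difference),
#'   `p_value`, `significant`, `alpha`.
#' @export
lsd_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) abort_domain("LSD needs at least 2 groups")
  if (any(table(groups) < 2)) abort_domain("every group needs n >= 2")
  k <- nlevels(groups)
  ns <- tapply(values, groups, length)
  ms <- tapply(values, groups, mean)
  vs <- tapply(values, groups, stats::var)
  df_err <- length(values) - k
  mse <- sum((ns - 1) * vs) / df_err
  pairs <- utils::combn(levels(groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    diff <- ms[[g1]] - ms[[g2]]
    se <- sqrt(mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
    tt <- if (se == 0) 0 else diff / se
    p <- if (se == 0 && diff == 0) 1 else 2 * stats::pt(-abs(tt), df_err)
    stat_result("lsd_posthoc", paste(g1, "vs", g2), tt, p, alpha, estimate = diff)
  })
}

#' Two-sample t-test from summary statistics
#'
#' Student's pooled-variance two-sample t-test computed directly from group
#' summaries (n, mean, SD), as used to compare published seasonal means.
#' Set `var_equal = FALSE` for the Welch-Satterthwaite variant.
#'
#' @param n1,mean1,sd1 summary of the first group (`n1 >= 2`, `sd1 > 0`).
#' @param n2,mean2,sd2 summary of the second group.
#' @param var_equal pool the variances (default `TRUE`).
#' @param alpha significance cut-off (default 0.05).
#' @return a one-row result tibble (statistic is t; estimate is the mean
#'   difference).
#' @examples
#' ttest_from_summary(11, 827.27, 39.27, 11, 528.18, 32.50)
#' @export
ttest_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                               var_equal = TRUE, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) abort_domain("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) abort_domain("both SDs must be > 0")
  diff <- mean1 - mean2
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- sd1^2 / n1; b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  tt <- diff / se
  p <- 2 * stats::pt(-abs(tt), df)
  stat_result(
    if (var_equal) "t_test_pooled" else "t_test_welch",
    "", tt, p, alpha, estimate = diff
  )
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' (asymptotic, since congestion codings are heavily tied).
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @param alpha significance cut-off (default 0.05).
#' @return a one-row result tibble; `estimate` is rho, `statistic` the S
#'   statistic.
#' @export
spearman <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) abort_domain("x and y must have equal length")
  if (length(x) < 3) abort_domain("Spearman needs n >= 3")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  stat_result("spearman", "", ct$statistic, ct$p.value, alpha,
              estimate = unname(ct$estimate))
}

#' Run the full statistical battery on a campaign
#'
#' Reproduces the study's analysis plan on one measurement table:
#' per-cell KS normality of concentrations, pooled-variance t-tests of hot
#' vs cold months within each hospital, one-way ANOVA of concentration
#' across hospitals (seasons pooled), Fisher LSD pairwise comparisons
#' between hospitals, and the Spearman correlation between concentration
#' and the ordinal traffic-congestion coding.
#'
#' @param measurements a measurement tibble.
#' @param alpha significance cut-off (default 0.05).
#' @return an object of class `no2_battery`; use [tidy()] for the flat
#'   result table and [glance()] for a one-row overview.
#' @export
run_stat_battery <- function(measurements, alpha = 0.05) {
  m <- measurements
  cells <- m |>
    dplyr::group_by(.data$hospital_id, .data$season) |>
    dplyr::group_split()
  ks <- purrr::map_dfr(cells, function(cc) {
    r <- ks_normality(cc$concentration, alpha)
    r$groups <- paste(cc$hospital_id[1], cc$season[1], sep = "/")
    r
  })
  tt <- m |>
    dplyr::distinct(.data$hospital_id) |>
    dplyr::pull() |>
    purrr::map_dfr(function(h) {
      hot <- m$concentration[m$hospital_id == h & m$season == "hot"]
      cold <- m$concentration[m$hospital_id == h & m$season == "cold"]
      r <- ttest_from_summary(
        length(hot), mean(hot), stats::sd(hot),
        length(cold), mean(cold), stats::sd(cold),
        alpha = alpha
      )
      r$groups <- paste0(h, ": hot vs cold")
      r
    })
  av <- anova_oneway(m$concentration, m$hospital_id, alpha)
  lsd <- lsd_posthoc(m$concentration, m$hospital_id, alpha)
  rank <- traffic_categories()
  code <- rank$ordinal_rank[match(m$traffic, rank$code)]
  sp <- spearman(m$concentration, code, alpha)
  sp$groups <- "concentration vs congestion"
  structure(
    list(tests = dplyr::bind_rows(ks, tt, av, lsd, sp), alpha = alpha),
    class = "no2_battery"
  )
}

#' @exportS3Method generics::tidy
tidy.no2_battery <- function(x, ...) x$tests

#' @exportS3Method generics::glance
glance.no2_battery <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$tests),
    n_significant = sum(x$tests$significant),
    alpha = x$alpha
  )
}

#' @export
print.no2_battery <- function(x, ...) {
  cat(sprintf("<no2_battery> %d tests at alpha = %g\n", nrow(x$tests), x$alpha))
  print(x$tests, n = Inf, ...)
  invisible(x)
}
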