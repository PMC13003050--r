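#' Score every location of a campaign
#'
#' Applies the risk matrix to each measurement row: the concentration is
#' banded into a severity score, the occupancy fraction into a likelihood
#' score, and their product gives the location's risk factor and category.
#'
#' @param measurements a measurement tibble (see [read_measurements()]).
#' @param profile a risk profile; see [default_risk_profile()].
#' @return a tibble of class `no2_risk_table`, one row per location:
#'   `hospital_id`, `season`, `location_label`, `n_staff`,
#'   `concentration`, `occupancy_fraction`, `likelihood`, `severity`,
#'   `risk_factor`, `category`, `color`, `traffic`.
#' @examples
#' run_assessment(build_risk_fixture("HTH", "hot"))
#' @export
run_assessment <- function(measurements, profile = default_risk_profile()) {
  if (is.null(measurements) || nrow(measurements) == 0) {
    abort_domain("no measurements to assess")
  }
  score <- compute_risk_factor(
    classify_likelihood(measurements$occupancy_fraction, profile),
    classify_severity(measurements$concentration, profile),
    profile
  )
  out <- dplyr::bind_cols(
    measurements[, c("hospital_id", "traffic", "season", "location_label",
                     "n_staff", "concentration", "occupancy_fraction")],
    score
  )
  class(out) <- c("no2_risk_table", class(out))
  out
}

#' Risk-category distribution of a scored table
#'
#' The share of locations falling in each risk category, per
#' (hospital, season) cell, as percentages rounded half-away-from-zero to
#' one decimal (8 of 11 locations -> 72.7). Categories with no locations
#' are omitted.
#'
#' @param risk_table a scored table from [run_assessment()].
#' @return a tibble with columns `hospital_id`, `season`, `category`, `n`,
#'   `percent`.
#' @examples
#' risk_distribution(run_assessment(build_risk_fixture("HTH", "hot")))
#' @export
risk_distribution <- function(risk_table) {
  if (nrow(risk_table) == 0) abort_domain("empty risk table")
  risk_table |>
    tibble::as_tibble() |>
    dplyr::count(.data$hospital_id, .data$season, .data$category) |>
    dplyr::group_by(.data$hospital_id, .data$season) |>
    dplyr::mutate(percent = round_half_up(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup()
}

#' Correlations against traffic congestion
#'
#' Two Spearman rank correlations: indoor NO2 concentration against the
#' ordinal traffic-congestion coding across all measurements, and the
#' per-location risk factor against the same coding across all scored
#' rows. The default coding is HT = 3, MT = 2, LT = 1, OS = 1 (the sea
#' road carries low congestion); pass `congestion_coding` to override.
#'
#' @param measurements a measurement tibble.
#' @param risk_tables a scored table from [run_assessment()]; defaults to
#'   scoring `measurements` with the default profile.
#' @param congestion_coding named numeric vector mapping traffic codes to
#'   ordinal ranks.
#' @param alpha significance cut-off (default 0.05).
#' @return a tibble with one row per correlation (`test` is
#'   `"concentration_vs_congestion"` or `"rf_vs_congestion"`; `estimate`
#'   is rho).
#' @export
correlation_report <- function(measurements,
                               risk_tables = run_assessment(measurements),
                               congestion_coding = NULL,
                               alpha = 0.05) {
  if (is.null(congestion_coding)) {
    tc <- traffic_categories()
    congestion_coding <- stats::setNames(tc$ordinal_rank, tc$code)
  }
  code_m <- unname(congestion_coding[measurements$traffic])
  if (nrow(measurements) < 3) abort_domain("need at least 3 measurements")
  if (length(unique(code_m)) < 2) {
    abort_domain("correlation undefined: all measurements share one traffic rank")
  }
  conc <- spearman(measurements$concentration, code_m, alpha)
  conc$test <- "concentration_vs_congestion"
  conc$groups <- ""
  code_r <- unname(congestion_coding[risk_tables$traffic])
  rf <- spearman(risk_tables$risk_factor, code_r, alpha)
  rf$test <- "rf_vs_congestion"
  rf$groups <- ""
  dplyr::bind_rows(conc, rf)
}

# minimal fixed-format markdown table; avoids any formatting dependency so
# that report bytes are stable across platforms
md_table <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x)) {
      ifelse(is.na(x), "", vapply(x, function(v) format(v, trim = TRUE), character(1)))
    } else {
      ifelse(is.na(x), "", as.character(x))
    }
  }
  cols <- lapply(df, fmt)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(vapply(cols, `[[`, "", i), collapse = " | "), " |")
  }, character(1))
  c(header, sep, rows)
}

#' Render assessment reports
#'
#' Writes deterministic renderings of a full assessment: `risk_tables.csv`
#' and `summaries.csv`, `stats.json` (a JSON bundle of every component
#' that round-trips to the same structures), and `report.md`. Colors are
#' emitted as plain text tokens (`green`, `yellow`, `bright_red`,
#' `deep_red`), never terminal codes, so reports diff cleanly.
#'
#' @param risk_tables a scored table from [run_assessment()].
#' @param summaries a per-cell summary from [summarize_by_group()], or NULL.
#' @param stats a result table (e.g. `tidy(run_stat_battery(...))`), or NULL.
#' @param correlations a [correlation_report()] table, or NULL.
#' @param out_dir output directory (created if absent).
#' @param format subset of `c("md", "csv", "json")`; all three by default.
#' @return named character vector of the files written, invisibly.
#' @export
render_report <- function(risk_tables, summaries = NULL, stats = NULL,
                          correlations = NULL, out_dir = ".",
                          format = c("md", "csv", "json")) {
  bad <- setdiff(format, c("md", "csv", "json"))
  if (length(bad) > 0) {
    abort_domain(paste0("unknown report format: ", paste(bad, collapse = ", ")))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  dist <- risk_distribution(risk_tables)
  written <- character()

  if ("csv" %in% format) {
    p1 <- file.path(out_dir, "risk_tables.csv")
    readr::write_csv(tibble::as_tibble(risk_tables), p1, na = "", progress = FALSE)
    written["risk_tables"] <- p1
    if (!is.null(summaries)) {
      p2 <- file.path(out_dir, "summaries.csv")
      readr::write_csv(summaries, p2, na = "", progress = FALSE)
      written["summaries"] <- p2
    }
  }
  if ("json" %in% format) {
    p3 <- file.path(out_dir, "stats.json")
    payload <- list(
      risk_tables = tibble::as_tibble(risk_tables),
      risk_distribution = dist,
      summaries = summaries,
      stats = stats,
      correlations = correlations
    )
    payload <- payload[!vapply(payload, is.null, logical(1))]
    jsonlite::write_json(payload, p3, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written["stats_json"] <- p3
  }
  if ("md" %in% format) {
    p4 <- file.path(out_dir, "report.md")
    lines <- c("# Indoor NO2 occupational risk assessment", "")
    for (key in unique(paste(risk_tables$hospital_id, risk_tables$season))) {
      sub <- risk_tables[paste(risk_tables$hospital_id, risk_tables$season) == key, ]
      lines <- c(
        lines,
        sprintf("## %s", key), "",
        md_table(tibble::as_tibble(sub)[, c(
          "location_label", "n_staff", "concentration", "occupancy_fraction",
          "likelihood", "severity", "risk_factor", "category", "color"
        )]),
        "",
        "Category distribution (% of locations):", "",
        md_table(dist[paste(dist$hospital_id, dist$season) == key,
                      c("category", "n", "percent")]),
        ""
      )
    }
    lines <- c(lines, "## Campaign summaries", "")
    lines <- c(lines, if (is.null(summaries)) "(none)" else md_table(summaries), "")
    lines <- c(lines, "## Statistical tests", "")
    lines <- c(lines, if (is.null(stats) || nrow(stats) == 0) "(none)" else
      md_table(stats), "")
    lines <- c(lines, "## Correlations with traffic congestion", "")
    lines <- c(lines, if (is.null(correlations)) "(none)" else
      md_table(correlations), "")
    writeLines(lines, p4)
    written["report_md"] <- p4
  }
  invisible(written)
}
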