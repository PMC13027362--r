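new_calibration_report <- function(study, params, replicates, summary) {
  structure(
    list(study = study, params = params, replicates = replicates, summary = summary),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> study = %s\n", x$study))
  print(x$summary, ...)
  invisible(x)
}

# per-drug decision rule identical to screen_signals() for a family of
# size one (BH over one p-value is the raw p-value)
single_drug_flags <- function(tab, config) {
  est <- ror(tab$a, tab$b, tab$c, tab$d)
  ci <- woolf_ci(tab$a, tab$b, tab$c, tab$d, ci_level = config$ci_level)
  p <- switch(config$p_method, fisher = exact_p, chisq = chisq_p)(
    tab$a, tab$b, tab$c, tab$d
  )
  tibble(
    ror = est, ci_low = ci$ci_low, ci_high = ci$ci_high, p_raw = p,
    inverse_flag = est < 1 & p < config$alpha & tab$a >= config$min_cases &
      (!config$strict_ci | ci$ci_high < 1)
  )
}

#' False-flag rate of the screen under the global null
#'
#' Simulates `replicates` datasets of `m_pairs` independent drug-event
#' tables with every planted odds ratio equal to 1 (via
#' [simulate_tables()]), runs [screen_signals()] on each, and reports the
#' fraction of pairs flagged in the configured direction. Under
#' Benjamini-Hochberg control this fraction is expected not to exceed
#' `alpha` (up to Monte-Carlo error).
#'
#' @param m_pairs Drug-event pairs per replicate (at least 100 for a stable
#'   estimate).
#' @param n_reports Reports per pair.
#' @param replicates Number of replicates.
#' @param seed Integer seed.
#' @param config A [screen_config()].
#' @param exposure_prob,baseline_event_prob Generative probabilities; the
#'   defaults give expected drug-with-event counts well above the default
#'   minimum-case threshold so the tested family is essentially all pairs.
#' @return A `calibration_report`: per-replicate tibble plus a one-row
#'   summary (mean flagged fraction, its standard error, mean and SD of the
#'   log-ROR estimates).
#' @export
null_fdr_study <- function(m_pairs, n_reports, replicates, seed,
                           config = screen_config(),
                           exposure_prob = 0.05,
                           baseline_event_prob = 0.1) {
  m_pairs <- chk_count(m_pairs, "m_pairs", min = 100L)
  n_reports <- chk_count(n_reports, "n_reports", min = 1L)
  replicates <- chk_count(replicates, "replicates", min = 1L)
  seed <- chk_count(seed, "seed", min = 0L)
  if (!inherits(config, "screen_config")) abort_validation("`config` must be a `screen_config`.")

  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, replicates))
  reps <- purrr::map_dfr(seq_len(replicates), function(r) {
    tabs <- simulate_tables(m_pairs, n_reports, exposure_prob,
                            baseline_event_prob, planted_or = 1,
                            seed = rep_seeds[r])
    scr <- screen_signals(tabs, config)
    res <- tidy(scr)
    flagged <- switch(config$direction,
      inverse = sum(res$inverse_flag),
      positive = sum(res$positive_flag),
      both = sum(res$inverse_flag | res$positive_flag)
    )
    tibble(
      replicate = r, n_tested = nrow(res), n_flagged = flagged,
      flagged_fraction = flagged / m_pairs,
      mean_log_ror = mean(log(res$ror)), sd_log_ror = stats::sd(log(res$ror))
    )
  })
  summary <- tibble(
    scenario = "null_fdr", m_pairs = m_pairs, n_reports = n_reports,
    replicates = replicates, planted_or = 1,
    flagged_fraction = mean(reps$flagged_fraction),
    flagged_fraction_se = stats::sd(reps$flagged_fraction) / sqrt(replicates),
    coverage = NA_real_,
    mean_log_ror = mean(reps$mean_log_ror),
    sd_log_ror = mean(reps$sd_log_ror),
    alpha = config$alpha, seed = seed
  )
  new_calibration_report(
    "null_fdr",
    list(m_pairs = m_pairs, n_reports = n_reports, replicates = replicates,
         exposure_prob = exposure_prob, baseline_event_prob = baseline_event_prob,
         config = unclass(config), seed = seed),
    reps, summary
  )
}

#' Coverage of the Woolf confidence interval
#'
#' Simulates `replicates` independent tables with a common planted odds
#' ratio and reports the fraction whose Woolf interval at `ci_level` covers
#' the planted value. With all expected cells large the coverage should be
#' close to the nominal level; with near-empty expected cells the normal
#' approximation degrades, which the report records (minimum expected cell)
#' rather than hides.
#'
#' @param planted_or Planted odds ratio (> 0).
#' @param n_reports Reports per replicate.
#' @param replicates Number of replicate tables.
#' @param seed Integer seed.
#' @param exposure_prob,baseline_event_prob Generative probabilities.
#' @param ci_level Nominal confidence level.
#' @return A `calibration_report` with per-replicate estimates and a
#'   one-row summary including `coverage`.
#' @export
coverage_study <- function(planted_or, n_reports, replicates, seed,
                           exposure_prob = 0.1,
                           baseline_event_prob = 0.1,
                           ci_level = 0.95) {
  if (!is.numeric(planted_or) || length(planted_or) != 1L || planted_or <= 0) {
    abort_validation("`planted_or` must be a single positive number.")
  }
  n_reports <- chk_count(n_reports, "n_reports", min = 1L)
  replicates <- chk_count(replicates, "replicates", min = 1L)
  seed <- chk_count(seed, "seed", min = 0L)
  ci_level <- chk_prob(ci_level, "ci_level")

  tabs <- simulate_tables(replicates, n_reports, exposure_prob,
                          baseline_event_prob, planted_or, seed = seed)
  est <- ror(tabs$a, tabs$b, tabs$c, tabs$d)
  ci <- woolf_ci(tabs$a, tabs$b, tabs$c, tabs$d, ci_level = ci_level)
  covered <- ci$ci_low <= planted_or & planted_or <= ci$ci_high
  base_odds <- baseline_event_prob / (1 - baseline_event_prob)
  p1 <- base_odds * planted_or / (1 + base_odds * planted_or)
  expected_cells <- n_reports * c(
    exposure_prob * p1, exposure_prob * (1 - p1),
    (1 - exposure_prob) * baseline_event_prob,
    (1 - exposure_prob) * (1 - baseline_event_prob)
  )
  reps <- tibble(
    replicate = seq_len(replicates),
    ror = est, ci_low = ci$ci_low, ci_high = ci$ci_high, covered = covered
  )
  summary <- tibble(
    scenario = "coverage", m_pairs = replicates, n_reports = n_reports,
    replicates = replicates, planted_or = planted_or,
    flagged_fraction = NA_real_, flagged_fraction_se = NA_real_,
    coverage = mean(covered),
    mean_log_ror = mean(log(est)), sd_log_ror = stats::sd(log(est)),
    min_expected_cell = min(expected_cells),
    ci_level = ci_level, seed = seed
  )
  new_calibration_report(
    "coverage",
    list(planted_or = planted_or, n_reports = n_reports, replicates = replicates,
         exposure_prob = exposure_prob, baseline_event_prob = baseline_event_prob,
         ci_level = ci_level, seed = seed),
    reps, summary
  )
}

#' Recovery of planted odds ratios across a grid
#'
#' For each planted odds ratio in `planted_or`, simulates `replicates`
#' tables, applies the single-drug screening decision rule (identical to
#' [screen_signals()] with a family of one), and reports the mean estimate,
#' the log-scale bias, CI coverage and the inverse-flag rate. Power to flag
#' decreases toward the null as the planted value approaches 1.
#'
#' @param planted_or Numeric vector (grid) of planted odds ratios.
#' @param n_reports Reports per replicate.
#' @param replicates Replicates per grid point.
#' @param seed Integer seed.
#' @param config A [screen_config()].
#' @param exposure_prob,baseline_event_prob Generative probabilities; the
#'   defaults put the expected drug-with-event count above the default
#'   minimum-case threshold for inverse planted values.
#' @return A `calibration_report` whose `summary` has one row per grid
#'   point (columns include `mean_ror`, `bias_log_ror`, `coverage`,
#'   `flagged_fraction`).
#' @export
recovery_study <- function(planted_or, n_reports, replicates, seed,
                           config = screen_config(),
                           exposure_prob = 0.05,
                           baseline_event_prob = 0.1) {
  if (!is.numeric(planted_or) || length(planted_or) < 1L || any(planted_or <= 0)) {
    abort_validation("`planted_or` must be a non-empty positive grid.")
  }
  n_reports <- chk_count(n_reports, "n_reports", min = 1L)
  replicates <- chk_count(replicates, "replicates", min = 1L)
  seed <- chk_count(seed, "seed", min = 0L)
  if (!inherits(config, "screen_config")) abort_validation("`config` must be a `screen_config`.")

  grid_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, length(planted_or)))
  reps <- purrr::map_dfr(seq_along(planted_or), function(g) {
    or_g <- planted_or[g]
    tabs <- simulate_tables(replicates, n_reports, exposure_prob,
                            baseline_event_prob, or_g, seed = grid_seeds[g])
    dec <- single_drug_flags(tabs, config)
    dplyr::mutate(dec, planted_or = or_g, replicate = dplyr::row_number())
  })
  summary <- reps |>
    dplyr::group_by(planted_or = .data$planted_or) |>
    dplyr::summarise(
      scenario = "recovery",
      m_pairs = replicates, n_reports = n_reports, replicates = replicates,
      mean_ror = mean(.data$ror),
      mean_log_ror = mean(log(.data$ror)),
      sd_log_ror = stats::sd(log(.data$ror)),
      bias_log_ror = mean(log(.data$ror)) - log(.data$planted_or[1]),
      coverage = mean(.data$ci_low <= .data$planted_or &
                        .data$planted_or <= .data$ci_high),
      flagged_fraction = mean(.data$inverse_flag),
      seed = seed,
      .groups = "drop"
    )
  new_calibration_report(
    "recovery",
    list(planted_or = planted_or, n_reports = n_reports, replicates = replicates,
         exposure_prob = exposure_prob, baseline_event_prob = baseline_event_prob,
         config = unclass(config), seed = seed),
    reps, summary
  )
}

#' Write a calibration report to disk
#'
#' Serializes the full report (parameters, per-replicate table, summary) as
#' JSON and the summary alone as a human-readable TSV.
#'
#' @param report A `calibration_report`.
#' @param path_prefix Output path prefix; writes `<prefix>.json` and
#'   `<prefix>_summary.tsv`.
#' @return Invisibly, the two paths.
#' @export
write_calibration <- function(report, path_prefix) {
  if (!inherits(report, "calibration_report")) {
    abort_validation("`report` must be a `calibration_report`.")
  }
  json_path <- paste0(path_prefix, ".json")
  tsv_path <- paste0(path_prefix, "_summary.tsv")
  jsonlite::write_json(
    list(study = report$study, params = report$params,
         replicates = report$replicates, summary = report$summary),
    json_path, auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  readr::write_tsv(report$summary, tsv_path)
  invisible(c(json_path, tsv_path))
}
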