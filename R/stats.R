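#' Reporting odds ratio of a 2x2 report-level table
#'
#' For a drug-event pair the report-level table counts `a` reports with both
#' drug and event, `b` with the drug only, `c` with the event only, and `d`
#' with neither; the reporting odds ratio is `(a*d)/(b*c)`, the odds-ratio
#' analogue of a case/non-case study. Values below 1 indicate the pair is
#' co-reported less often than expected (a potential inverse signal).
#'
#' When `correct = TRUE` (default) and any cell is zero, 0.5 is added to all
#' four cells (Haldane-Anscombe) so the estimate and its Woolf interval stay
#' finite; [exact_p()] always uses the raw counts.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorized).
#' @param correct Apply the Haldane-Anscombe correction to zero-cell tables.
#' @return Numeric vector of reporting odds ratios.
#' @examples
#' ror(40, 160, 1000, 2000) # 0.5
#' @export
ror <- function(a, b, c, d, correct = TRUE) {
  chk_cells(a, b, c, d)
  if (any(a + b + c + d == 0)) abort_validation("ROR is undefined for an all-zero table.")
  k <- if (correct) 0.5 * (a == 0 | b == 0 | c == 0 | d == 0) else 0
  ((a + k) * (d + k)) / ((b + k) * (c + k))
}

#' Woolf confidence interval for the reporting odds ratio
#'
#' Normal-approximation interval on the log odds-ratio scale:
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the
#' two-sided normal quantile at `ci_level`. The bounds are geometrically
#' symmetric about the point estimate: `sqrt(low * high)` equals the ROR to
#' machine precision.
#'
#' @inheritParams ror
#' @param ci_level Confidence level (default 0.95).
#' @return A tibble with columns `ci_low` and `ci_high`.
#' @examples
#' woolf_ci(10, 90, 100, 900) # 0.504 to 1.984
#' @export
woolf_ci <- function(a, b, c, d, ci_level = 0.95, correct = TRUE) {
  chk_cells(a, b, c, d)
  ci_level <- chk_prob(ci_level, "ci_level")
  est <- ror(a, b, c, d, correct = correct)
  k <- if (correct) 0.5 * (a == 0 | b == 0 | c == 0 | d == 0) else 0
  se <- sqrt(1 / (a + k) + 1 / (b + k) + 1 / (c + k) + 1 / (d + k))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  tibble(ci_low = exp(log(est) - z * se), ci_high = exp(log(est) + z * se))
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' The standard two-sided exact test: with margins fixed, sums the
#' hypergeometric probabilities of every table whose point probability does
#' not exceed that of the observed table (within relative tolerance 1e-7).
#' Degenerate margins (an empty row or column, where only one table is
#' possible) give p = 1. Always computed on raw counts, never on
#' continuity-corrected cells.
#'
#' @inheritParams ror
#' @return Numeric vector of p-values in \[0, 1\].
#' @examples
#' exact_p(5, 0, 0, 5) # 2/252
#' @export
exact_p <- function(a, b, c, d) {
  chk_cells(a, b, c, d)
  n <- max(lengths(list(a, b, c, d)))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    if ((a[i] + b[i]) == 0 || (c[i] + d[i]) == 0 ||
        (a[i] + c[i]) == 0 || (b[i] + d[i]) == 0) {
      return(1)
    }
    stats::fisher.test(matrix(c(a[i], c[i], b[i], d[i]), nrow = 2))$p.value
  }, numeric(1))
}

#' Pearson chi-square p-value for a 2x2 table
#'
#' Alternative raw p-value for [screen_signals()]: Pearson's chi-square test
#' without continuity correction. Degenerate margins give p = 1.
#'
#' @inheritParams ror
#' @return Numeric vector of p-values.
#' @export
chisq_p <- function(a, b, c, d) {
  chk_cells(a, b, c, d)
  n <- max(lengths(list(a, b, c, d)))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    if ((a[i] + b[i]) == 0 || (c[i] + d[i]) == 0 ||
        (a[i] + c[i]) == 0 || (b[i] + d[i]) == 0) {
      return(1)
    }
    suppressWarnings(
      stats::chisq.test(matrix(c(a[i], c[i], b[i], d[i]), nrow = 2),
                        correct = FALSE)$p.value
    )
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: with the p-values sorted
#' ascending, the adjusted value at rank i is `min over j >= i of
#' min(1, p_(j) * m / j)`, returned in input order.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values (BH q-values), same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort_validation("`p` must contain p-values in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' Screening thresholds and options
#'
#' @param event_pts Target event preferred terms; reports listing at least
#'   one (case-insensitive, trimmed match) are cases.
#' @param min_cases Minimum `a` (drug-with-event reports) for a drug to
#'   enter the tested family; default 40, a conservative threshold against
#'   small-count instability of inverse signals.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param ci_level Confidence level for the Woolf interval (default 0.95).
#' @param direction Which signals to flag: `"inverse"` (ROR < 1, the
#'   repurposing direction), `"positive"`, or `"both"`.
#' @param strict_ci Additionally require `ci_high < 1` (or `ci_low > 1` for
#'   positive signals) for a flag.
#' @param p_method Raw p-value: two-sided Fisher exact (default) or Pearson
#'   chi-square without continuity correction.
#' @param adjust `"filter_then_adjust"` (default) applies the minimum-case
#'   filter first and BH-adjusts across the surviving family;
#'   `"adjust_then_filter"` BH-adjusts across all drugs first.
#' @return A `screen_config` object.
#' @export
screen_config <- function(event_pts = c("Ulcerative colitis", "Crohn's disease"),
                          min_cases = 40L,
                          alpha = 0.05,
                          ci_level = 0.95,
                          direction = c("inverse", "positive", "both"),
                          strict_ci = FALSE,
                          p_method = c("fisher", "chisq"),
                          adjust = c("filter_then_adjust", "adjust_then_filter")) {
  if (!is.character(event_pts) || length(event_pts) < 1L) {
    abort_validation("`event_pts` must be a non-empty character vector.")
  }
  structure(
    list(
      event_pts = event_pts,
      min_cases = chk_count(min_cases, "min_cases", min = 1L),
      alpha = chk_prob(alpha, "alpha"),
      ci_level = chk_prob(ci_level, "ci_level"),
      direction = rlang::arg_match(direction),
      strict_ci = chk_flag(strict_ci, "strict_ci"),
      p_method = rlang::arg_match(p_method),
      adjust = rlang::arg_match(adjust)
    ),
    class = "screen_config"
  )
}

#' Build per-drug report-level 2x2 contingency tables
#'
#' A report is a case if it lists at least one preferred term in
#' `event_pts` (matched case-insensitively after trimming); listing several
#' target terms still counts once. For each ingredient, `a` counts reports
#' exposed to the ingredient (any role) with the event, `b` exposed without
#' the event, `c` the event without the ingredient, and `d` neither, so
#' every table sums to the total deduplicated report count.
#'
#' @param cases A `case_set` from [normalize_drugs()].
#' @param event_pts Target preferred terms (default: the screening default
#'   in [screen_config()]).
#' @return A tibble with columns `ingredient`, `a`, `b`, `c`, `d`, one row
#'   per ingredient, with the total report count in attribute `n_reports`.
#' @export
build_contingency_tables <- function(cases,
                                     event_pts = c("Ulcerative colitis",
                                                   "Crohn's disease")) {
  if (!inherits(cases, "case_set")) abort_validation("`cases` must be a `case_set`.")
  if (!is.character(event_pts) || length(event_pts) < 1L) {
    abort_validation("`event_pts` must be a non-empty character vector.")
  }
  canon <- tolower(trimws(event_pts))
  n_total <- length(cases$report_ids)
  event_ids <- cases$events |>
    dplyr::filter(tolower(trimws(.data$pt)) %in% canon) |>
    dplyr::distinct(.data$report_id)
  n_event <- nrow(event_ids)
  tabs <- cases$exposures |>
    dplyr::group_by(.data$ingredient) |>
    dplyr::summarise(
      exposed = dplyr::n_distinct(.data$report_id),
      a = sum(.data$report_id %in% event_ids$report_id),
      .groups = "drop"
    ) |>
    dplyr::transmute(
      ingredient = .data$ingredient,
      a = as.integer(.data$a),
      b = as.integer(.data$exposed - .data$a),
      c = as.integer(n_event - .data$a),
      d = as.integer(n_total - .data$exposed - n_event + .data$a)
    ) |>
    dplyr::arrange(.data$ingredient)
  attr(tabs, "n_reports") <- n_total
  tabs
}

#' Screen drug-event contingency tables for disproportionality signals
#'
#' The core screening step: restricts to drugs meeting the minimum-case
#' threshold, computes the reporting odds ratio, Woolf confidence interval
#' and raw p-value for each, adjusts the p-values by Benjamini-Hochberg
#' across exactly that family, and flags signals. A drug is flagged as an
#' inverse signal when `ror < 1`, `p_adj < alpha` and `a >= min_cases`
#' (plus `ci_high < 1` under `strict_ci`); positive signals mirror this
#' above 1. The full tested family — flagged or not — is returned for
#' audit, sorted by ascending ROR with ties broken by ingredient name.
#'
#' @param tables A tibble with columns `ingredient`, `a`, `b`, `c`, `d`
#'   (from [build_contingency_tables()] or [simulate_tables()]).
#' @param config A [screen_config()].
#' @return A `ror_screen` object. Its `results` tibble has columns
#'   `ingredient`, `a`, `b`, `c`, `d`, `n_cases`, `ror`, `ci_low`,
#'   `ci_high`, `p_raw`, `p_adj`, `inverse_flag`, `positive_flag`,
#'   `corrected_flag`. Use [generics::tidy()] / [generics::glance()] to
#'   extract tidy summaries and [flagged_signals()] to start the candidate
#'   funnel.
#' @examples
#' tabs <- simulate_tables(50, 5e4, planted_or = c(0.2, rep(1, 49)), seed = 42)
#' scr <- screen_signals(tabs, screen_config())
#' glance(scr)
#' @export
screen_signals <- function(tables, config = screen_config()) {
  if (!inherits(config, "screen_config")) abort_validation("`config` must be a `screen_config`.")
  if (!is.data.frame(tables) ||
      !all(c("ingredient", "a", "b", "c", "d") %in% names(tables))) {
    abort_validation("`tables` needs columns ingredient, a, b, c, d.")
  }
  chk_cells(tables$a, tables$b, tables$c, tables$d)
  p_fun <- switch(config$p_method, fisher = exact_p, chisq = chisq_p)

  fam <- as_tibble(tables)[c("ingredient", "a", "b", "c", "d")]
  if (config$adjust == "filter_then_adjust") {
    fam <- dplyr::filter(fam, .data$a >= config$min_cases)
  }
  if (nrow(fam) == 0L) {
    rlang::warn("No drug meets the minimum case threshold; empty screening family.")
  }
  res <- fam |>
    dplyr::mutate(
      n_cases = .data$a,
      ror = ror(.data$a, .data$b, .data$c, .data$d),
      woolf_ci(.data$a, .data$b, .data$c, .data$d, ci_level = config$ci_level),
      p_raw = p_fun(.data$a, .data$b, .data$c, .data$d),
      corrected_flag = .data$a == 0 | .data$b == 0 | .data$c == 0 | .data$d == 0
    ) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p_raw))
  if (config$adjust == "adjust_then_filter") {
    res <- dplyr::filter(res, .data$a >= config$min_cases)
  }
  res <- res |>
    dplyr::mutate(
      inverse_flag = .data$ror < 1 & .data$p_adj < config$alpha &
        .data$a >= config$min_cases &
        (!config$strict_ci | .data$ci_high < 1),
      positive_flag = .data$ror > 1 & .data$p_adj < config$alpha &
        .data$a >= config$min_cases &
        (!config$strict_ci | .data$ci_low > 1)
    ) |>
    dplyr::relocate("p_adj", .after = "p_raw") |>
    dplyr::arrange(.data$ror, .data$ingredient)

  structure(
    list(results = res, config = config,
         n_reports = attr(tables, "n_reports", exact = TRUE)),
    class = "ror_screen"
  )
}

#' @export
print.ror_screen <- function(x, ...) {
  cat(sprintf(
    "<ror_screen> %d drugs tested (min %d cases), %d inverse / %d positive signals at BH alpha = %g\n",
    nrow(x$results), x$config$min_cases, sum(x$results$inverse_flag),
    sum(x$results$positive_flag), x$config$alpha
  ))
  print(x$results, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-drug results of a screen
#'
#' @param x A `ror_screen` object.
#' @param ... Unused.
#' @return The per-drug results tibble, ascending by ROR.
#' @method tidy ror_screen
#' @export
tidy.ror_screen <- function(x, ...) x$results

#' One-row summary of a screen
#'
#' @param x A `ror_screen` object.
#' @param ... Unused.
#' @return A one-row tibble: family size, counts of inverse and positive
#'   flags, thresholds used, and the total report count if known.
#' @method glance ror_screen
#' @export
glance.ror_screen <- function(x, ...) {
  tibble(
    n_tested = nrow(x$results),
    n_inverse = sum(x$results$inverse_flag),
    n_positive = sum(x$results$positive_flag),
    min_cases = x$config$min_cases,
    alpha = x$config$alpha,
    ci_level = x$config$ci_level,
    p_method = x$config$p_method,
    n_reports = x$n_reports %||% NA_integer_
  )
}

#' Export the full tested family as TSV
#'
#' One row per family member (flagged or not), ascending ROR; `ror`,
#' `ci_low` and `ci_high` are rounded to 3 decimals, p-values kept at full
#' precision.
#'
#' @param x A `ror_screen` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_family <- function(x, path) {
  if (!inherits(x, "ror_screen")) abort_validation("`x` must be a `ror_screen`.")
  x$results |>
    dplyr::mutate(dplyr::across(c("ror", "ci_low", "ci_high"), round_half_up)) |>
    readr::write_tsv(path)
  invisible(path)
}
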