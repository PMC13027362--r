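test_that("ror matches hand-computed values and rejects undefined input", {
  expect_equal(ror(10, 90, 100, 900), 1.0)
  expect_equal(ror(40, 160, 1000, 2000), 0.5)
  expect_equal(ror(5, 995, 50, 8950), 44750 / 49750)
  expect_error(ror(0, 0, 0, 0), class = "rorscreen_validation_error")
  expect_error(ror(-1, 2, 3, 4), class = "rorscreen_validation_error")
  # Haldane-Anscombe on zero cells keeps the estimate finite
  expect_equal(ror(5, 0, 3, 10), (5.5 * 10.5) / (0.5 * 3.5))
  expect_true(is.finite(ror(0, 10, 10, 10)))
})

test_that("ror is reciprocal under column swap and monotone in a", {
  set.seed(41)
  for (i in 1:25) {
    t <- rpois(4, 30) + 1
    expect_equal(ror(t[2], t[1], t[4], t[3]), 1 / ror(t[1], t[2], t[3], t[4]))
  }
  a <- 1:50
  expect_true(all(diff(ror(a, 100, 200, 300)) > 0))
})

test_that("woolf_ci matches the hand evaluation and its geometric-mean identity", {
  ci <- woolf_ci(10, 90, 100, 900, ci_level = 0.95)
  expect_equal(round(ci$ci_low, 4), 0.5040)
  expect_equal(round(ci$ci_high, 4), 1.9842)
  set.seed(42)
  for (i in 1:50) {
    t <- rpois(4, 50) + 1
    est <- ror(t[1], t[2], t[3], t[4])
    ci <- woolf_ci(t[1], t[2], t[3], t[4], ci_level = runif(1, 0.5, 0.99))
    expect_lt(ci$ci_low, ci$ci_high)
    expect_equal(sqrt(ci$ci_low * ci$ci_high), est)
  }
})

test_that("exact_p reproduces hypergeometric enumeration on frozen examples", {
  expect_equal(exact_p(2, 3, 3, 2), 1.0)
  expect_equal(exact_p(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  # degenerate margins: only one table is possible
  expect_equal(exact_p(0, 0, 5, 7), 1)
  expect_equal(exact_p(3, 0, 4, 0), 1)
})

test_that("chi-square alternative agrees with the asymptotic test", {
  p <- chisq_p(30, 70, 60, 140)
  expect_equal(p, suppressWarnings(
    stats::chisq.test(matrix(c(30, 60, 70, 140), 2), correct = FALSE)$p.value
  ))
  expect_equal(chisq_p(0, 0, 5, 7), 1)
})

test_that("bh_adjust matches the step-up definition and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), class = "rorscreen_validation_error")
  expect_error(bh_adjust(c(0.1, NA)), class = "rorscreen_validation_error")
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

test_that("contingency tables enumerate reports correctly", {
  d <- tempfile(); dir.create(d)
  writeLines(c("report_id$case_id$case_version",
               sprintf("R%d$C%d$1", 1:4, 1:4)), file.path(d, "demo.txt"))
  writeLines(c("report_id$drug_seq$role_code$verbatim_name",
               "R1$1$PS$drugX", "R2$1$C$drugX",
               "R3$1$PS$other", "R4$1$PS$other"), file.path(d, "drug.txt"))
  writeLines(c("report_id$pt",
               "R1$Ulcerative colitis",
               "R1$Crohn's disease",   # both target PTs still count once
               "R3$Crohn's disease"), file.path(d, "reac.txt"))
  lex_path <- file.path(d, "lex.tsv")
  writeLines(c("DRUGX\tDRUGX", "OTHER\tOTHER"), lex_path)
  cs <- read_faers_tables(d) |> deduplicate_cases() |> normalize_drugs(read_lexicon(lex_path))
  tabs <- build_contingency_tables(cs)
  x <- tabs[tabs$ingredient == "DRUGX", ]
  expect_equal(unlist(x[c("a", "b", "c", "d")], use.names = FALSE), c(1L, 1L, 1L, 1L))
  expect_true(all(tabs$a + tabs$b + tabs$c + tabs$d == 4))
  expect_error(build_contingency_tables(cs, character()),
               class = "rorscreen_validation_error")
  unlink(d, recursive = TRUE)
})

test_that("screen flags inverse signals per thresholds and sorts by ror", {
  tabs <- tibble::tibble(
    ingredient = c("STRONG_INVERSE", "NULLISH", "RARE", "POSITIVE"),
    a = c(50L, 60L, 5L, 120L),
    b = c(1950L, 540L, 45L, 380L),
    c = c(450L, 440L, 495L, 200L),
    d = c(7550L, 3960L, 4455L, 1300L)
  )
  scr <- screen_signals(tabs, screen_config(min_cases = 40))
  res <- tidy(scr)
  # below the case threshold: excluded from the family entirely
  expect_false("RARE" %in% res$ingredient)
  expect_equal(nrow(res), 3)
  expect_equal(res$ingredient, res$ingredient[order(res$ror, res$ingredient)])
  strong <- res[res$ingredient == "STRONG_INVERSE", ]
  expect_true(strong$inverse_flag)
  expect_lt(strong$ror, 1)
  expect_false(res$inverse_flag[res$ingredient == "POSITIVE"])
  expect_true(res$positive_flag[res$ingredient == "POSITIVE"])
  expect_true(all(res$p_adj >= res$p_raw))
  g <- glance(scr)
  expect_equal(g$n_tested, 3L)
  expect_equal(g$n_inverse, sum(res$inverse_flag))
})

test_that("BH family is the post-threshold family by default", {
  tabs <- tibble::tibble(
    ingredient = c("A", "B", "TINY1", "TINY2"),
    a = c(45L, 50L, 2L, 3L),
    b = c(755L, 750L, 30L, 25L),
    c = c(500L, 495L, 543L, 542L),
    d = c(3700L, 3705L, 4370L, 4375L)
  )
  scr <- screen_signals(tabs, screen_config(min_cases = 40))
  res <- tidy(scr)
  expect_equal(sort(res$ingredient), c("A", "B"))
  expect_equal(res$p_adj, bh_adjust(res$p_raw), tolerance = 1e-12)
  # the alternative scope adjusts across all four drugs before filtering;
  # since the sub-threshold drugs here have the largest raw p-values, the
  # surviving drugs keep their ranks and their adjusted values can only grow
  scr2 <- screen_signals(tabs, screen_config(min_cases = 40, adjust = "adjust_then_filter"))
  res2 <- tidy(scr2)
  expect_equal(sort(res2$ingredient), c("A", "B"))
  expect_true(all(res2$p_adj >= res$p_adj[match(res2$ingredient, res$ingredient)] - 1e-12))
})

test_that("strict CI mode flags exactly the default flags whose interval excludes 1", {
  tabs <- simulate_tables(300, 20000, exposure_prob = 0.1,
                          baseline_event_prob = 0.05,
                          planted_or = rep(c(0.6, 0.85, 1), each = 100), seed = 55)
  cfg <- screen_config(min_cases = 40)
  default <- tidy(screen_signals(tabs, cfg))
  strict <- tidy(screen_signals(tabs, screen_config(min_cases = 40, strict_ci = TRUE)))
  expect_equal(strict$inverse_flag, default$inverse_flag & default$ci_high < 1)
  expect_true(any(default$inverse_flag))
})

test_that("empty family warns and returns zero rows", {
  tabs <- tibble::tibble(ingredient = "X", a = 3L, b = 10L, c = 20L, d = 100L)
  expect_warning(scr <- screen_signals(tabs, screen_config(min_cases = 40)),
                 "minimum case threshold")
  expect_equal(nrow(tidy(scr)), 0)
})

test_that("screen statistics agree with simulation ground truth end to end", {
  sim <- simulate_reports(sim_config(
    n_cases = 4000, planted_or = c(0.2, 1), exposure_prob = 0.3,
    baseline_event_prob = 0.2, duplicate_fraction = 0.1, seed = 77
  ))
  d <- tempfile(); write_faers_tables(sim, d)
  tabs <- read_faers_tables(d) |>
    deduplicate_cases() |>
    normalize_drugs(read_lexicon(file.path(d, "lexicon.tsv"))) |>
    build_contingency_tables()
  tabs_focal <- dplyr::semi_join(tabs, sim$truth, by = "ingredient") |>
    dplyr::arrange(.data$ingredient)
  tr <- dplyr::arrange(sim$truth, .data$ingredient)
  expect_equal(tabs_focal$a, tr$a)
  expect_equal(tabs_focal$b, tr$b)
  expect_equal(tabs_focal$c, tr$c)
  expect_equal(tabs_focal$d, tr$d)
  unlink(d, recursive = TRUE)
})
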