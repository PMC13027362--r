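test_that("key normalization uppercases, squashes and strips dosage/form tokens", {
  expect_equal(normalize_key("Lipitor  20mg Tablet"), "LIPITOR")
  expect_equal(normalize_key("  atorvastatin calcium"), "ATORVASTATIN CALCIUM")
  expect_equal(normalize_key("A+B"), "A B")
  expect_equal(normalize_key("DRUG 10 MG CAPSULES"), "DRUG")
  # idempotent
  keys <- normalize_key(c("Humira 40mg injection", "plain name", "X-1.5ML"))
  expect_equal(normalize_key(keys), keys)
})

test_that("reader joins tables, drops orphans and fails on malformed input", {
  d <- write_toy_dataset(tempfile())
  x <- read_faers_tables(d)
  expect_equal(nrow(x$demo), 5)
  expect_equal(nrow(x$drug), 8)  # 9 minus 1 orphan
  expect_equal(nrow(x$reac), 6)  # 7 minus 1 orphan
  audit <- ingest_audit(x)
  expect_equal(audit$count[audit$metric == "orphan_drug_rows_dropped"], 1)
  expect_equal(audit$count[audit$metric == "orphan_reac_rows_dropped"], 1)

  expect_error(read_faers_tables(tempfile()), "Missing FAERS table")
  # corrupt a header
  writeLines(c("wrong$header", "R1$C1"), file.path(d, "reac.txt"))
  expect_error(read_faers_tables(d), "Malformed header")
  # non-integer version
  writeLines(c("report_id$pt", "R1$x"), file.path(d, "reac.txt"))
  writeLines(c("report_id$case_id$case_version", "R1$C1$one"),
             file.path(d, "demo.txt"))
  expect_error(read_faers_tables(d), "Non-integer case_version")
  unlink(d, recursive = TRUE)
})

test_that("deduplication keeps the highest case version with a deterministic tie-break", {
  d <- tempfile(); dir.create(d)
  writeLines(c("report_id$case_id$case_version",
               "RA$C1$1", "RB$C1$2", "RC$C1$3",
               "RX$C2$1", "RY$C2$1",
               "RZ$C3$1"), file.path(d, "demo.txt"))
  writeLines("report_id$drug_seq$role_code$verbatim_name", file.path(d, "drug.txt"))
  writeLines("report_id$pt", file.path(d, "reac.txt"))
  x <- deduplicate_cases(read_faers_tables(d))
  kept <- x$demo
  expect_equal(kept$report_id[kept$case_id == "C1"], "RC")      # max version
  expect_equal(kept$report_id[kept$case_id == "C2"], "RY")      # tie -> greatest id
  audit <- ingest_audit(x)
  expect_equal(audit$count[audit$metric == "duplicate_versions_removed"], 3)
  # conservation: inputs = kept + removed
  expect_equal(audit$count[audit$metric == "reports_in"],
               audit$count[audit$metric == "reports_kept"] +
                 audit$count[audit$metric == "duplicate_versions_removed"])
  # idempotent
  x2 <- deduplicate_cases(x)
  expect_equal(as.data.frame(x2$demo), as.data.frame(x$demo))
  unlink(d, recursive = TRUE)
})

test_that("all-distinct case ids pass through deduplication unchanged", {
  sim <- simulate_reports(sim_config(n_cases = 50, duplicate_fraction = 0, seed = 2))
  d <- tempfile(); write_faers_tables(sim, d)
  x <- deduplicate_cases(read_faers_tables(d))
  expect_equal(nrow(x$demo), 50)
  audit <- ingest_audit(x)
  expect_equal(audit$count[audit$metric == "duplicate_versions_removed"], 0)
  unlink(d, recursive = TRUE)
})

test_that("normalization resolves variants, decomposes combos and audits drops", {
  d <- write_toy_dataset(tempfile())
  cs <- read_faers_tables(d) |>
    deduplicate_cases() |>
    normalize_drugs(toy_lexicon())

  # report R5's only mention is unmapped -> the report is dropped
  expect_setequal(cs$report_ids, c("R2", "R3", "R4"))
  exp <- cs$exposures
  # combination product decomposed; constituent listed alone is not double counted
  r2 <- exp[exp$report_id == "R2", ]
  expect_setequal(r2$ingredient, c("ATORVASTATIN", "AMOXICILLIN", "CLAVULANIC ACID"))
  # roles are unioned per ingredient within a report
  expect_equal(r2$roles[r2$ingredient == "AMOXICILLIN"], "C,SS")
  expect_equal(exp$ingredient[exp$report_id == "R3"], "ADALIMUMAB")
  # verbatim strings never leak through as ingredients
  expect_true(all(exp$ingredient %in% c("ATORVASTATIN", "AMOXICILLIN",
                                        "CLAVULANIC ACID", "ADALIMUMAB")))

  audit <- ingest_audit(cs)
  get <- function(m) audit$count[audit$metric == m]
  expect_equal(get("mentions_in"), 7)
  expect_equal(get("mentions_resolved"), 5)
  expect_equal(get("combinations_decomposed"), 1)
  expect_equal(get("mentions_dropped_unresolvable"), 1)
  expect_equal(get("mentions_dropped_missing_key"), 1)
  expect_equal(get("reports_dropped_no_resolvable"), 1)
  # conservation at the mention level
  expect_equal(get("mentions_in"),
               get("mentions_resolved") + get("mentions_dropped_unresolvable") +
                 get("mentions_dropped_missing_key"))
  empty_lex <- structure(
    tibble::tibble(key = character(), ingredients = character()),
    class = c("drug_lexicon", class(tibble::tibble()))
  )
  expect_error(normalize_drugs(deduplicate_cases(read_faers_tables(d)), empty_lex),
               class = "rorscreen_validation_error")
  unlink(d, recursive = TRUE)
})

test_that("per-ingredient exposure counts match simulation ground truth exactly", {
  cfg <- sim_config(
    n_cases = 1500, planted_or = c(0.3, 1, 2), duplicate_fraction = 0.2,
    exposure_prob = c(0.2, 0.1, 0.15), baseline_event_prob = 0.15, seed = 23,
    combo_products = list(list(name = "SIMDRUG001-SIMDRUG003 COMBO",
                               constituents = c(1L, 3L)))
  )
  sim <- simulate_reports(cfg)
  d <- tempfile(); write_faers_tables(sim, d)
  cs <- read_faers_tables(d) |>
    deduplicate_cases() |>
    normalize_drugs(read_lexicon(file.path(d, "lexicon.tsv")))
  counts <- cs$exposures |>
    dplyr::count(.data$ingredient, name = "exposed") |>
    dplyr::semi_join(sim$truth, by = "ingredient") |>
    dplyr::arrange(.data$ingredient)
  expect_equal(counts$exposed, dplyr::arrange(sim$truth, .data$ingredient)$exposed)
  unlink(d, recursive = TRUE)
})

test_that("downstream counts are invariant to permuting role codes", {
  sim <- simulate_reports(sim_config(n_cases = 500, planted_or = c(0.5, 1),
                                     exposure_prob = 0.2,
                                     baseline_event_prob = 0.2, seed = 12))
  d <- tempfile(); write_faers_tables(sim, d)
  x <- read_faers_tables(d)
  tabs1 <- x |> deduplicate_cases() |>
    normalize_drugs(read_lexicon(file.path(d, "lexicon.tsv"))) |>
    build_contingency_tables()
  perm <- c(PS = "C", SS = "I", C = "PS", I = "SS")
  x$drug$role_code <- unname(perm[x$drug$role_code])
  tabs2 <- x |> deduplicate_cases() |>
    normalize_drugs(read_lexicon(file.path(d, "lexicon.tsv"))) |>
    build_contingency_tables()
  expect_equal(as.data.frame(tabs1), as.data.frame(tabs2))
  unlink(d, recursive = TRUE)
})
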