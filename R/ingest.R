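#' Read FAERS-dialect report tables
#'
#' Reads the three `$`-separated UTF-8 tables of the FAERS ASCII dialect:
#' `demo.txt` (`report_id$case_id$case_version`), `drug.txt`
#' (`report_id$drug_seq$role_code$verbatim_name`) and `reac.txt`
#' (`report_id$pt`). DRUG/REAC rows whose `report_id` has no DEMO row are
#' orphans: they are counted in the audit and discarded.
#'
#' @param dir Directory containing `demo.txt`, `drug.txt`, `reac.txt`.
#' @return An `icsr_tables` object: list of tibbles `demo`, `drug`, `reac`
#'   and an `audit` tibble of row counts.
#' @seealso [deduplicate_cases()], [normalize_drugs()]
#' @export
read_faers_tables <- function(dir) {
  paths <- file.path(dir, c("demo.txt", "drug.txt", "reac.txt"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("Missing FAERS table file(s): ", paste(missing, collapse = ", "))
  }
  specs <- list(
    demo = list(path = paths[1], cols = c("report_id", "case_id", "case_version")),
    drug = list(path = paths[2], cols = c("report_id", "drug_seq", "role_code", "verbatim_name")),
    reac = list(path = paths[3], cols = c("report_id", "pt"))
  )
  tabs <- lapply(specs, function(sp) {
    tb <- readr::read_delim(sp$path, delim = "$", col_types = readr::cols(.default = "c"),
                            progress = FALSE, na = character())
    if (!identical(names(tb), sp$cols)) {
      stop(sprintf("Malformed header in %s: expected '%s', found '%s'.",
                   sp$path, paste(sp$cols, collapse = "$"), paste(names(tb), collapse = "$")))
    }
    tb
  })
  for (nm in c("case_version", "drug_seq")) {
    tb_name <- if (nm == "case_version") "demo" else "drug"
    raw <- tabs[[tb_name]][[nm]]
    val <- suppressWarnings(as.integer(raw))
    bad <- which(is.na(val) | val != suppressWarnings(as.numeric(raw)))
    if (length(bad) > 0L) {
      stop(sprintf("Non-integer %s in %s at data line %d: '%s'.",
                   nm, specs[[tb_name]]$path, bad[1], raw[bad[1]]))
    }
    tabs[[tb_name]][[nm]] <- val
  }
  if (anyDuplicated(tabs$demo$report_id)) {
    stop("Duplicated report_id in ", specs$demo$path)
  }
  known <- tabs$demo$report_id
  orphan_drug <- sum(!tabs$drug$report_id %in% known)
  orphan_reac <- sum(!tabs$reac$report_id %in% known)
  structure(
    list(
      demo = tabs$demo,
      drug = dplyr::filter(tabs$drug, .data$report_id %in% known),
      reac = dplyr::filter(tabs$reac, .data$report_id %in% known),
      audit = tibble(
        metric = c("reports_in", "drug_rows_in", "reac_rows_in",
                   "orphan_drug_rows_dropped", "orphan_reac_rows_dropped"),
        count = c(nrow(tabs$demo), nrow(tabs$drug), nrow(tabs$reac),
                  orphan_drug, orphan_reac)
      )
    ),
    class = "icsr_tables"
  )
}

new_lexicon <- function(entries) {
  structure(entries, class = c("drug_lexicon", class(tibble())))
}

#' Read a drug-name lexicon
#'
#' The lexicon maps key-normalized verbatim drug names (see
#' [normalize_key()]) to one or more active-ingredient names. The file is a
#' two-column headerless TSV: `verbatim_key<TAB>INGREDIENT1|INGREDIENT2`, or
#' the literal `UNRESOLVABLE` to mark a verbatim name that cannot be
#' unambiguously resolved.
#'
#' @param path Path to the lexicon TSV.
#' @return A `drug_lexicon` tibble with columns `key` and `ingredients`
#'   (pipe-joined, or `"UNRESOLVABLE"`).
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("Lexicon file not found: ", path)
  tb <- readr::read_tsv(path, col_names = c("key", "ingredients"),
                        col_types = "cc", progress = FALSE)
  if (nrow(tb) == 0L) abort_validation(paste0("Lexicon is empty: ", path))
  if (anyDuplicated(tb$key)) abort_validation("Lexicon keys must be unique.")
  if (any(is.na(tb$ingredients) | tb$ingredients == "")) {
    abort_validation("Lexicon ingredient lists must be non-empty.")
  }
  new_lexicon(tb)
}

write_lexicon <- function(lexicon, path) {
  readr::write_tsv(tibble(key = lexicon$key, ingredients = lexicon$ingredients),
                   path, col_names = FALSE)
  invisible(path)
}

#' Normalize a verbatim drug name to its lexicon key
#'
#' Uppercases, strips punctuation to spaces, collapses internal whitespace,
#' and repeatedly removes trailing dosage tokens (digits plus MG/MCG/G/ML/IU/%)
#' and formulation tokens (TABLET(S), CAPSULE(S), INJECTION, SOLUTION, SYRUP,
#' CREAM). Idempotent.
#'
#' @param x Character vector of verbatim names.
#' @return Character vector of lexicon keys.
#' @examples
#' normalize_key("Lipitor  20mg Tablet")  # "LIPITOR"
#' @export
normalize_key <- function(x) {
  key <- toupper(x)
  key <- gsub("[^A-Z0-9 ]+", " ", key)
  key <- stringr::str_squish(key)
  trailing <- paste0(
    "( (\\d+(\\.\\d+)?(MG|MCG|G|ML|IU)?|MG|MCG|ML|IU|",
    "TABLETS?|CAPSULES?|INJECTION|SOLUTION|SYRUP|CREAM))+$"
  )
  sub(trailing, "", key)
}

#' Deduplicate reports by FDA case-version logic
#'
#' Within each `case_id`, keeps only the report with the highest
#' `case_version` (the definitive version); earlier versions are superseded
#' and removed, along with their DRUG and REAC rows. A tie on version —
#' which a well-formed extract should not contain — is broken
#' deterministically in favour of the lexicographically greatest
#' `report_id`.
#'
#' @param x An `icsr_tables` object from [read_faers_tables()].
#' @return An `icsr_tables` object with one report per case and audit rows
#'   `duplicate_versions_removed` and `reports_kept` appended.
#' @export
deduplicate_cases <- function(x) {
  if (!inherits(x, "icsr_tables")) abort_validation("`x` must be an `icsr_tables`.")
  keep <- x$demo |>
    dplyr::arrange(.data$case_id, dplyr::desc(.data$case_version),
                   dplyr::desc(.data$report_id)) |>
    dplyr::distinct(.data$case_id, .keep_all = TRUE)
  removed <- nrow(x$demo) - nrow(keep)
  keep <- dplyr::arrange(keep, .data$report_id)
  structure(
    list(
      demo = keep,
      drug = dplyr::filter(x$drug, .data$report_id %in% keep$report_id),
      reac = dplyr::filter(x$reac, .data$report_id %in% keep$report_id),
      audit = dplyr::bind_rows(x$audit, tibble(
        metric = c("duplicate_versions_removed", "reports_kept"),
        count = c(removed, nrow(keep))
      ))
    ),
    class = "icsr_tables"
  )
}

#' Normalize verbatim drug mentions to active ingredients
#'
#' Each mention's verbatim name is key-normalized ([normalize_key()]) and
#' looked up in the lexicon. Combination products contribute every
#' constituent ingredient; mentions marked `UNRESOLVABLE`, or whose key is
#' absent from the lexicon, are dropped (counted separately in the audit). A
#' report left with zero resolvable mentions is dropped entirely. Within a
#' report, ingredients are a set (a combination listing an ingredient that is
#' also reported alone contributes it once) and role codes are unioned per
#' ingredient.
#'
#' @param x A deduplicated `icsr_tables` object.
#' @param lexicon A `drug_lexicon` from [read_lexicon()] or [sim_lexicon()].
#' @return A `case_set` object: list with tibbles `exposures` (`report_id`,
#'   `case_id`, `ingredient`, `roles` — comma-joined sorted role codes),
#'   `events` (`report_id`, `pt`), the kept `report_ids`, and the cumulative
#'   `audit`.
#' @export
normalize_drugs <- function(x, lexicon) {
  if (!inherits(x, "icsr_tables")) abort_validation("`x` must be an `icsr_tables`.")
  if (!inherits(lexicon, "drug_lexicon") || nrow(lexicon) == 0L) {
    abort_validation("`lexicon` must be a non-empty `drug_lexicon`.")
  }
  mentions <- x$drug |>
    dplyr::mutate(key = normalize_key(.data$verbatim_name)) |>
    dplyr::left_join(as_tibble(lexicon), by = "key")

  n_missing <- sum(is.na(mentions$ingredients))
  n_unresolvable <- sum(!is.na(mentions$ingredients) &
                          mentions$ingredients == "UNRESOLVABLE")
  resolved <- mentions |>
    dplyr::filter(!is.na(.data$ingredients), .data$ingredients != "UNRESOLVABLE")
  n_combo <- sum(grepl("|", resolved$ingredients, fixed = TRUE))

  exposures <- resolved |>
    dplyr::mutate(ingredient = strsplit(.data$ingredients, "|", fixed = TRUE)) |>
    tidyr::unnest("ingredient") |>
    dplyr::group_by(.data$report_id, .data$ingredient) |>
    dplyr::summarise(
      roles = paste(sort(unique(.data$role_code)), collapse = ","),
      .groups = "drop"
    )

  kept_ids <- sort(unique(exposures$report_id))
  dropped_reports <- nrow(x$demo) - length(kept_ids)
  exposures <- x$demo |>
    dplyr::select("report_id", "case_id") |>
    dplyr::inner_join(exposures, by = "report_id") |>
    dplyr::arrange(.data$report_id, .data$ingredient)

  structure(
    list(
      exposures = exposures,
      events = x$reac |>
        dplyr::filter(.data$report_id %in% kept_ids) |>
        dplyr::distinct(.data$report_id, .data$pt),
      report_ids = kept_ids,
      audit = dplyr::bind_rows(x$audit, tibble(
        metric = c("mentions_in", "mentions_resolved", "combinations_decomposed",
                   "mentions_dropped_unresolvable", "mentions_dropped_missing_key",
                   "reports_dropped_no_resolvable", "reports_after_normalization"),
        count = c(nrow(mentions), nrow(resolved), n_combo,
                  n_unresolvable, n_missing, dropped_reports, length(kept_ids))
      ))
    ),
    class = "case_set"
  )
}

#' @export
print.case_set <- function(x, ...) {
  cat(sprintf("<case_set> %d reports, %d distinct ingredients, %d event rows\n",
              length(x$report_ids), dplyr::n_distinct(x$exposures$ingredient),
              nrow(x$events)))
  invisible(x)
}

#' Retrieve the ingest audit trail
#'
#' @param x An `icsr_tables` or `case_set` object.
#' @return A tibble of audit metrics and counts accumulated across the
#'   ingest stages (row counts, duplicates removed, mentions resolved or
#'   dropped, reports dropped).
#' @export
ingest_audit <- function(x) {
  if (!inherits(x, c("icsr_tables", "case_set"))) {
    abort_validation("`x` must be an `icsr_tables` or `case_set`.")
  }
  x$audit
}
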