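#' Feasibility exclusion lists
#'
#' Post-statistical feasibility filtering is a clinical judgment that cannot
#' be recomputed from the data; it is represented here as declarative,
#' versioned exclusion lists with mandatory reason logging. Categories are
#' checked in the order given below; the first matching category is recorded
#' as the exclusion reason.
#'
#' @param non_systemic Ingredients excluded as non-systemic formulations.
#' @param diagnostic Diagnostic agents.
#' @param withdrawn Withdrawn products.
#' @param pk_implausible Pharmacokinetically implausible compounds.
#' @param known_ineffective_or_aggravating Drugs with established lack of
#'   efficacy or documented disease-aggravating effects.
#' @return A `feasibility_config` object.
#' @export
feasibility_config <- function(non_systemic = character(),
                               diagnostic = character(),
                               withdrawn = character(),
                               pk_implausible = character(),
                               known_ineffective_or_aggravating = character()) {
  cfg <- list(
    non_systemic = non_systemic,
    diagnostic = diagnostic,
    withdrawn = withdrawn,
    pk_implausible = pk_implausible,
    known_ineffective_or_aggravating = known_ineffective_or_aggravating
  )
  for (nm in names(cfg)) {
    if (!is.character(cfg[[nm]])) abort_validation(sprintf("`%s` must be a character vector.", nm))
  }
  structure(cfg, class = "feasibility_config")
}

#' Read a feasibility configuration from JSON
#'
#' The JSON document holds one array of ingredient names per category named
#' as in [feasibility_config()]; absent categories default to empty.
#'
#' @param path Path to the JSON file.
#' @return A `feasibility_config` object.
#' @export
read_feasibility_config <- function(path) {
  if (!file.exists(path)) stop("Feasibility config not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(feasibility_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    abort_validation(paste0("Unknown feasibility categories: ", paste(unknown, collapse = ", ")))
  }
  do.call(feasibility_config, lapply(raw[intersect(known, names(raw))], as.character))
}

#' Therapeutic-class annotation map
#'
#' Maps ingredient names to free-text therapeutic class labels and
#' designates a subset of labels as immune-mediated/immunomodulatory (or any
#' other prioritized family). Unmapped ingredients receive the class
#' `"UNCLASSIFIED"`.
#'
#' @param classes Named character vector: ingredient name -> class label.
#' @param designated Character vector of class labels counted as designated.
#' @return A `class_map` object.
#' @export
class_map <- function(classes, designated) {
  if (!is.character(classes) || is.null(names(classes)) || anyDuplicated(names(classes))) {
    abort_validation("`classes` must be a uniquely named character vector.")
  }
  if (!is.character(designated)) abort_validation("`designated` must be a character vector.")
  structure(list(classes = classes, designated = designated), class = "class_map")
}

#' Read a therapeutic-class map from JSON
#'
#' The JSON document has an object `classes` (ingredient -> class label) and
#' an array `designated` of prioritized class labels.
#'
#' @param path Path to the JSON file.
#' @return A `class_map` object.
#' @export
read_class_map <- function(path) {
  if (!file.exists(path)) stop("Class map not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$classes) || is.null(raw$designated)) {
    abort_validation("Class map JSON needs `classes` and `designated`.")
  }
  class_map(unlist(raw$classes), as.character(raw$designated))
}

funnel_stages <- function(x) attr(x, "funnel_stages") %||%
  tibble(stage = character(), n_in = integer(), n_out = integer())

funnel_exclusions <- function(x) attr(x, "funnel_exclusions") %||%
  tibble(ingredient = character(), stage = character(), reason = character())

push_stage <- function(x, parent, stage, n_in, excluded) {
  attr(x, "funnel_stages") <- dplyr::bind_rows(
    funnel_stages(parent),
    tibble(stage = stage, n_in = as.integer(n_in), n_out = nrow(x))
  )
  attr(x, "funnel_exclusions") <- dplyr::bind_rows(funnel_exclusions(parent), excluded)
  x
}

#' Extract flagged signals from a screen to start the candidate funnel
#'
#' @param x A `ror_screen` object.
#' @param direction Flag direction; defaults to the screen's configuration.
#' @return A tibble of flagged results (ascending ROR) carrying the funnel
#'   audit in attributes; pipe into [apply_feasibility()],
#'   [restrict_to_classes()] and [rank_candidates()], and read the audit
#'   with [funnel_audit()].
#' @export
flagged_signals <- function(x, direction = NULL) {
  if (!inherits(x, "ror_screen")) abort_validation("`x` must be a `ror_screen`.")
  direction <- direction %||% x$config$direction
  direction <- rlang::arg_match(direction, c("inverse", "positive", "both"))
  keep <- switch(direction,
    inverse = x$results$inverse_flag,
    positive = x$results$positive_flag,
    both = x$results$inverse_flag | x$results$positive_flag
  )
  out <- x$results[keep, , drop = FALSE]
  push_stage(out, out, paste0("statistical_flag_", direction), nrow(x$results),
             excluded = NULL)
}

#' Apply feasibility exclusions
#'
#' Removes ingredients listed in any category of the configuration
#' (case-insensitive match) and records the first matching category as the
#' exclusion reason. With an empty configuration this is the identity.
#' Ascending-ROR order is preserved.
#'
#' @param results A tibble of signal results with an `ingredient` column
#'   (typically from [flagged_signals()] or [ibd_candidates()]).
#' @param config A [feasibility_config()].
#' @return The surviving results, with the funnel audit updated.
#' @export
apply_feasibility <- function(results, config = feasibility_config()) {
  if (!is.data.frame(results) || !"ingredient" %in% names(results)) {
    abort_validation("`results` must be a data frame with an `ingredient` column.")
  }
  if (!inherits(config, "feasibility_config")) {
    abort_validation("`config` must be a `feasibility_config`.")
  }
  key <- tolower(trimws(results$ingredient))
  reason <- rep(NA_character_, nrow(results))
  for (cat in names(config)) {
    hit <- is.na(reason) & key %in% tolower(trimws(config[[cat]]))
    reason[hit] <- cat
  }
  out <- results[is.na(reason), , drop = FALSE]
  excluded <- tibble(
    ingredient = results$ingredient[!is.na(reason)],
    stage = "feasibility",
    reason = reason[!is.na(reason)]
  )
  push_stage(out, results, "feasibility", nrow(results), excluded)
}

#' Restrict candidates to designated therapeutic classes
#'
#' Annotates every result with its therapeutic class (`"UNCLASSIFIED"` when
#' unmapped; matching is case-insensitive) and keeps those whose class label
#' is in the map's designated set.
#'
#' @param results A tibble of signal results with an `ingredient` column.
#' @param map A [class_map()].
#' @return The surviving results with a `class` column added and the funnel
#'   audit updated.
#' @export
restrict_to_classes <- function(results, map) {
  if (!is.data.frame(results) || !"ingredient" %in% names(results)) {
    abort_validation("`results` must be a data frame with an `ingredient` column.")
  }
  if (!inherits(map, "class_map")) abort_validation("`map` must be a `class_map`.")
  lut <- stats::setNames(unname(map$classes), tolower(trimws(names(map$classes))))
  cls <- unname(lut[tolower(trimws(results$ingredient))])
  cls[is.na(cls)] <- "UNCLASSIFIED"
  annotated <- dplyr::mutate(results, class = cls)
  keep <- cls %in% map$designated
  out <- annotated[keep, , drop = FALSE]
  excluded <- tibble(
    ingredient = results$ingredient[!keep],
    stage = "class_restriction",
    reason = paste0("class:", cls[!keep])
  )
  push_stage(out, results, "class_restriction", nrow(results), excluded)
}

#' Rank candidates by ascending reporting odds ratio
#'
#' @param results A tibble of signal results with `ror` and `ingredient`
#'   columns; ties on ROR are broken by ingredient name.
#' @return The ranked tibble (funnel audit preserved).
#' @export
rank_candidates <- function(results) {
  if (!is.data.frame(results) || !all(c("ingredient", "ror") %in% names(results))) {
    abort_validation("`results` must have `ingredient` and `ror` columns.")
  }
  out <- results[order(results$ror, results$ingredient), , drop = FALSE]
  attr(out, "funnel_stages") <- funnel_stages(results)
  attr(out, "funnel_exclusions") <- funnel_exclusions(results)
  out
}

#' Retrieve the candidate-funnel audit
#'
#' @param results A tibble that has passed through [flagged_signals()],
#'   [apply_feasibility()] or [restrict_to_classes()].
#' @return A list with tibbles `stages` (stage, entering count, surviving
#'   count) and `exclusions` (ingredient, stage, reason). Entering counts of
#'   each stage equal the surviving count of the previous stage.
#' @export
funnel_audit <- function(results) {
  list(stages = funnel_stages(results), exclusions = funnel_exclusions(results))
}

#' Export ranked candidates and forest-plot data as TSV
#'
#' `export_candidates()` writes columns `drug`, `ror`, `ci_low`, `ci_high`
#' rounded to 3 decimals in ascending ROR order (ties by name).
#' `export_forest()` writes the same plus `log_mid`, the geometric mean of
#' the confidence bounds (the midpoint on a log-scaled axis).
#'
#' @param results A tibble with `ingredient`, `ror`, `ci_low`, `ci_high`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_candidates <- function(results, path) {
  ranked <- rank_candidates(results)
  ranked |>
    dplyr::transmute(
      drug = .data$ingredient,
      ror = round_half_up(.data$ror),
      ci_low = round_half_up(.data$ci_low),
      ci_high = round_half_up(.data$ci_high)
    ) |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname export_candidates
#' @export
export_forest <- function(results, path) {
  ranked <- rank_candidates(results)
  ranked |>
    dplyr::transmute(
      drug = .data$ingredient,
      ror = round_half_up(.data$ror),
      ci_low = round_half_up(.data$ci_low),
      ci_high = round_half_up(.data$ci_high),
      log_mid = round_half_up(sqrt(.data$ci_low * .data$ci_high))
    ) |>
    readr::write_tsv(path)
  invisible(path)
}
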