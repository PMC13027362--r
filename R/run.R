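read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("Config file not found: ", config)
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else if (is.list(config)) {
    config
  } else {
    abort_validation("`config` must be a JSON file path or a list.")
  }
}

write_resolved_config <- function(cfg, out_dir) {
  jsonlite::write_json(cfg, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

ensure_dir <- function(path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("Cannot create output directory: ", path)
  path
}

#' Run the simulation stage from a configuration file
#'
#' Generates a synthetic FAERS-like dataset and writes `demo.txt`,
#' `drug.txt`, `reac.txt`, `lexicon.tsv`, `ground_truth.tsv` and a
#' resolved-configuration copy to the output directory. Recognized config
#' fields are the arguments of [sim_config()] plus `out_dir`; `seed` is
#' mandatory.
#'
#' @param config Path to a JSON configuration, or an equivalent list.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return Invisibly, the output directory.
#' @export
run_simulate <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) abort_validation("`out_dir` is required.")
  cfg$out_dir <- NULL
  known <- names(formals(sim_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    abort_validation(paste0("Unknown simulate config fields: ",
                            paste(unknown, collapse = ", ")))
  }
  sim <- simulate_reports(do.call(sim_config, cfg))
  ensure_dir(out_dir)
  write_faers_tables(sim, out_dir)
  resolved <- sim$config
  resolved$name_variants <- as.list(resolved$name_variants)
  write_resolved_config(c(unclass(resolved), list(out_dir = out_dir)), out_dir)
  invisible(out_dir)
}

#' Run the full screening pipeline from a configuration file
#'
#' End-to-end run: read FAERS-dialect tables, deduplicate case versions,
#' normalize drug names against the lexicon, build report-level 2x2 tables
#' for the configured event terms, screen for disproportionality signals,
#' apply feasibility exclusions and therapeutic-class restriction, and rank
#' the surviving candidates. Writes `family.tsv` (the whole tested family),
#' `candidates.tsv`, `forest.tsv`, `funnel.json` (ingest audit + candidate
#' funnel) and `resolved_config.json` to the output directory.
#'
#' Config fields: `data_dir` (with the three tables), `lexicon` (TSV path),
#' `out_dir`, optional `event_pts`, `min_cases`, `alpha`, `ci_level`,
#' `direction`, `strict_ci`, `p_method`, `adjust` (see [screen_config()]),
#' and optional `feasibility` / `class_map` JSON paths.
#'
#' @param config Path to a JSON configuration, or an equivalent list.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return Invisibly, a list with the `ror_screen` object, the final
#'   candidates tibble and the funnel audit.
#' @export
run_screen <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  for (field in c("data_dir", "lexicon")) {
    if (is.null(cfg[[field]])) abort_validation(sprintf("`%s` is required.", field))
  }
  if (is.null(out_dir)) abort_validation("`out_dir` is required.")

  sc_args <- cfg[intersect(names(cfg), names(formals(screen_config)))]
  if (!is.null(sc_args$event_pts)) sc_args$event_pts <- as.character(sc_args$event_pts)
  sconf <- do.call(screen_config, sc_args)

  cases <- read_faers_tables(cfg$data_dir) |>
    deduplicate_cases() |>
    normalize_drugs(read_lexicon(cfg$lexicon))
  scr <- build_contingency_tables(cases, sconf$event_pts) |>
    screen_signals(sconf)

  candidates <- flagged_signals(scr)
  if (!is.null(cfg$feasibility)) {
    candidates <- apply_feasibility(candidates, read_feasibility_config(cfg$feasibility))
  }
  if (!is.null(cfg$class_map)) {
    candidates <- restrict_to_classes(candidates, read_class_map(cfg$class_map))
  }
  candidates <- rank_candidates(candidates)

  ensure_dir(out_dir)
  export_family(scr, file.path(out_dir, "family.tsv"))
  export_candidates(candidates, file.path(out_dir, "candidates.tsv"))
  export_forest(candidates, file.path(out_dir, "forest.tsv"))
  audit <- funnel_audit(candidates)
  jsonlite::write_json(
    list(ingest = ingest_audit(cases), funnel = audit$stages,
         exclusions = audit$exclusions),
    file.path(out_dir, "funnel.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  write_resolved_config(c(cfg, list(out_dir = out_dir)), out_dir)
  invisible(list(screen = scr, candidates = candidates, funnel = audit))
}

#' Run a calibration study from a configuration file
#'
#' Dispatches to [null_fdr_study()], [coverage_study()] or
#' [recovery_study()] according to the config's `study` field; remaining
#' fields are passed as arguments. Writes `<study>.json`,
#' `<study>_summary.tsv` and `resolved_config.json` to the output
#' directory.
#'
#' @param config Path to a JSON configuration, or an equivalent list.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return Invisibly, the `calibration_report`.
#' @export
run_calibrate <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) abort_validation("`out_dir` is required.")
  study <- cfg$study
  studies <- list(null_fdr = null_fdr_study, coverage = coverage_study,
                  recovery = recovery_study)
  if (is.null(study) || !study %in% names(studies)) {
    abort_validation(paste0("`study` must be one of: ",
                            paste(names(studies), collapse = ", ")))
  }
  args <- cfg[setdiff(names(cfg), c("study", "out_dir"))]
  if (!is.null(args$config) && !inherits(args$config, "screen_config")) {
    args$config <- do.call(screen_config, args$config)
  }
  unknown <- setdiff(names(args), names(formals(studies[[study]])))
  if (length(unknown) > 0L) {
    abort_validation(paste0("Unknown fields for study '", study, "': ",
                            paste(unknown, collapse = ", ")))
  }
  report <- do.call(studies[[study]], args)
  ensure_dir(out_dir)
  write_calibration(report, file.path(out_dir, study))
  write_resolved_config(c(cfg, list(out_dir = out_dir)), out_dir)
  invisible(report)
}
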