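#' Configure a synthetic spontaneous-reporting system
#'
#' Defines the generative model for FAERS-like individual case safety reports
#' (ICSRs) with known ground truth. Each case is independently exposed to each
#' drug with probability `exposure_prob`; the odds of the target event for a
#' case are the baseline odds multiplied by `planted_or` for every drug the
#' case is exposed to (effects combine multiplicatively on the odds scale), so
#' the marginal report-level reporting odds ratio of a drug estimates its
#' planted value. Exposed drugs are written under messy verbatim spellings
#' drawn from `name_variants`, configured combination products replace their
#' constituents' mentions, and a fraction of cases additionally emit a
#' superseded earlier case version that ingest-side deduplication must remove.
#'
#' @param n_cases Number of unique cases to simulate.
#' @param n_drugs Number of drugs; defaults to `length(planted_or)`.
#' @param exposure_prob Per-drug exposure probability in (0, 1); recycled to
#'   `n_drugs`.
#' @param baseline_event_prob Probability in (0, 1) of the target event for a
#'   fully unexposed case.
#' @param planted_or Per-drug multiplier on the event odds (1 = null,
#'   values below 1 plant an inverse signal); recycled to `n_drugs`.
#' @param duplicate_fraction Probability in \[0, 1) that a case also emits a
#'   superseded version-1 report row.
#' @param name_variants Named list (names are ingredient names, uppercase) of
#'   character vectors of verbatim spellings, one element per drug. `NULL`
#'   builds a default set per drug: the canonical name, a dosage-suffixed
#'   form, and a lower-case salt form.
#' @param combo_products List of `list(name =, constituents =)` combination
#'   products; `constituents` are drug indices. When a case is exposed to all
#'   constituents, their individual mentions are replaced by one mention of
#'   the combination's verbatim name.
#' @param n_noise_events Number of non-target preferred terms drawn per
#'   report from a fixed synthetic vocabulary (`"PT_0001"`...), disjoint from
#'   the target terms.
#' @param background_drugs Size of a vocabulary of background co-medications
#'   (`"COMED001"`...); every case reports one, drawn uniformly, mirroring
#'   the concomitant therapy that makes real reports never drug-free. This
#'   keeps unexposed reports in the analysis universe through
#'   normalization, so the pipeline recovers the ground-truth cells
#'   exactly. Set to 0 to disable (cases without exposures then emit no
#'   drug rows and are dropped at normalization).
#' @param event_pts Target preferred terms; a case with the event reports one
#'   of these, chosen uniformly.
#' @param seed Integer seed; identical configurations produce byte-identical
#'   datasets.
#'
#' @return A `sim_config` object (a validated list).
#' @seealso [simulate_reports()], [write_faers_tables()]
#' @export
sim_config <- function(n_cases,
                       n_drugs = NULL,
                       exposure_prob = 0.05,
                       baseline_event_prob = 0.05,
                       planted_or = 1,
                       duplicate_fraction = 0,
                       name_variants = NULL,
                       combo_products = list(),
                       n_noise_events = 2L,
                       background_drugs = 20L,
                       event_pts = c("Ulcerative colitis", "Crohn's disease"),
                       seed = NULL) {
  n_cases <- chk_count(n_cases, "n_cases", min = 1L)
  if (is.null(seed)) abort_validation("`seed` is required for a reproducible simulation.")
  seed <- chk_count(seed, "seed", min = 0L)
  n_drugs <- chk_count(n_drugs %||% max(length(planted_or), 1L), "n_drugs", min = 1L)
  exposure_prob <- chk_prob(rep_len(exposure_prob, n_drugs), "exposure_prob", n = n_drugs)
  baseline_event_prob <- chk_prob(baseline_event_prob, "baseline_event_prob")
  if (!is.numeric(planted_or) || anyNA(planted_or) || any(planted_or <= 0)) {
    abort_validation("`planted_or` must be positive.")
  }
  planted_or <- rep_len(as.numeric(planted_or), n_drugs)
  duplicate_fraction <- chk_prob(duplicate_fraction, "duplicate_fraction",
                                 open_lower = FALSE)
  n_noise_events <- chk_count(n_noise_events, "n_noise_events", min = 0L)
  background_drugs <- chk_count(background_drugs, "background_drugs", min = 0L)
  if (!is.character(event_pts) || length(event_pts) < 1L) {
    abort_validation("`event_pts` must be a non-empty character vector.")
  }

  if (is.null(name_variants)) {
    ingredient <- sprintf("SIMDRUG%03d", seq_len(n_drugs))
    name_variants <- lapply(ingredient, function(nm) {
      c(nm, paste(nm, "10MG TABLET"), tolower(paste(nm, "sodium")))
    })
    names(name_variants) <- ingredient
  }
  if (!is.list(name_variants) || length(name_variants) != n_drugs ||
      is.null(names(name_variants)) || anyDuplicated(names(name_variants))) {
    abort_validation("`name_variants` must be a uniquely named list with one element per drug.")
  }
  if (any(lengths(name_variants) == 0L)) {
    abort_validation("Every drug needs at least one verbatim name variant.")
  }

  for (cp in combo_products) {
    if (!is.list(cp) || is.null(cp$name) || is.null(cp$constituents)) {
      abort_validation("Each combo product needs `name` and `constituents`.")
    }
    idx <- cp$constituents
    if (length(idx) < 2L || any(idx < 1L | idx > n_drugs | idx != floor(idx))) {
      abort_validation("Combo `constituents` must be >= 2 valid drug indices.")
    }
  }

  structure(
    list(
      n_cases = n_cases, n_drugs = n_drugs,
      exposure_prob = exposure_prob,
      baseline_event_prob = baseline_event_prob,
      planted_or = planted_or,
      duplicate_fraction = duplicate_fraction,
      name_variants = name_variants,
      combo_products = combo_products,
      n_noise_events = n_noise_events,
      background_drugs = background_drugs,
      event_pts = event_pts,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' Simulate a FAERS-like dataset with known ground truth
#'
#' Draws exposures, target events, verbatim drug mentions, noise preferred
#' terms and superseded duplicate case versions under the model described in
#' [sim_config()]. The returned ground truth records, per drug, the planted
#' odds ratio, the realized exposure count and the realized report-level 2x2
#' cells among the definitive (highest-version) reports — exactly what the
#' ingest and statistics stages should recover.
#'
#' @param cfg A [sim_config()].
#' @return A `faers_sim` object: a list with tibbles `demo`, `drug`, `reac`
#'   (the three raw report tables, including superseded versions), `truth`
#'   (per-drug ground truth), `lexicon` (the verbatim-to-ingredient lexicon
#'   matching the emitted names), and the `config`.
#' @examples
#' sim <- simulate_reports(sim_config(n_cases = 500, planted_or = c(0.3, 1), seed = 7))
#' sim$demo
#' sim$truth
#' @export
simulate_reports <- function(cfg) {
  if (!inherits(cfg, "sim_config")) abort_validation("`cfg` must be a `sim_config`.")
  withr::with_seed(cfg$seed, simulate_reports_impl(cfg))
}

simulate_reports_impl <- function(cfg) {
  n <- cfg$n_cases
  J <- cfg$n_drugs
  ingredients <- names(cfg$name_variants)

  # exposure matrix and event indicator
  x <- matrix(stats::rbinom(n * J, 1L, rep(cfg$exposure_prob, each = n)),
              nrow = n, ncol = J)
  base_odds <- cfg$baseline_event_prob / (1 - cfg$baseline_event_prob)
  odds <- base_odds * exp(as.vector(x %*% log(cfg$planted_or)))
  event <- stats::rbinom(n, 1L, odds / (1 + odds)) == 1L

  case_id <- sprintf("C%07d", seq_len(n))
  dup <- stats::runif(n) < cfg$duplicate_fraction
  def_version <- ifelse(dup, 2L, 1L)
  def_report <- sprintf("R%07d", seq_len(n))
  sup_report <- sprintf("S%07d", which(dup))

  demo <- tibble(
    report_id = c(def_report, sup_report),
    case_id = c(case_id, case_id[dup]),
    case_version = c(def_version, rep(1L, sum(dup)))
  )

  # verbatim drug mentions for definitive rows
  hit <- which(x == 1L, arr.ind = TRUE)
  mention <- tibble(case = hit[, 1L], drug = hit[, 2L])
  # combination products: a case exposed to all constituents reports the
  # combo's verbatim name instead of the individual constituents
  combo_rows <- NULL
  for (cp in cfg$combo_products) {
    cs <- as.integer(cp$constituents)
    eligible <- which(rowSums(x[, cs, drop = FALSE]) == length(cs))
    if (length(eligible) == 0L) next
    mention <- dplyr::filter(mention, !(.data$case %in% eligible & .data$drug %in% cs))
    combo_rows <- dplyr::bind_rows(
      combo_rows, tibble(case = eligible, verbatim = cp$name)
    )
  }
  nv <- lengths(cfg$name_variants)
  flat <- unlist(cfg$name_variants, use.names = FALSE)
  off <- cumsum(c(0L, nv[-length(nv)]))
  vi <- ceiling(stats::runif(nrow(mention)) * nv[mention$drug])
  mention <- tibble(case = mention$case, verbatim = flat[off[mention$drug] + vi])
  mention <- dplyr::bind_rows(mention, combo_rows)
  if (cfg$background_drugs > 0L) {
    comed <- sprintf("COMED%03d", sample.int(cfg$background_drugs, n, replace = TRUE))
    mention <- dplyr::bind_rows(mention, tibble(case = seq_len(n), verbatim = comed))
  }
  mention <- dplyr::arrange(mention, .data$case, .data$verbatim)
  mention$role_code <- sample(c("PS", "SS", "C", "I"), nrow(mention), replace = TRUE)

  drug_def <- mention |>
    dplyr::group_by(.data$case) |>
    dplyr::mutate(drug_seq = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      report_id = def_report[.data$case],
      drug_seq = .data$drug_seq,
      role_code = .data$role_code,
      verbatim_name = .data$verbatim,
      case = .data$case
    )
  # superseded rows carry the same content under the earlier report id
  drug_sup <- drug_def |>
    dplyr::filter(dup[.data$case]) |>
    dplyr::mutate(report_id = sprintf("S%07d", .data$case))
  drug <- dplyr::bind_rows(drug_def, drug_sup) |>
    dplyr::select(!"case") |>
    dplyr::arrange(.data$report_id, .data$drug_seq)

  # reactions: the target PT (if the event fired) plus noise PTs from a
  # vocabulary disjoint from any plausible target term
  target_pt <- sample(cfg$event_pts, n, replace = TRUE)
  reac <- tibble(case = which(event), pt = target_pt[event])
  if (cfg$n_noise_events > 0L) {
    noise <- tibble(
      case = rep(seq_len(n), each = cfg$n_noise_events),
      pt = sprintf("PT_%04d", sample.int(500L, n * cfg$n_noise_events, replace = TRUE))
    )
    reac <- dplyr::bind_rows(reac, noise)
  }
  reac <- dplyr::distinct(reac, .data$case, .data$pt)
  reac_def <- tibble(report_id = def_report[reac$case], pt = reac$pt, case = reac$case)
  reac_sup <- reac_def |>
    dplyr::filter(dup[.data$case]) |>
    dplyr::mutate(report_id = sprintf("S%07d", .data$case))
  reac <- dplyr::bind_rows(reac_def, reac_sup) |>
    dplyr::select(!"case") |>
    dplyr::arrange(.data$report_id, .data$pt)

  # ground truth over definitive reports only
  a <- as.integer(colSums(x * event))
  exposed <- as.integer(colSums(x))
  n_event <- sum(event)
  truth <- tibble(
    ingredient = ingredients,
    planted_or = cfg$planted_or,
    exposed = exposed,
    a = a,
    b = exposed - a,
    c = n_event - a,
    d = n - exposed - n_event + a
  )

  structure(
    list(demo = demo, drug = drug, reac = reac, truth = truth,
         lexicon = sim_lexicon(cfg), config = cfg),
    class = "faers_sim"
  )
}

#' Build the drug-name lexicon matching a simulation's verbatim names
#'
#' Every configured name variant and combination product maps, under
#' [normalize_key()], to its ingredient(s), so the normalization stage can
#' resolve all emitted mentions.
#'
#' @param cfg A [sim_config()].
#' @return A `drug_lexicon` tibble (see [read_lexicon()]).
#' @export
sim_lexicon <- function(cfg) {
  if (!inherits(cfg, "sim_config")) abort_validation("`cfg` must be a `sim_config`.")
  ingredients <- names(cfg$name_variants)
  entries <- tibble(
    key = normalize_key(unlist(cfg$name_variants, use.names = FALSE)),
    ingredients = rep(ingredients, lengths(cfg$name_variants))
  )
  if (cfg$background_drugs > 0L) {
    comed <- sprintf("COMED%03d", seq_len(cfg$background_drugs))
    entries <- dplyr::bind_rows(entries, tibble(key = comed, ingredients = comed))
  }
  if (length(cfg$combo_products) > 0L) {
    entries <- dplyr::bind_rows(entries, tibble(
      key = normalize_key(vapply(cfg$combo_products, `[[`, "", "name")),
      ingredients = vapply(
        cfg$combo_products,
        function(cp) paste(ingredients[cp$constituents], collapse = "|"), ""
      )
    ))
  }
  new_lexicon(dplyr::distinct(entries, .data$key, .keep_all = TRUE))
}

#' Write a simulated dataset as FAERS-dialect files
#'
#' Writes `demo.txt`, `drug.txt` and `reac.txt` in the `$`-separated FAERS
#' ASCII dialect read by [read_faers_tables()], plus `lexicon.tsv`,
#' `ground_truth.tsv` and `sim_config.json` so a run is fully reproducible
#' from its output directory.
#'
#' @param sim A `faers_sim` from [simulate_reports()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_faers_tables <- function(sim, dir) {
  if (!inherits(sim, "faers_sim")) abort_validation("`sim` must be a `faers_sim`.")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("Cannot create output directory: ", dir)
  has_sep <- vapply(
    list(sim$demo, sim$drug, sim$reac),
    function(tb) any(vapply(tb, function(col) any(grepl("$", col, fixed = TRUE)), TRUE)),
    TRUE
  )
  if (any(has_sep)) abort_validation("Field values must not contain the '$' separator.")
  readr::write_delim(sim$demo, file.path(dir, "demo.txt"), delim = "$")
  readr::write_delim(sim$drug, file.path(dir, "drug.txt"), delim = "$")
  readr::write_delim(sim$reac, file.path(dir, "reac.txt"), delim = "$")
  write_lexicon(sim$lexicon, file.path(dir, "lexicon.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "ground_truth.tsv"))
  cfg <- sim$config
  cfg$name_variants <- as.list(cfg$name_variants)
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate per-drug 2x2 contingency tables directly at the count level
#'
#' Count-level shortcut for calibration runs: instead of materializing
#' reports, draws each drug-event pair's table from the marginal distribution
#' the report-level model implies. The exposed-report count is binomial in
#' `n_reports`; the event counts among exposed and unexposed reports are
#' binomial with event odds `baseline_event_prob/(1-baseline_event_prob)`
#' multiplied by `planted_or` among the exposed.
#'
#' @param m_pairs Number of independent drug-event pairs.
#' @param n_reports Reports per pair.
#' @param exposure_prob,baseline_event_prob,planted_or As in [sim_config()];
#'   `planted_or` is recycled across pairs.
#' @param seed Integer seed.
#' @return A tibble with columns `ingredient`, `planted_or`, `a`, `b`, `c`,
#'   `d`, one row per pair.
#' @export
simulate_tables <- function(m_pairs, n_reports,
                            exposure_prob = 0.05,
                            baseline_event_prob = 0.05,
                            planted_or = 1,
                            seed = NULL) {
  m_pairs <- chk_count(m_pairs, "m_pairs", min = 1L)
  n_reports <- chk_count(n_reports, "n_reports", min = 1L)
  exposure_prob <- chk_prob(exposure_prob, "exposure_prob")
  baseline_event_prob <- chk_prob(baseline_event_prob, "baseline_event_prob")
  if (!is.numeric(planted_or) || anyNA(planted_or) || any(planted_or <= 0)) {
    abort_validation("`planted_or` must be positive.")
  }
  if (is.null(seed)) abort_validation("`seed` is required.")
  seed <- chk_count(seed, "seed", min = 0L)
  planted_or <- rep_len(as.numeric(planted_or), m_pairs)

  withr::with_seed(seed, {
    n_exp <- stats::rbinom(m_pairs, n_reports, exposure_prob)
    base_odds <- baseline_event_prob / (1 - baseline_event_prob)
    p1 <- base_odds * planted_or / (1 + base_odds * planted_or)
    a <- stats::rbinom(m_pairs, n_exp, p1)
    c <- stats::rbinom(m_pairs, n_reports - n_exp, baseline_event_prob)
    tibble(
      ingredient = sprintf("PAIR_%05d", seq_len(m_pairs)),
      planted_or = planted_or,
      a = a, b = n_exp - a, c = c, d = n_reports - n_exp - c
    )
  })
}
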