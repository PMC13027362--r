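#' Packaged reference screening table for inflammatory bowel disease
#'
#' A packaged table of 73 drugs from a published FAERS-wide inverse-signal
#' screen against the preferred terms "Ulcerative colitis" and "Crohn's
#' disease": each row carries the drug name, its reporting odds ratio and
#' the 95% Woolf confidence bounds, printed to 3 decimals and sorted by
#' ascending ROR. All 73 rows have `ci_high < 1`. Useful as a realistic
#' downstream-funnel input and for consistency checks exploiting the
#' geometric-mean identity of the Woolf interval.
#'
#' @return A tibble with columns `ingredient`, `ror`, `ci_low`, `ci_high`.
#' @examples
#' ibd_candidates() |> restrict_to_classes(ibd_class_map())
#' @export
ibd_candidates <- function() {
  path <- system.file("extdata", "ibd_ror_screen.tsv", package = "rorscreen",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "cddd", progress = FALSE) |>
    dplyr::rename(ingredient = "drug")
}

#' Packaged therapeutic-class map for the reference screening table
#'
#' Annotates each of the 73 reference drugs with a therapeutic class; the
#' designated (immune-mediated/immunomodulatory) labels select the nine
#' candidates prioritized for immune-mediated disease.
#'
#' @return A [class_map()] object.
#' @export
ibd_class_map <- function() {
  read_class_map(system.file("extdata", "ibd_class_map.json",
                             package = "rorscreen", mustWork = TRUE))
}

#' Packaged feasibility configuration for the reference screening table
#'
#' The reference table is already post-feasibility (its 73 rows survived
#' exclusion of non-systemic formulations, diagnostic agents, withdrawn
#' products, pharmacokinetically implausible compounds and drugs with
#' documented lack of efficacy), so the packaged configuration is empty:
#' applying it is the identity. Users screening new raw data supply their
#' own lists.
#'
#' @return A [feasibility_config()] object.
#' @export
ibd_feasibility <- function() {
  read_feasibility_config(system.file("extdata", "ibd_feasibility.json",
                                      package = "rorscreen", mustWork = TRUE))
}

#' Path to a small example drug-name lexicon
#'
#' A toy lexicon mapping a handful of brand names, salt forms and
#' combination products to active ingredients, for examples and tests.
#'
#' @return File path to the packaged TSV (readable with [read_lexicon()]).
#' @export
example_lexicon_path <- function() {
  system.file("extdata", "example_lexicon.tsv", package = "rorscreen",
              mustWork = TRUE)
}
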