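---
title: "Inverse signal screening: model, design choices and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse signal screening: model, design choices and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorscreen)
```

## The case/non-case model

Spontaneous reporting systems collect individual case safety reports
(ICSRs): one patient, one or more drugs, one or more adverse events coded
as MedDRA preferred terms (PTs). A case/non-case analysis treats the
database itself as the study population: for a target event set, *cases*
are reports listing at least one target PT and *non-cases* are all other
reports. For each drug the report-level 2×2 table (a = drug and event,
b = drug only, c = event only, d = neither) yields the reporting odds
ratio ROR = (a·d)/(b·c), the odds-ratio analogue of a case–control study.

Most signal detection looks for ROR > 1. This package screens the other
tail: a statistically robust ROR < 1 — an *inverse signal* — means the
drug is co-reported with the disease less often than co-reporting patterns
would predict, which can be a hypothesis-generating hint of a protective or
disease-modifying association and hence a repurposing lead. It is only a
hint: prescribing channels, comorbidity structure and reporting behavior
all move the same statistic (see Limitations).

Inference uses the Woolf construction: the log-ROR standard error is
`sqrt(1/a + 1/b + 1/c + 1/d)` and the confidence interval is
`exp(log(ROR) ± z·SE)` with `z` the full-precision two-sided normal
quantile (1.959964 at 95%, not 1.96 — the difference is below output
rounding). The bounds are geometrically symmetric about the estimate, so
`sqrt(low·high)` recovers it to machine precision; the package exploits
this identity both as an invariant test and as a consistency check on
printed tables whose underlying counts are unavailable.

## Thresholds and their defaults

* `min_cases = 40`: a drug enters the tested family only with at least 40
  drug-with-event reports. Conventional safety signalling often uses 3–5;
  inverse signals are more fragile under small counts (a handful of
  missing co-reports can manufacture an apparent deficit), so the default
  trades sensitivity for estimate stability. With `a ≥ 40` no cell of a
  tested table is zero in practice.
* `alpha = 0.05` on the Benjamini–Hochberg adjusted p-value, computed by
  default across the post-threshold family (*filter-then-adjust*). The
  alternative order — adjust across all drugs, then filter — is available
  via `screen_config(adjust = "adjust_then_filter")`; which order a given
  published screen used is rarely stated, so both are first-class.
* Raw p-values default to the two-sided Fisher exact test (point
  probability rule, the convention implemented by `stats::fisher.test`);
  a Pearson chi-square without continuity correction is available via
  `p_method = "chisq"`. Published disproportionality screens frequently
  leave the raw test unnamed; the default is the exact test because the
  tested family always contains moderate counts where the two agree
  closely, and exactness costs little at family sizes in the thousands.
* `strict_ci = FALSE`: the default inverse flag is point estimate < 1 and
  adjusted p < alpha. The stricter variant additionally requires the upper
  confidence bound below 1; it exists because interval-significant
  candidate sets are common in published tables (all 73 rows of the
  packaged reference table satisfy it).
* Zero cells: if any cell of a table is zero, 0.5 is added to all four
  cells (Haldane–Anscombe) for the ROR and its interval only — never for
  the exact p-value, which always uses raw counts. The correction is also
  applied when `a = 0` (not only b, c, d), since otherwise the estimate is
  0 with an undefined interval; corrected rows carry `corrected_flag` in
  the output. Under the default `min_cases` the correction never fires for
  tested drugs.

## Ingest: deduplication and name normalization

FAERS-style extracts carry multiple versions of the same case; the
definitive record is the highest `case_version` per `case_id`. Ties on
version should not occur in well-formed data, but the implementation
breaks them deterministically (lexicographically greatest `report_id`) so
reruns are byte-stable. Every removal is counted, and the audit reconciles
exactly: reports in = reports kept + versions removed.

Verbatim drug names are resolved against a declarative lexicon after key
normalization: uppercase, punctuation to spaces, whitespace collapsed,
trailing dosage/formulation tokens stripped (digits with MG/MCG/G/ML/IU
units, TABLET/CAPSULE/INJECTION and similar). Combination products map to
all constituents; within a report, ingredients form a set and role codes
(PS/SS/C/I) are unioned. The analysis is deliberately role-agnostic: a
potentially protective drug is unlikely to be labelled "suspect" in a
report about the disease it protects against, so restricting to suspect
drugs would bias exactly the signals being sought.

A mention whose key is missing from the lexicon, or mapped to
`UNRESOLVABLE`, is dropped (the two are counted separately); the report
itself is dropped only when *no* resolvable mention remains. Published
method descriptions are ambiguous between mention-level and report-level
exclusion; the mention-level choice was made here to preserve the
background report universe, and the audit makes the consequence of either
choice visible.

## The synthetic reporting system

`simulate_reports()` generates ICSRs with known ground truth. Each case is
exposed to each drug independently with probability `exposure_prob`; the
target-event odds are the baseline odds times the product of `planted_or`
over the case's exposures (effects multiply on the odds scale, so the
marginal report-level ROR of each drug estimates its planted value —
which is what makes recovery testable). On top of the clean model the
generator layers the mess the ingest stage exists for: verbatim name
variants (brand, dosage-suffixed, lower-case salt forms), combination
products that replace their constituents' mentions whenever all
constituents are exposed, superseded duplicate case versions
(`duplicate_fraction`), noise PTs from a vocabulary disjoint from any
target term, and uniformly random role codes (the analysis ignores roles,
so they only exercise plumbing).

Every case also reports one background co-medication from a small
`COMED` vocabulary. Real reports are never drug-free — there is always
concomitant therapy — and without this the unexposed stratum would vanish
at normalization and the c/d cells could not be recovered. With it, the
pipeline reproduces the generator's realized 2×2 cells *exactly*, an
integer-equality invariant in the test suite.

What the generator does **not** emulate: demographic covariates, reporting
dates and time-to-onset, country/reporter effects, channeling or
indication bias, correlated co-prescription, cross-manufacturer duplicate
cases (only superseded versions are modelled), and misspellings beyond the
configured variant lists. Passing tests therefore demonstrate that the
pipeline is correct *under the stated generative model* — they say nothing
about whether a real inverse signal is causal, which no disproportionality
method can establish.

Determinism: all generation flows through a single integer seed; identical
configurations produce byte-identical files.

## Calibration studies

`simulate_tables()` is a count-level shortcut drawing each drug's 2×2
table from the marginal distribution the report model implies (binomial
exposure count; binomial event counts at baseline odds, multiplied by the
planted odds ratio among the exposed). It exists for speed in replicated
studies; a test compares its mean log-ROR against the full report-level
path at matched parameters to guard against drift between the two.

* `null_fdr_study()` — all planted odds ratios 1; the flagged fraction
  must stay at or below alpha. Run at 2,000 pairs × 20 replicates with
  20,000 reports per pair, tolerances computed from the replicate spread
  (never hard-coded margins).
* `coverage_study()` — fraction of Woolf intervals covering a planted
  odds ratio of 0.3 over 1,000 replicate tables, with all expected cells
  above 50 so the normal approximation should be in its asymptotic regime;
  the acceptance band is 93–97%. The report also carries the minimum
  expected cell so degraded small-sample scenarios are surfaced, not
  asserted away.
* `recovery_study()` — a grid of planted odds ratios; per grid point, the
  mean estimate, log-scale bias, coverage and inverse-flag rate. The
  headline scenario plants 0.056 — the strongest inverse magnitude in the
  packaged reference table — at 200,000 reports and checks mean recovery
  within 10% with a flag rate above 90% over 100 replicates.

The calibration scenarios use exposure probability 0.05 and baseline event
probability 0.1. The baseline is higher than a single rare disease's share
of a real database; it was chosen once, by power analysis before any test
was run, so that the expected drug-with-event count (about 62 at planted
OR 0.056 and 200,000 reports) clears the 40-case floor — otherwise the
case threshold, not the statistic, would dominate the operating
characteristics being measured. The single-drug decision rule used inside
the recovery study is tested for exact agreement with the full screen on a
family of one.

## The candidate funnel

Post-statistical selection — feasibility and therapeutic class — is
clinical judgment, not computation. The package represents it as
declarative, versioned configuration: ordered exclusion-list categories
(non-systemic, diagnostic, withdrawn, pharmacokinetically implausible,
documented lack of efficacy/disease-aggravating) with the first matching
category recorded as the exclusion reason, and a class map with a
designated label set. Every stage logs entering and surviving counts that
must reconcile exactly, stages preserve ascending-ROR order (ties broken
by name), and empty configurations are identities.

The packaged reference table carries 73 interval-significant inverse
candidates from a published FAERS-wide IBD screen (drug, ROR, 95% bounds,
3 decimals); it is already post-feasibility, so the packaged feasibility
configuration is empty. The packaged class map annotates all 73 with
standard therapeutic classes; its designated immune-mediated labels select
the nine drugs prioritized in that screen. The per-stage membership of the
original funnel between its initial 3,585 drug–event combinations and the
73 survivors is not public; the packaged configurations guarantee the
endpoint counts (73, then 9), not intermediate ones. Only the endpoint
table itself is shipped — the other drugs' class assignments here are
ordinary pharmacology, made so the designated set reproduces the published
nine.

## Numerical and interface choices

* Exported tables round ROR and bounds half-up to 3 decimals (matching
  the precision of published candidate tables); p-values keep full
  precision. All internal computation is double precision.
* The forest export adds `log_mid = sqrt(ci_low·ci_high)`, the midpoint on
  a log axis, computed from the rounded bounds so a re-parsed file is
  self-consistent.
* Degenerate exact-test margins (an empty row or column) give p = 1, the
  single-possible-table case.
* Problem sizes in the test suite (for example 30 replicates of the
  200,000-report generative check, exhaustive exact-test sweeps to table
  totals of 17 plus 1,500 random tables to 200) were chosen to keep the
  default run in the low minutes while leaving Monte-Carlo bands at 3
  standard errors.

## Limitations

Inverse disproportionality is associative. Underreporting, confounding by
indication, channeling, co-medication distortion and demographic reporting
structure can all produce ROR < 1 without any protective pharmacology, and
report-level data carry no exposure denominators or temporal anchors to
adjust for them. The package's outputs are ranked hypotheses with audit
trails — inputs to mechanistic and epidemiological follow-up, not evidence
of efficacy.
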