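# rorscreen

Inverse pharmacovigilance signal screening for drug repurposing.

Spontaneous adverse-event databases such as FAERS are usually mined for
*positive* safety signals — drug–event pairs reported more often than
expected. `rorscreen` turns the same case/non-case machinery around: it
screens for **inverse signals**, drugs co-reported with a disease *less*
often than expected, as hypothesis-generating hints of protective or
disease-modifying associations worth repurposing follow-up. The packaged
reference data target inflammatory bowel disease (IBD; MedDRA preferred
terms "Ulcerative colitis" and "Crohn's disease"), but every stage is
configuration-driven and works for any event set.

It is written for pharmacoepidemiologists and computational drug-repurposing
researchers who want the whole pipeline — raw report tables to ranked
candidate list — as tested, reproducible code rather than a point-and-click
query.

## The statistic

For each drug, reports are cross-classified at the report level:

|                | event         | no event |
|----------------|---------------|----------|
| **drug**       | a             | b        |
| **no drug**    | c             | d        |

* Reporting odds ratio: `ROR = (a·d)/(b·c)`; values below 1 indicate the
  drug–event pair is under-reported relative to expectation.
* Woolf confidence interval:
  `exp(log ROR ± z · sqrt(1/a + 1/b + 1/c + 1/d))`; its bounds are
  geometrically symmetric, so `sqrt(low · high)` recovers the point
  estimate.
* Raw p-values are two-sided Fisher exact (Pearson chi-square available),
  adjusted across the tested family by Benjamini–Hochberg.
* A drug is an inverse signal when `ROR < 1`, adjusted `p < 0.05`, and it
  has at least 40 drug-with-event reports (a conservative floor against
  small-count instability).

Around the statistic sit the standard FAERS chores, each audited: case-version
deduplication, lexicon-based normalization of verbatim drug names (brands,
salts, dosage suffixes, combination products), and a staged candidate funnel
(feasibility exclusion lists, therapeutic-class restriction) with exact count
conservation at every stage. A synthetic report generator with *planted*
odds ratios makes every stage testable without downloading anything, and
calibration studies measure the procedure's false-flag rate, confidence
interval coverage and parameter recovery.

## Worked example

Simulate 20,000 reports with one planted inverse drug (odds ratio 0.2) and
two null drugs, write them as FAERS-dialect files, and run the full screen:

```r
library(rorscreen)

sim <- simulate_reports(sim_config(
  n_cases = 20000, planted_or = c(0.2, 1, 1), exposure_prob = 0.2,
  baseline_event_prob = 0.1, duplicate_fraction = 0.1, seed = 42
))
dir <- tempfile()
write_faers_tables(sim, dir)

screen <- read_faers_tables(dir) |>
  deduplicate_cases() |>
  normalize_drugs(read_lexicon(file.path(dir, "lexicon.tsv"))) |>
  build_contingency_tables() |>
  screen_signals(screen_config())

glance(screen)
#>   n_tested n_inverse n_positive min_cases alpha ci_level p_method n_reports
#> 1       23         1          0        40  0.05     0.95 fisher       20000

head(tidy(screen)[c("ingredient", "a", "ror", "ci_low", "ci_high", "p_adj", "inverse_flag")], 4)
#>   ingredient     a   ror ci_low ci_high    p_adj inverse_flag
#> 1 SIMDRUG001   100 0.233  0.190   0.286 2.48e-63 TRUE
#> 2 COMED013      67 0.807  0.626   1.04  6.22e- 1 FALSE
#> 3 COMED002      72 0.840  0.657   1.07  6.82e- 1 FALSE
#> 4 COMED020      76 0.858  0.676   1.09  7.02e- 1 FALSE
```

The planted drug is recovered (estimate 0.233, interval covering 0.2,
flagged), while the null co-medications scatter around 1 and stay unflagged.
23 drugs reached the 40-case floor; one is an inverse signal.

The packaged 73-drug IBD reference table runs through the candidate funnel
the same way:

```r
nine <- ibd_candidates() |>
  restrict_to_classes(ibd_class_map()) |>
  rank_candidates()
nine[c("ingredient", "ror", "ci_low", "ci_high", "class")]
#>   ingredient           ror ci_low ci_high class
#> 1 Lenalidomide       0.056  0.043   0.073 immunomodulatory imide
#> 2 Dupilumab          0.213  0.185   0.245 monoclonal antibody immunotherapy
#> 3 Cyclophosphamide   0.215  0.175   0.265 cytotoxic immunosuppressant
#> 4 Fingolimod         0.261  0.205   0.334 sphingosine-1-phosphate modulator
#> 5 Dimethyl fumarate  0.332  0.275   0.400 fumarate immunomodulator
#> 6 Apremilast         0.357  0.296   0.431 PDE4 inhibitor immunomodulator
#> 7 Imatinib           0.423  0.339   0.527 tyrosine kinase inhibitor
#> 8 Glatiramer acetate 0.446  0.352   0.565 peptide copolymer immunomodulator
#> 9 Interferon beta-1a 0.594  0.533   0.662 interferon immunomodulator
plot_forest(nine)   # forest plot on a log axis, reference line at ROR = 1
```

The nine drugs with designated immune-mediated class labels survive, led by
lenalidomide (strongest inverse association, ROR 0.056).

A thin command-line wrapper (`inst/cli/rorscreen.R`) exposes
`simulate` / `screen` / `calibrate` / `fixtures` subcommands over the same
functions, writing every run's resolved configuration next to its outputs.

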