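# Independent oracles used to check the package implementations.

# Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min over j >= i of min(1, p_(j) * m / j), returned in input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) min(1, p[ord[j]] * m / j), numeric(1))
    q_sorted[i] <- min(cand)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Two-sided Fisher exact p by full hypergeometric enumeration with fixed
# margins; tables with point probability <= observed (within relative
# tolerance 1e-7) are summed.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(k, r1, r2, c1)
  p_obs <- probs[k == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Enumerate all 2x2 tables (a, b, c, d) with total N.
all_tables_with_total <- function(N) {
  out <- list()
  i <- 1L
  for (a in 0:N) for (b in 0:(N - a)) for (c in 0:(N - a - b)) {
    out[[i]] <- c(a, b, c, N - a - b - c)
    i <- i + 1L
  }
  do.call(rbind, out)
}

# A small handmade dataset exercising duplicates, variants, combos and
# unresolvable names, written as FAERS-dialect files. Returns the directory.
write_toy_dataset <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c(
    "report_id$case_id$case_version",
    "R1$CASE1$1",
    "R2$CASE1$2",    # definitive version of CASE1
    "R3$CASE2$1",
    "R4$CASE3$1",
    "R5$CASE4$1"
  ), file.path(dir, "demo.txt"))
  writeLines(c(
    "report_id$drug_seq$role_code$verbatim_name",
    "R1$1$PS$Lipitor 20mg",
    "R2$1$PS$Lipitor 20mg Tablet",
    "R2$2$C$Augmentin",
    "R2$3$SS$amoxicillin",
    "R3$1$PS$HUMIRA",
    "R4$1$C$Unknown Herbal Blend",
    "R4$2$PS$Atorvastatin Calcium",
    "R5$1$PS$Completely Novel Compound",
    "R9$1$PS$Orphan Drug Row"
  ), file.path(dir, "drug.txt"))
  writeLines(c(
    "report_id$pt",
    "R1$Crohn's disease",
    "R2$Ulcerative colitis",
    "R2$PT_0001",
    "R3$ ulcerative COLITIS ",
    "R4$PT_0002",
    "R5$Crohn's disease",
    "R9$PT_0003"
  ), file.path(dir, "reac.txt"))
  dir
}

toy_lexicon <- function() {
  rorscreen::read_lexicon(rorscreen::example_lexicon_path())
}
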