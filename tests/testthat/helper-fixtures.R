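suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# One valid variant row; override any field.
make_variants <- function(n = 1, ...) {
  base <- tibble(
    chrom = "chr1", pos = seq_len(n) * 100, ref = "A", alt = "T",
    gene = sprintf("G%03d", seq_len(n)), vaf = 0.30, alt_reads = NA_real_,
    tumor_depth = 100, normal_depth = 60, impact = "moderate",
    cmc_annotated = FALSE, in_gnomad = FALSE, kind = "SNV"
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base$alt_reads <- ifelse(is.na(base$alt_reads),
                           round(base$vaf * base$tumor_depth), base$alt_reads)
  base$impact <- classify_impact(base$impact)
  base
}

# Independent AUC oracle: brute-force pair concordance with ties counting 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Independent Youden oracle: exhaustive scan over candidate thresholds with
# the rule "positive iff score > t"; ties broken toward the smallest t.
brute_youden <- function(scores, labels) {
  cand <- c(sort(unique(scores)), -Inf)
  j <- sapply(cand, function(t) {
    sens <- mean(scores[labels] > t)
    spec <- mean(scores[!labels] <= t)
    sens + spec - 1
  })
  min(cand[j >= max(j) - 1e-12])
}

# Independent Cox oracle: Breslow partial log-likelihood for a binary
# covariate, maximized by grid search.
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

grid_cox_beta <- function(time, event, x) {
  coarse <- seq(-3, 3, by = 0.01)
  b0 <- coarse[which.max(sapply(coarse, breslow_loglik, time, event, x))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  fine[which.max(sapply(fine, breslow_loglik, time, event, x))]
}

# Cohort realizing a printed 4-stratum responder table: counts are
# c(non_responders, responders) for (tcr, tmb) in (low,low), (high,low),
# (low,high), (high,high); values placed around the cutoffs.
strata_cohort <- function(counts, tmb_cutoff = 10, tcr_cutoff = 1) {
  strata <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  rows <- list()
  for (s in seq_along(strata)) {
    hi <- strata[[s]]
    for (k in 1:2) {
      n <- counts[[s]][k]
      if (n == 0) next
      rows[[length(rows) + 1]] <- tibble(
        tcr_entropy = if (hi[1] == 1) tcr_cutoff + 0.5 else tcr_cutoff - 0.5,
        tmb = if (hi[2] == 1) tmb_cutoff + 5 else tmb_cutoff - 5,
        outcome = rep(if (k == 1) "non_responder" else "responder", n)
      )
    }
  }
  bind_rows(rows)
}

# Biomarker specs for the simulation-based checks: a global null and a
# planted-effect recovery design (strong TMB, moderate entropy shift).
null_biomarker_spec <- function(prev = 0.15) {
  sim_biomarker_spec() %>%
    mutate(shift = ifelse(is.na(shift), NA, 0),
           prev_responder = ifelse(is.na(prev_responder), NA, prev),
           prev_nonresponder = ifelse(is.na(prev_nonresponder), NA, prev))
}

recovery_biomarker_spec <- function() {
  null_biomarker_spec() %>%
    mutate(shift = case_when(biomarker == "tmb" ~ 2.0,
                             biomarker == "tcr_entropy" ~ 1.0,
                             TRUE ~ shift))
}
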