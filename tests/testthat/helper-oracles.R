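# Independent brute-force oracles, deliberately written without reusing any
# package internals, plus small fixture builders shared across test files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# --- fixtures -----------------------------------------------------------

# Tiny two-chromosome genome for per-basepair oracle checks.
toyGenome <- function() {
  armsGr <- GRanges(c("chrA", "chrA", "chrB", "chrB"),
                    IRanges(start = c(1, 1201, 1, 1001),
                            end = c(1000, 2600, 800, 3000)),
                    arm = c("Ap", "Aq", "Bp", "Bq"))
  lc <- GRanges("chrA", IRanges(1501, 1520))
  names(lc) <- "MYC"
  GenomeModel(armsGr, lc, genome = "toy")
}

# Profile with given (chrom, start, end, log2) rows.
mkProfile <- function(id, chrom, start, end, log2) {
  CNProfile(id, GRanges(chrom, IRanges(start, end), log2 = log2))
}

# A fresh truth table of n random WCA/amp/i17q combinations.
randomTruth <- function(n, seed) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    chr7_gain = sample(c(TRUE, FALSE), n, TRUE),
    chr8_loss = sample(c(TRUE, FALSE), n, TRUE),
    chr11_loss = sample(c(TRUE, FALSE), n, TRUE),
    i17q = sample(c(TRUE, FALSE), n, TRUE),
    myc_amp = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.2, 0.8)),
    mycn_amp = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.2, 0.8)))
}

# Small analysis table drawn from the generator defaults.
smallAnalysisTable <- function(n = 300, seed = 42, ...) {
  cfg <- cohortConfig(n_patients = n, seed = seed, ...)
  sim <- generateCohort(cfg)
  calls <- callCohort(renderProfiles(sim$truth, cfg))
  strata <- stratifyCohort(sim$patients, sim$labels, calls)
  assembleAnalysisTable(sim$patients, sim$labels, calls, strata)
}

# --- oracles ------------------------------------------------------------

# Per-basepair gain/loss fractions of one arm: walk every base the profile
# covers inside the arm and count.
bpArmFractions <- function(profile, armGr, baseline, arm_log2) {
  b <- profileBins(profile)
  b <- b[as.character(seqnames(b)) == as.character(seqnames(armGr))]
  gain <- 0; loss <- 0; covered <- 0
  for (i in seq_along(b)) {
    for (pos in seq(start(b)[i], end(b)[i])) {
      if (pos >= start(armGr) && pos <= end(armGr)) {
        covered <- covered + 1
        dev <- b$log2[i] - baseline
        if (dev >= arm_log2) gain <- gain + 1
        if (dev <= -arm_log2) loss <- loss + 1
      }
    }
  }
  c(gain = gain / covered, loss = loss / covered)
}

# Graf IPCW Brier score by direct per-subject enumeration.
bruteBrier <- function(S, time, event, grid) {
  kmCens <- function(t) {
    # Kaplan-Meier of the censoring distribution, evaluated at t (right cont.)
    ut <- sort(unique(time))
    surv <- 1
    for (u in ut[ut <= t]) {
      atrisk <- sum(time >= u)
      d <- sum(time == u & !event)
      surv <- surv * (1 - d / atrisk)
    }
    surv
  }
  kmCensMinus <- function(t) {
    ut <- sort(unique(time))
    surv <- 1
    for (u in ut[ut < t]) {
      atrisk <- sum(time >= u)
      d <- sum(time == u & !event)
      surv <- surv * (1 - d / atrisk)
    }
    surv
  }
  vapply(seq_along(grid), function(k) {
    t <- grid[k]
    total <- 0
    for (i in seq_along(time)) {
      if (time[i] <= t && event[i]) {
        total <- total + S[i, k]^2 / kmCensMinus(time[i])
      } else if (time[i] > t) {
        total <- total + (1 - S[i, k])^2 / kmCens(t)
      }
    }
    total / length(time)
  }, numeric(1))
}

# Incident/dynamic AUC by exhaustive case/control pair counting.
brutePairAUC <- function(lp, start, stop, event, horizon) {
  et <- sort(unique(stop[event & stop <= horizon]))
  auc <- numeric(length(et)); nev <- integer(length(et))
  for (k in seq_along(et)) {
    t <- et[k]
    cases <- which(start < t & stop == t & event)
    ctrls <- which(start < t & stop >= t &
                     !(event & stop == t))
    nev[k] <- length(cases)
    tot <- 0; np <- 0
    for (i in cases) for (j in ctrls) {
      np <- np + 1
      tot <- tot + if (lp[i] > lp[j]) 1 else if (lp[i] == lp[j]) 0.5 else 0
    }
    auc[k] <- tot / np
  }
  list(times = et, auc = auc, iauc = sum(auc * nev) / sum(nev))
}

# Cox partial log-likelihood (Breslow risk sets, no ties) for a single
# covariate on time-fixed data.
bruteCoxLoglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    atrisk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[atrisk])))
  }
  ll
}

# Declarative clinical rule table, written as data, independent of the
# package's control flow.
declarativeClinical <- function(age_ge4, m0, r0, nonLCA, noMYC, mycnOK) {
  if (age_ge4 && m0 && r0 && nonLCA && noMYC && mycnOK) "SR" else "HR"
}

declarativeCM <- function(clinical, subgroup, wcaFR) {
  if (clinical == "SR") {
    if (subgroup == "VII" || wcaFR) "LR" else "SR"
  } else {
    if (subgroup %in% c("II", "III", "V")) "VHR" else "HR"
  }
}
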