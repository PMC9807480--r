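# Synthetic cohort generation: clinical covariates, molecular ground truth,
# stratum-calibrated survival, and rendered bin-level copy-number profiles.

# Post-progression exponential rate such that the marginal 5-year OS of
# T_os = T_pfs + Exp(rate) hits the target.  T_pfs ~ Exp(l1); the sum is
# hypoexponential with S(t) = (l2 e^{-l1 t} - l1 e^{-l2 t}) / (l2 - l1).
# When the OS target does not exceed the PFS target the delay is zero
# (death at progression).
.postProgressionRate <- function(l1, s_os5, t = 5) {
  s_pfs5 <- exp(-l1 * t)
  if (s_os5 <= s_pfs5 + 1e-9) return(Inf)
  f <- function(log_l2) {
    l2 <- exp(log_l2)
    if (abs(l2 - l1) < 1e-10) l2 <- l1 * (1 + 1e-6)
    (l2 * exp(-l1 * t) - l1 * exp(-l2 * t)) / (l2 - l1) - s_os5
  }
  exp(stats::uniroot(f, c(-12, 10), tol = 1e-12)$root)
}

#' Generate a synthetic cohort
#'
#' Draws subgroup labels, clinical covariates, molecular ground truth
#' (whole-chromosomal aberrations, MYC/MYCN amplification, i17q), classifier
#' scores, and survival outcomes.  The true clinico-molecular stratum is
#' derived from the generated covariates with the package's own rule set and
#' drives stratum-specific exponential progression hazards calibrated so that
#' S(5) equals the configured 5-year PFS target; death time is progression
#' time plus an exponential post-progression delay calibrated to the OS
#' target.  Censoring is independent: a \code{censor_rate} fraction get a
#' uniform censoring time on (0, followup_max), the rest are administratively
#' censored at followup_max.  Radiotherapy start times are assigned only to
#' primary-CSI patients (age >= 4), plus a salvage fraction of infant-type
#' patients.  Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{cohortConfig}}
#' @return list with data.frames \code{patients} (clinical table),
#'   \code{labels} (group/subgroup and classifier scores), and \code{truth}
#'   (planted molecular aberrations, true strata, uncensored times), plus the
#'   \code{config}
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "cohortConfig"))
  set.seed(config$seed)
  n <- config$n_patients
  sg <- sample(.SUBGROUPS, n, replace = TRUE, prob = config$subgroup_freqs)
  group <- ifelse(stats::rbinom(n, 1L, config$group4_prob_by_subgroup[sg]) == 1L,
                  "Group4", "Group3")
  m_stage <- ifelse(stats::rbinom(n, 1L, config$m_plus_rate_by_subgroup[sg]) == 1L,
                    "M+", "M0")
  resection <- ifelse(stats::rbinom(n, 1L, config$r_plus_rate) == 1L, "R+", "R0")
  histology <- sample(c("LCA", "DMB", "CMB"), n, replace = TRUE,
                      prob = c(config$lca_rate, config$dmb_rate,
                               1 - config$lca_rate - config$dmb_rate))
  lt4 <- stats::rbinom(n, 1L, config$age_lt4_rate) == 1L
  age <- ifelse(lt4, stats::runif(n, 0.5, config$age_cut),
                stats::runif(n, config$age_cut, 18))
  myc <- stats::rbinom(n, 1L, config$myc_amp_rate_by_subgroup[sg]) == 1L
  mycn <- stats::rbinom(n, 1L, config$mycn_amp_rate_by_subgroup[sg]) == 1L
  wr <- config$wca_truth_rates_by_subgroup[sg]
  chr7 <- stats::rbinom(n, 1L, wr) == 1L
  chr8 <- stats::rbinom(n, 1L, wr) == 1L
  chr11 <- stats::rbinom(n, 1L, wr) == 1L
  i17q <- stats::rbinom(n, 1L, config$i17q_rate) == 1L
  wca_count <- as.integer(chr7) + as.integer(chr8) + as.integer(chr11)
  wca_phen <- ifelse(wca_count >= 2L, "FR", "SR")

  clin <- classifyClinical(age, m_stage, resection, histology, myc, mycn,
                           group, config$age_cut)
  cm <- classifyCM(clin, sg, wca_phen)

  l1 <- -log(config$surv5_pfs_by_stratum) / 5
  lpp <- vapply(names(l1), function(s)
    .postProgressionRate(l1[[s]], config$surv5_os_by_stratum[[s]]), numeric(1))
  t_pfs <- stats::rexp(n, l1[cm])
  delay <- ifelse(is.infinite(lpp[cm]), 0, stats::rexp(n, pmin(lpp[cm], 1e9)))
  delay[is.infinite(lpp[cm])] <- 0
  t_os <- t_pfs + delay
  early <- stats::rbinom(n, 1L, config$censor_rate) == 1L
  cens <- ifelse(early, stats::runif(n, 0, config$followup_max_years),
                 config$followup_max_years)
  pfs_years <- pmin(t_pfs, cens)
  os_years <- pmin(t_os, cens)
  pfs_event <- t_pfs <= cens
  os_event <- t_os <= cens

  therapy <- ifelse(age < config$age_cut, "infant_type", "primary_CSI")
  salvage <- therapy == "infant_type" & stats::rbinom(n, 1L, config$rt_salvage_rate) == 1L
  rt_start <- ifelse(therapy == "primary_CSI", config$rt_start_years, NA_real_)
  rt_start[salvage] <- stats::runif(sum(salvage), 0.5, 3)

  mcf_score <- stats::runif(n, 0.92, 1)
  group_score <- stats::runif(n, 0.85, 1)
  subgroup_score <- stats::runif(n, 0.85, 1)
  inel <- stats::rbinom(n, 1L, config$ineligible_rate) == 1L
  subgroup_score[inel] <- stats::runif(sum(inel), 0.4, 0.79)

  id <- sprintf("P%04d", seq_len(n))
  patients <- data.frame(patient_id = id, age_years = age, m_stage = m_stage,
    resection = resection, histology = histology, therapy = therapy,
    rt_start_years = rt_start, pfs_years = pfs_years, os_years = os_years,
    pfs_event = pfs_event, os_event = os_event, stringsAsFactors = FALSE)
  labels <- data.frame(patient_id = id, group = group, subgroup = sg,
    mcf_score = mcf_score, group_score = group_score,
    subgroup_score = subgroup_score, stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = id, subgroup = sg, group = group,
    chr7_gain = chr7, chr8_loss = chr8, chr11_loss = chr11,
    wca_count = wca_count, wca_phenotype = wca_phen, i17q = i17q,
    myc_amp = myc, mycn_amp = mycn, clinical_stratum = clin, cm_stratum = cm,
    event_time = t_pfs, death_time = t_os, censor_time = cens,
    stringsAsFactors = FALSE)
  list(patients = patients, labels = labels, truth = truth, config = config)
}

.effectColumns <- function(bins, genome) {
  list(chr7 = which(bins$arm %in% c("7p", "7q")),
       chr8 = which(bins$arm %in% c("8p", "8q")),
       chr11 = which(bins$arm %in% c("11p", "11q")),
       p17 = which(bins$arm == "17p"),
       q17 = which(bins$arm == "17q"),
       myc = queryHits(findOverlaps(bins, loci(genome)["MYC"])),
       mycn = queryHits(findOverlaps(bins, loci(genome)["MYCN"])))
}

#' Render a cohort's ground truth as binned copy-number profiles
#'
#' Bins tile each arm at \code{bin_size_bp}.  Bins inside a planted
#' aberration are shifted by the configured effect (gain +0.35, loss -0.35,
#' amplification +1.0 at the locus by default); neutral bins are centered at
#' 0; i.i.d. Gaussian noise of SD \code{noise_sd} is added throughout.
#'
#' @param truth data.frame from \code{\link{generateCohort}} (needs the
#'   logical aberration columns and \code{patient_id})
#' @param config a \code{\link{cohortConfig}}
#' @param genome a \linkS4class{GenomeModel}
#' @param seed RNG seed for the noise (defaults to \code{config$seed + 1})
#' @return RangedSummarizedExperiment, bins x samples, assay \code{"log2"}
#' @export
renderProfiles <- function(truth, config = cohortConfig(),
                           genome = hg19ArmModel(), seed = NULL) {
  bins <- binGenome(genome, config$bin_size_bp)
  n <- nrow(truth)
  X <- matrix(0, nrow = length(bins), ncol = n)
  ix <- .effectColumns(bins, genome)
  add <- function(rows, cols, eff) {
    if (length(rows) && any(cols)) X[rows, cols] <<- X[rows, cols] + eff
  }
  add(ix$chr7, truth$chr7_gain, config$gain_effect)
  add(ix$chr8, truth$chr8_loss, config$loss_effect)
  add(ix$chr11, truth$chr11_loss, config$loss_effect)
  if (!is.null(truth$i17q)) {
    add(ix$p17, truth$i17q, config$loss_effect)
    add(ix$q17, truth$i17q, config$gain_effect)
  }
  add(ix$myc, truth$myc_amp, config$amp_effect)
  add(ix$mycn, truth$mycn_amp, config$amp_effect)
  if (config$noise_sd > 0) {
    set.seed(if (is.null(seed)) (config$seed %% .Machine$integer.max) + 1L else seed)
    X <- X + stats::rnorm(length(X), 0, config$noise_sd)
  }
  colnames(X) <- truth$patient_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = X), rowRanges = bins)
  S4Vectors::metadata(se)$config_seed <- config$seed
  se
}

#' Render one patient's profile
#'
#' Single-sample convenience wrapper around the same effect model as
#' \code{\link{renderProfiles}}; with \code{noise_sd = 0} the output is the
#' exact noise-free expectation.
#'
#' @param truth_row one-row data.frame with the aberration flags
#' @param config a \code{\link{cohortConfig}}
#' @param genome a \linkS4class{GenomeModel}
#' @param seed optional RNG seed for the noise
#' @return a \linkS4class{CNProfile}
#' @export
renderProfile <- function(truth_row, config = cohortConfig(),
                          genome = hg19ArmModel(), seed = NULL) {
  stopifnot(nrow(truth_row) == 1L)
  se <- renderProfiles(truth_row, config, genome, seed = seed)
  profileFromSE(se, 1L)
}
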