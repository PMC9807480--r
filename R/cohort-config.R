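# Synthetic cohort configuration.
#
# Defaults are calibrated to the published cohort structure of Group 3/4
# medulloblastoma: subgroup frequencies and clinical covariate margins from
# the combined discovery cohort tables, subgroup-conditional metastasis and
# MYC/MYCN rates anchored at the printed values, and stratum-specific 5-year
# survival targets from the reported clinico-molecular strata.

.default_subgroup_freqs <- c(I = 7, II = 34, III = 40, IV = 29, V = 26,
                             VI = 33, VII = 42, VIII = 83) / 294

.default_m_plus <- c(I = 0.60, II = 0.70, III = 0.725, IV = 0.483,
                     V = 0.808, VI = 0.65, VII = 0.62, VIII = 0.68)

.default_myc <- c(I = 0.01, II = 0.25, III = 0.35, IV = 0.01, V = 0.01,
                  VI = 0.01, VII = 0.01, VIII = 0.01)

.default_mycn <- c(I = 0.01, II = 0.01, III = 0.01, IV = 0.01, V = 0.35,
                   VI = 0.20, VII = 0.01, VIII = 0.01)

.default_wca <- c(I = 0.15, II = 0.05, III = 0.05, IV = 0.50, V = 0.15,
                  VI = 0.50, VII = 0.50, VIII = 0.25)

.default_group4_prob <- c(I = 1, II = 0, III = 0, IV = 0, V = 1, VI = 1,
                          VII = 1, VIII = 0.9)

.default_surv5_pfs <- c(LR = 0.94, SR = 0.65, HR = 0.62, VHR = 0.29)
.default_surv5_os  <- c(LR = 0.94, SR = 0.78, HR = 0.72, VHR = 0.35)

#' Configuration for the synthetic cohort generator
#'
#' All probabilities are validated; \code{subgroup_freqs} must sum to 1.
#' Per-subgroup vectors must be named over subgroups I-VIII.  Stratum-level
#' survival targets are 5-year survival probabilities in (0, 1] per
#' clinico-molecular stratum (LR, SR, HR, VHR).
#'
#' @param n_patients cohort size.
#' @param subgroup_freqs probability vector over subgroups I-VIII.
#' @param m_plus_rate_by_subgroup per-subgroup probability of metastatic (M+)
#'   disease.
#' @param r_plus_rate probability of incomplete resection.
#' @param lca_rate,dmb_rate histology probabilities (remainder is classic).
#' @param age_lt4_rate probability of age < 4 years at diagnosis.
#' @param myc_amp_rate_by_subgroup,mycn_amp_rate_by_subgroup per-subgroup
#'   amplification probabilities.
#' @param wca_truth_rates_by_subgroup per-subgroup probability applied
#'   independently to each of the three WCA markers (chr7 gain, chr8 loss,
#'   chr11 loss).
#' @param i17q_rate marginal probability of isochromosome 17q.
#' @param group4_prob_by_subgroup per-subgroup probability of Group 4 (vs
#'   Group 3).
#' @param surv5_pfs_by_stratum,surv5_os_by_stratum target 5-year PFS/OS per
#'   clinico-molecular stratum.
#' @param censor_rate probability that a patient has a uniform early-censoring
#'   time on (0, followup_max_years); others are administratively censored at
#'   \code{followup_max_years}.
#' @param followup_max_years maximum follow-up in years.
#' @param rt_start_years radiotherapy start offset after surgery for
#'   primary-CSI patients.
#' @param rt_salvage_rate fraction of infant-type patients receiving late
#'   (salvage) radiotherapy.
#' @param ineligible_rate fraction of patients whose subgroup score is drawn
#'   below the eligibility threshold.
#' @param bin_size_bp bin width for rendered copy-number profiles.
#' @param noise_sd Gaussian noise SD added to each rendered bin.
#' @param gain_effect,loss_effect,amp_effect mean log2 shifts of rendered
#'   aberrations.
#' @param age_cut clinical age threshold in years.
#' @param seed integer RNG seed.
#' @return list of class \code{cohortConfig}
#' @export
cohortConfig <- function(n_patients = 294L,
                         subgroup_freqs = .default_subgroup_freqs,
                         m_plus_rate_by_subgroup = .default_m_plus,
                         r_plus_rate = 0.12,
                         lca_rate = 0.095, dmb_rate = 0.024,
                         age_lt4_rate = 0.197,
                         myc_amp_rate_by_subgroup = .default_myc,
                         mycn_amp_rate_by_subgroup = .default_mycn,
                         wca_truth_rates_by_subgroup = .default_wca,
                         i17q_rate = 0.63,
                         group4_prob_by_subgroup = .default_group4_prob,
                         surv5_pfs_by_stratum = .default_surv5_pfs,
                         surv5_os_by_stratum = .default_surv5_os,
                         censor_rate = 0.3,
                         followup_max_years = 12,
                         rt_start_years = 0.25,
                         rt_salvage_rate = 0.15,
                         ineligible_rate = 0,
                         bin_size_bp = 1e6,
                         noise_sd = 0.1,
                         gain_effect = 0.35, loss_effect = -0.35,
                         amp_effect = 1.0,
                         age_cut = 4,
                         seed = 1L) {
  cfg <- as.list(environment())
  sg <- .SUBGROUPS
  chk_named <- function(x, what) {
    if (!all(sg %in% names(x))) {
      mbStop(sprintf("cohortConfig: %s must be named over subgroups I-VIII", what))
    }
    x[sg]
  }
  cfg$subgroup_freqs <- chk_named(subgroup_freqs, "subgroup_freqs")
  if (abs(sum(cfg$subgroup_freqs) - 1) > 1e-9) {
    mbStop("cohortConfig: subgroup_freqs must sum to 1")
  }
  cfg$m_plus_rate_by_subgroup <- chk_named(m_plus_rate_by_subgroup, "m_plus_rate_by_subgroup")
  cfg$myc_amp_rate_by_subgroup <- chk_named(myc_amp_rate_by_subgroup, "myc_amp_rate_by_subgroup")
  cfg$mycn_amp_rate_by_subgroup <- chk_named(mycn_amp_rate_by_subgroup, "mycn_amp_rate_by_subgroup")
  cfg$wca_truth_rates_by_subgroup <- chk_named(wca_truth_rates_by_subgroup, "wca_truth_rates_by_subgroup")
  cfg$group4_prob_by_subgroup <- chk_named(group4_prob_by_subgroup, "group4_prob_by_subgroup")
  probs <- c(cfg$subgroup_freqs, cfg$m_plus_rate_by_subgroup, r_plus_rate,
             lca_rate, dmb_rate, age_lt4_rate, cfg$myc_amp_rate_by_subgroup,
             cfg$mycn_amp_rate_by_subgroup, cfg$wca_truth_rates_by_subgroup,
             i17q_rate, cfg$group4_prob_by_subgroup, censor_rate,
             rt_salvage_rate, ineligible_rate)
  if (!isProb(probs)) mbStop("cohortConfig: all rates must be probabilities in [0,1]")
  strata <- c("LR", "SR", "HR", "VHR")
  for (nm in c("surv5_pfs_by_stratum", "surv5_os_by_stratum")) {
    v <- cfg[[nm]]
    if (!all(strata %in% names(v))) mbStop(sprintf("cohortConfig: %s must be named over LR/SR/HR/VHR", nm))
    v <- v[strata]
    if (any(v <= 0 | v > 1)) mbStop(sprintf("cohortConfig: %s must lie in (0, 1]", nm))
    cfg[[nm]] <- v
  }
  if (n_patients < 1) mbStop("cohortConfig: n_patients must be positive")
  if (followup_max_years <= 0 || bin_size_bp < 1 || noise_sd < 0) {
    mbStop("cohortConfig: invalid followup/bin/noise settings")
  }
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "cohortConfig"
  cfg
}

#' @export
print.cohortConfig <- function(x, ...) {
  cat(sprintf("cohortConfig: n=%d, seed=%d, noise_sd=%.3g, bin=%g bp\n",
              x$n_patients, x$seed, x$noise_sd, x$bin_size_bp))
  cat(" subgroup freqs:", paste(sprintf("%s=%.3f", names(x$subgroup_freqs),
                                        x$subgroup_freqs), collapse = " "), "\n")
  cat(" 5y PFS targets:", paste(sprintf("%s=%.2f", names(x$surv5_pfs_by_stratum),
                                        x$surv5_pfs_by_stratum), collapse = " "), "\n")
  invisible(x)
}
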