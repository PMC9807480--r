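# Rule-based clinical and clinico-molecular risk stratification.
#
# Strata spellings are frozen: clinical in {SR, HR}, clinico-molecular in
# {LR, SR, HR, VHR}, plus the sentinel "unclassifiable" for patients whose
# molecular classification scores fail the eligibility thresholds.

#' Eligibility of the molecular classification
#'
#' A sample's class assignment is considered reliable when the methylation
#' class family score reaches 0.9 and both the group and the subgroup scores
#' reach 0.8 (closed comparisons).  Missing scores yield NA, not exclusion.
#'
#' @param mcf_score methylation-class-family score(s) in [0,1]
#' @param group_score Group 3/4 class score(s)
#' @param subgroup_score subgroup I-VIII score(s)
#' @param mcf_min,group_min,subgroup_min thresholds
#' @return logical vector (NA where any score is missing)
#' @export
eligibilityFilter <- function(mcf_score, group_score, subgroup_score,
                              mcf_min = 0.9, group_min = 0.8, subgroup_min = 0.8) {
  mcf_score >= mcf_min & group_score >= group_min & subgroup_score >= subgroup_min
}

.SUBGROUPS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")

#' Clinical risk stratum (SR/HR)
#'
#' Standard risk requires all of: age at diagnosis at least \code{age_cut}
#' years, M0, complete resection (R0, residual < 1.5 cm2), non-anaplastic
#' histology (not LCA; desmoplastic counts as non-anaplastic), no MYC
#' amplification, and no MYCN amplification unless the tumor is Group 4.
#' Any failing condition makes the patient high risk.  Missing inputs
#' propagate to NA.
#'
#' @param age_years age at diagnosis
#' @param m_stage \code{"M0"} or \code{"M+"}
#' @param resection \code{"R0"} or \code{"R+"}
#' @param histology \code{"CMB"}, \code{"DMB"}, or \code{"LCA"}
#' @param myc_amp,mycn_amp logical amplification flags
#' @param group \code{"Group3"} or \code{"Group4"}
#' @param age_cut age threshold in years (default 4)
#' @return character vector \code{"SR"}/\code{"HR"} (NA on missing data)
#' @export
classifyClinical <- function(age_years, m_stage, resection, histology,
                             myc_amp, mycn_amp, group, age_cut = 4) {
  sr <- (age_years >= age_cut) & (m_stage == "M0") & (resection == "R0") &
        (histology != "LCA") & (!myc_amp) & !(mycn_amp & group == "Group3")
  ifelse(is.na(sr), NA_character_, ifelse(sr, "SR", "HR"))
}

#' Clinico-molecular risk stratum (LR/SR/HR/VHR)
#'
#' In a clinical standard-risk background, subgroup VII and/or the WCA
#' favorable-risk phenotype demote to low risk (CM-LR); otherwise CM-SR.  In
#' a clinical high-risk background, subgroups II, III, or V promote to very
#' high risk (CM-VHR); otherwise CM-HR.  Clinical HR can never reach LR and
#' clinical SR can never reach VHR.
#'
#' @param clinical \code{"SR"}/\code{"HR"} from \code{\link{classifyClinical}}
#' @param subgroup subgroup label \code{"I"}..\code{"VIII"}
#' @param wca_phenotype \code{"FR"} or \code{"SR"}
#' @return character vector over \code{"LR"},\code{"SR"},\code{"HR"},\code{"VHR"}
#' @export
classifyCM <- function(clinical, subgroup, wca_phenotype) {
  ok <- !is.na(clinical) & !is.na(subgroup) & !is.na(wca_phenotype)
  out <- rep(NA_character_, length(ok))
  lowrisk <- subgroup == "VII" | wca_phenotype == "FR"
  vhr <- subgroup %in% c("II", "III", "V")
  out[ok & clinical == "SR"] <- ifelse(lowrisk[ok & clinical == "SR"], "LR", "SR")
  out[ok & clinical == "HR"] <- ifelse(vhr[ok & clinical == "HR"], "VHR", "HR")
  out
}

.clinReasons <- function(age_years, m_stage, resection, histology,
                         myc_amp, mycn_amp, group, age_cut = 4) {
  r <- cbind(
    `age<cut` = age_years < age_cut, `M+` = m_stage == "M+",
    `R+` = resection == "R+", LCA = histology == "LCA",
    `MYC amp` = myc_amp, `MYCN amp (Group 3)` = mycn_amp & group == "Group3")
  apply(r, 1L, function(z) paste(colnames(r)[which(z)], collapse = ";"))
}

#' Stratify a cohort
#'
#' Joins the clinical table, molecular labels, and molecular calls by
#' \code{patient_id} and assigns each patient the clinical and the
#' clinico-molecular stratum, with an audit trail of triggered rules.
#' Patients failing the eligibility filter are retained with the sentinel
#' stratum \code{"unclassifiable"} rather than dropped.
#'
#' @param patients data.frame with \code{patient_id}, \code{age_years},
#'   \code{m_stage}, \code{resection}, \code{histology}
#' @param labels data.frame with \code{patient_id}, \code{group},
#'   \code{subgroup}, and scores \code{mcf_score}, \code{group_score},
#'   \code{subgroup_score}
#' @param calls data.frame from \code{\link{callCohort}} (needs
#'   \code{sample_id} or \code{patient_id}, \code{myc_amp}, \code{mycn_amp},
#'   \code{wca_phenotype})
#' @param age_cut age threshold in years (default 4)
#' @return data.frame with \code{patient_id}, \code{eligible},
#'   \code{clinical}, \code{cm}, \code{reasons}
#' @export
stratifyCohort <- function(patients, labels, calls, age_cut = 4) {
  if (!"patient_id" %in% names(calls) && "sample_id" %in% names(calls)) {
    calls$patient_id <- calls$sample_id
  }
  d <- merge(patients, labels, by = "patient_id", sort = FALSE)
  d <- merge(d, calls[, c("patient_id", "myc_amp", "mycn_amp", "wca_phenotype")],
             by = "patient_id", sort = FALSE)
  d <- d[match(patients$patient_id, d$patient_id), ]
  if (nrow(d) != nrow(patients)) {
    mbStop("stratifyCohort: labels/calls do not cover every patient")
  }
  elig <- eligibilityFilter(d$mcf_score, d$group_score, d$subgroup_score)
  clin <- classifyClinical(d$age_years, d$m_stage, d$resection, d$histology,
                           d$myc_amp, d$mycn_amp, d$group, age_cut)
  cm <- classifyCM(clin, d$subgroup, d$wca_phenotype)
  reasons <- .clinReasons(d$age_years, d$m_stage, d$resection, d$histology,
                          d$myc_amp, d$mycn_amp, d$group, age_cut)
  lowrisk <- ifelse(d$subgroup == "VII" & d$wca_phenotype == "FR", "subgroup VII;WCA-FR",
             ifelse(d$subgroup == "VII", "subgroup VII",
             ifelse(d$wca_phenotype == "FR", "WCA-FR", "")))
  reasons <- ifelse(!is.na(cm) & cm == "LR", paste0("LR:", lowrisk),
             ifelse(!is.na(cm) & cm == "VHR",
                    paste0("VHR:subgroup ", d$subgroup, ";", reasons), reasons))
  cm[!is.na(elig) & !elig] <- "unclassifiable"
  data.frame(patient_id = d$patient_id, eligible = elig, clinical = clin,
             cm = cm, reasons = reasons, stringsAsFactors = FALSE)
}

#' WCA marker combination labels
#'
#' For a chosen subset of the three WCA markers, labels each patient as
#' carrying at least k of the selected markers, for k = 1..|markers|.  With
#' all three markers, the k = 2 column reproduces the favorable-risk
#' phenotype definition.
#'
#' @param calls data.frame with logical columns \code{chr7_gain},
#'   \code{chr8_loss}, \code{chr11_loss}
#' @param markers non-empty subset of
#'   \code{c("chr7_gain","chr8_loss","chr11_loss")}
#' @return data.frame with \code{sample_id} (if present), \code{n_markers},
#'   and logical columns \code{ge1}, \code{ge2}, ...
#' @export
markerCombinations <- function(calls, markers = c("chr7_gain", "chr8_loss", "chr11_loss")) {
  markers <- unique(markers)
  if (length(markers) == 0L) mbStop("markerCombinations: empty marker set")
  bad <- setdiff(markers, c("chr7_gain", "chr8_loss", "chr11_loss"))
  if (length(bad)) mbStop("markerCombinations: unknown markers ", paste(bad, collapse = ", "))
  m <- as.matrix(calls[, markers, drop = FALSE])
  n <- rowSums(m)
  out <- data.frame(n_markers = as.integer(n))
  for (k in seq_along(markers)) out[[paste0("ge", k)]] <- n >= k
  if ("sample_id" %in% names(calls)) out <- cbind(sample_id = calls$sample_id, out)
  out
}
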