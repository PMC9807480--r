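# Model evaluation: time-dependent ROC, IPCW prediction-error curves,
# integrated Brier score, bootstrap cross-validation, external validation.
#
# The incident/dynamic AUC and the Graf IPCW Brier estimator are implemented
# here directly; Cox fitting underneath goes through the survival package.

#' Incident/dynamic time-dependent ROC AUC
#'
#' At each event time t up to the horizon, the incident/dynamic AUC is the
#' probability that the linear predictor of a subject failing at t exceeds
#' that of a randomly chosen subject still at risk at t (risk-set definition;
#' ties count 1/2).  Risk sets respect counting-process intervals, so
#' time-dependent covariates are handled through row-level predictors.  The
#' integrated AUC is the event-count-weighted average of AUC(t) up to the
#' horizon.
#'
#' @param lp linear predictor per counting-process row
#' @param start,stop,event counting-process interval columns
#' @param horizon evaluation horizon (same time unit as \code{stop})
#' @return list with \code{times}, \code{auc} (curve), \code{n_events},
#'   \code{iauc} (integrated AUC), \code{auc_last} (AUC at the last event
#'   time before the horizon)
#' @export
incidentDynamicAUC <- function(lp, start, stop, event, horizon) {
  stopifnot(length(lp) == length(start), length(start) == length(stop),
            length(stop) == length(event))
  event <- as.logical(event)
  et <- sort(unique(stop[event & stop <= horizon]))
  if (length(et) == 0L) mbStop("incidentDynamicAUC: no events before horizon")
  auc <- numeric(length(et))
  nev <- integer(length(et))
  for (k in seq_along(et)) {
    t <- et[k]
    atrisk <- start < t & stop >= t
    case <- atrisk & event & stop == t
    ctrl <- atrisk & !case
    nev[k] <- sum(case)
    if (!any(ctrl)) { auc[k] <- NA_real_; next }
    cs <- sort(lp[ctrl])
    below <- findInterval(lp[case], cs)                 # controls strictly or equal below
    belowStrict <- findInterval(lp[case], cs, left.open = TRUE)
    auc[k] <- mean((belowStrict + (below - belowStrict) / 2) / length(cs))
  }
  ok <- !is.na(auc)
  list(times = et, auc = auc, n_events = nev,
       iauc = sum(auc[ok] * nev[ok]) / sum(nev[ok]),
       auc_last = auc[max(which(ok))])
}

# Censoring-distribution Kaplan-Meier (roles of event and censoring swapped).
# Returns a lookup closure; minus = TRUE evaluates the left limit G(t-).
.censoringKM <- function(time, event) {
  fit <- survfit(Surv(time, 1 - as.integer(as.logical(event))) ~ 1)
  tt <- fit$time[fit$n.event > 0]
  ss <- fit$surv[fit$n.event > 0]
  function(t, minus = FALSE) {
    idx <- if (minus) findInterval(t, tt, left.open = TRUE) else findInterval(t, tt)
    ifelse(idx == 0L, 1, ss[pmax(idx, 1L)])
  }
}

#' IPCW prediction-error (Brier) curve
#'
#' Graf inverse-probability-of-censoring-weighted Brier score over a time
#' grid.  At time t, subjects with an observed event by t contribute their
#' squared predicted survival weighted by 1/G(T-); subjects still under
#' observation contribute (1 - S(t))^2 weighted by 1/G(t); subjects censored
#' before t contribute zero (their mass is carried by the weights).  G is the
#' Kaplan-Meier estimate of the censoring distribution.
#'
#' @param surv_matrix predicted survival probabilities, subjects x grid times
#' @param time,event observed follow-up time and event indicator per subject
#' @param grid evaluation time grid (matching columns of \code{surv_matrix})
#' @return numeric vector of Brier scores along \code{grid}
#' @export
brierCurve <- function(surv_matrix, time, event, grid) {
  surv_matrix <- as.matrix(surv_matrix)
  n <- length(time)
  stopifnot(nrow(surv_matrix) == n, ncol(surv_matrix) == length(grid))
  if (any(surv_matrix < -1e-9 | surv_matrix > 1 + 1e-9)) {
    mbStop("brierCurve: predictions must be survival probabilities in [0,1]")
  }
  event <- as.logical(event)
  G <- .censoringKM(time, event)
  g_minus <- G(time, minus = TRUE)
  gt <- G(grid)
  ng <- length(grid)
  timeM <- matrix(time, n, ng)
  gridM <- matrix(grid, n, ng, byrow = TRUE)
  failedM <- (timeM <= gridM) & event
  aliveM <- timeM > gridM
  if (any(failedM & g_minus <= 0)) {
    mbStop("brierCurve: censoring survival is 0 before an observed event time")
  }
  bad <- gt <= 0 & colSums(aliveM) > 0
  if (any(bad)) {
    mbStop(sprintf("brierCurve: censoring survival is 0 at t=%g",
                   grid[which(bad)[1]]))
  }
  contrib <- surv_matrix^2 * failedM / g_minus +
    sweep((1 - surv_matrix)^2 * aliveM, 2L, pmax(gt, .Machine$double.eps), "/")
  colSums(contrib) / n
}

#' Integrated Brier score
#'
#' Trapezoid time-average of a prediction-error curve over [0, horizon],
#' normalized by the horizon.
#'
#' @param brier Brier scores along \code{grid}
#' @param grid time grid (must span the horizon)
#' @param horizon upper integration limit
#' @return numeric integrated Brier score
#' @export
integratedBrier <- function(brier, grid, horizon = max(grid)) {
  if (length(grid) == 0L) mbStop("integratedBrier: empty grid")
  stopifnot(length(brier) == length(grid))
  o <- order(grid)
  grid <- grid[o]; brier <- brier[o]
  if (horizon > max(grid) + 1e-9) {
    mbStop("integratedBrier: horizon beyond last grid point")
  }
  keep <- grid <= horizon + 1e-12
  g <- grid[keep]; b <- brier[keep]
  if (g[1] > 0) { g <- c(0, g); b <- c(b[1], b) }
  if (length(g) == 1L) return(b[1])
  sum(diff(g) * (utils::head(b, -1) + utils::tail(b, -1)) / 2) / (g[length(g)] - g[1])
}

#' Specification of a risk model
#'
#' Names the covariates of a Cox model on the assembled analysis table.  The
#' pseudo-covariate \code{"rt"} denotes craniospinal radiotherapy as the
#' time-dependent exposure built by \code{\link{buildTdDataset}}; every other
#' name must be a column of the table.
#'
#' @param name model label
#' @param covariates character vector of covariate names
#' @param endpoint \code{"PFS"} (default) or \code{"OS"}
#' @return list of class \code{modelSpec}
#' @export
modelSpec <- function(name, covariates, endpoint = "PFS") {
  stopifnot(is.character(name), length(name) == 1L, length(covariates) >= 1L)
  structure(list(name = name, covariates = covariates, endpoint = endpoint),
            class = "modelSpec")
}

#' The published backbone plus a biology term
#'
#' Convenience constructors: \code{backboneSpec} is the standard clinical
#' backbone (RT time-dependent, staging, MYC and MYCN amplification) plus
#' optional biology covariates; \code{clinicalStratumSpec} and
#' \code{cmStratumSpec} are the stratum-only clinical and clinico-molecular
#' models compared by cross-validated prediction error.
#'
#' @param biology extra covariate names appended to the backbone
#' @param endpoint endpoint passed to \code{\link{modelSpec}}
#' @return a \code{\link{modelSpec}}
#' @export
backboneSpec <- function(biology = character(), endpoint = "PFS") {
  nm <- if (length(biology)) paste0("backbone+", paste(biology, collapse = "+"))
        else "backbone"
  modelSpec(nm, c("rt", "m_stage", "myc_amp", "mycn_amp", biology), endpoint)
}

#' @rdname backboneSpec
#' @export
clinicalStratumSpec <- function(endpoint = "PFS") {
  modelSpec("clinical", "clinical_stratum", endpoint)
}

#' @rdname backboneSpec
#' @export
cmStratumSpec <- function(endpoint = "PFS") {
  modelSpec("clinico-molecular", "cm_stratum", endpoint)
}

# Assemble patients + labels + calls + strata into one analysis table with
# frozen factor codings (reference levels: M0, no amp, WCA-SR, Group4 ...,
# clinical SR, CM LR).
#' Assemble the per-patient analysis table
#'
#' Joins the clinical table, molecular labels, molecular calls, and risk
#' strata by \code{patient_id} and applies the frozen factor codings used by
#' the model specifications (reference levels M0, SR phenotype, LR stratum).
#'
#' @param patients clinical table
#' @param labels molecular label table
#' @param calls \code{\link{callCohort}} output
#' @param strata \code{\link{stratifyCohort}} output
#' @return data.frame, one row per patient
#' @export
assembleAnalysisTable <- function(patients, labels, calls, strata) {
  if (!"patient_id" %in% names(calls) && "sample_id" %in% names(calls)) {
    calls$patient_id <- calls$sample_id
  }
  d <- Reduce(function(a, b) merge(a, b, by = "patient_id", sort = FALSE),
              list(patients, labels,
                   calls[, setdiff(names(calls), "sample_id"), drop = FALSE],
                   strata[, c("patient_id", "clinical", "cm"), drop = FALSE]))
  d$m_stage <- factor(d$m_stage, levels = c("M0", "M+"))
  d$resection <- factor(d$resection, levels = c("R0", "R+"))
  d$histology <- factor(d$histology, levels = c("CMB", "DMB", "LCA"))
  d$group <- factor(d$group, levels = c("Group4", "Group3"))
  d$subgroup <- factor(d$subgroup, levels = .SUBGROUPS)
  d$wca_phenotype <- factor(d$wca_phenotype, levels = c("SR", "FR"))
  d$clinical_stratum <- factor(d$clinical, levels = c("SR", "HR"))
  d$cm_stratum <- factor(d$cm, levels = c("LR", "SR", "HR", "VHR"))
  d
}

#' Fit a specified risk model
#'
#' Builds the counting-process dataset for the spec's endpoint and fits the
#' Cox model with Efron ties.  The fit keeps its training rows so that
#' predictions and apparent metrics can be recomputed.
#'
#' @param spec a \code{\link{modelSpec}}
#' @param table analysis table from \code{\link{assembleAnalysisTable}}
#' @return list of class \code{fittedRiskModel}: \code{spec}, \code{cox}
#'   (a \code{\link{coxFit}}), \code{rows} (training counting-process rows)
#' @export
fitModel <- function(spec, table) {
  rows <- buildTdDataset(table, spec$endpoint)
  cf <- coxFit(rows, spec$covariates)
  structure(list(spec = spec, cox = cf, rows = rows), class = "fittedRiskModel")
}

#' @export
print.fittedRiskModel <- function(x, ...) {
  cat(sprintf("Risk model '%s' (%s): ", x$spec$name, x$spec$endpoint))
  print(x$cox, ...)
  invisible(x)
}

# Uncentered linear predictors for counting-process rows under a coxph fit;
# errors on factor levels unseen at training time.
.lpZero <- function(fit, rows) {
  xl <- fit$xlevels
  for (v in names(xl)) {
    lev <- unique(as.character(rows[[v]]))
    unseen <- setdiff(lev[!is.na(lev)], xl[[v]])
    if (length(unseen)) {
      mbStop(sprintf("unseen level(s) of '%s' in validation data: %s",
                     v, paste(unseen, collapse = ", ")))
    }
  }
  as.numeric(stats::predict(fit, newdata = rows, type = "lp", reference = "zero"))
}

# Per-subject predicted survival over a grid, honouring each subject's own
# time-dependent covariate path: S_i(t) = exp(-sum_rows e^lp [H0(min(t, stop))
# - H0(start)]+), with H0 the Breslow baseline at covariates zero.
.predictSurvMatrix <- function(fit, rows, grid, id = rows$patient_id) {
  bh <- survival::basehaz(fit, centered = FALSE)
  H0 <- stats::stepfun(bh$time, c(0, bh$hazard))
  lp <- .lpZero(fit, rows)
  R <- nrow(rows); G <- length(grid)
  H0g <- H0(grid)
  M <- pmin(matrix(H0g, nrow = R, ncol = G, byrow = TRUE),
            matrix(H0(rows$stop), nrow = R, ncol = G))
  M <- pmax(M - H0(rows$start), 0) * exp(lp)
  cum <- rowsum(M, group = id, reorder = FALSE)
  exp(-cum[match(unique(id), rownames(cum)), , drop = FALSE])
}

# Evaluate a fitted model on counting-process rows (training or validation):
# IBS over event-time grid up to horizon, Harrell C (plus horizon-truncated C).
.evalOnRows <- function(fit, rows, horizon) {
  subj <- rows[!duplicated(rows$patient_id),
               c("patient_id"), drop = FALSE]
  exit <- tapply(rows$stop, rows$patient_id, max)[subj$patient_id]
  ev <- tapply(rows$event, rows$patient_id, any)[subj$patient_id]
  et <- sort(unique(rows$stop[rows$event & rows$stop <= horizon]))
  grid <- unique(c(0, et, horizon))
  S <- .predictSurvMatrix(fit, rows, grid, id = rows$patient_id)
  S <- S[match(subj$patient_id, rownames(S)), , drop = FALSE]
  bs <- brierCurve(S, as.numeric(exit), as.logical(ev), grid)
  lp <- .lpZero(fit, rows)
  cc <- survival::concordance(Surv(start, stop, event) ~ lp,
                              data = cbind(rows, lp = lp), reverse = TRUE)
  cct <- survival::concordance(Surv(start, stop, event) ~ lp,
                               data = cbind(rows, lp = lp), reverse = TRUE,
                               ymax = horizon)
  list(grid = grid, brier = bs,
       ibs = integratedBrier(bs, grid, horizon),
       cindex = as.numeric(cc$concordance),
       cindex_truncated = as.numeric(cct$concordance))
}

#' Bootstrap cross-validation of a risk model
#'
#' For each bootstrap resample of patients the model is refit (including the
#' counting-process construction) and evaluated on the out-of-bag patients:
#' IPCW integrated Brier score up to the horizon and Harrell concordance.
#' Replicates whose resample has no events, an empty out-of-bag set, or a
#' rank-deficient design are skipped and counted; a warning is raised when
#' more than 5\% are skipped.  Deterministic given \code{seed}.
#'
#' @param spec a \code{\link{modelSpec}}
#' @param table analysis table
#' @param B number of bootstrap resamples (>= 2)
#' @param horizon evaluation horizon in years
#' @param seed RNG seed
#' @return list with \code{cv_ibs}, \code{cv_cindex} (replicate means),
#'   \code{replicates} data.frame, \code{n_skipped}
#' @export
bootstrapCV <- function(spec, table, B = 500L, horizon = 5, seed = 1L) {
  if (B < 2L) mbStop("bootstrapCV: B must be >= 2")
  if (nrow(table) < 2L) mbStop("bootstrapCV: degenerate cohort")
  set.seed(seed)
  n <- nrow(table)
  reps <- data.frame(b = seq_len(B), ibs = NA_real_, cindex = NA_real_)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(idx))
    res <- tryCatch({
      train <- table[idx, , drop = FALSE]
      train$patient_id <- sprintf("B%05d", seq_len(n))   # resampled copies are distinct subjects
      fitted <- fitModel(spec, train)
      oobRows <- buildTdDataset(table[oob, , drop = FALSE], spec$endpoint)
      .evalOnRows(fitted$cox$fit, oobRows, horizon)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      reps$ibs[b] <- res$ibs
      reps$cindex[b] <- res$cindex
    }
  }
  skipped <- sum(is.na(reps$ibs))
  if (skipped > 0.05 * B) {
    warning(sprintf("bootstrapCV: %d/%d replicates skipped", skipped, B))
  }
  list(cv_ibs = mean(reps$ibs, na.rm = TRUE),
       cv_cindex = mean(reps$cindex, na.rm = TRUE),
       replicates = reps, n_skipped = skipped)
}

#' Frozen-model external validation
#'
#' Applies a model fitted on the discovery cohort, without refitting, to an
#' independent validation cohort: predictions are carried from the discovery
#' fit and the IPCW integrated Brier score and concordance are computed on
#' the validation data only.  Factor levels absent from the discovery fit
#' raise an error naming them.
#'
#' @param fitted a \code{fittedRiskModel} from \code{\link{fitModel}}
#' @param validation analysis table of the validation cohort
#' @param horizon evaluation horizon in years
#' @return list with \code{ibs}, \code{cindex}, \code{cindex_truncated},
#'   \code{grid}, \code{brier}
#' @export
externalValidate <- function(fitted, validation, horizon = 5) {
  rows <- buildTdDataset(validation, fitted$spec$endpoint)
  .evalOnRows(fitted$cox$fit, rows, horizon)
}

#' Compare risk models on one cohort
#'
#' Fits every specification on the same counting-process data and reports,
#' per model: AIC, Harrell concordance (full and horizon-truncated),
#' incident/dynamic AUC curve with its integrated value, apparent IPCW
#' integrated Brier score, and (when \code{B > 0}) bootstrap cross-validated
#' IBS and concordance.  The model with the highest integrated AUC is
#' declared best, mirroring the published selection procedure.
#'
#' @param specs list of \code{\link{modelSpec}}s (>= 2)
#' @param table analysis table
#' @param horizon evaluation horizon in years
#' @param B bootstrap resamples for cross-validation (0 to skip)
#' @param seed RNG seed for the bootstrap
#' @return object of class \code{modelComparison}: \code{metrics} data.frame,
#'   \code{fits}, \code{auc_curves}, \code{brier_curves}, \code{replicates},
#'   \code{best}
#' @export
compareModels <- function(specs, table, horizon = 5, B = 0L, seed = 1L) {
  if (length(specs) < 2L) mbStop("compareModels: need at least two model specs")
  fits <- list(); aucs <- list(); pecs <- list(); repl <- list()
  rowsL <- list()
  met <- data.frame()
  for (sp in specs) {
    fitted <- tryCatch(fitModel(sp, table), error = function(e) e)
    if (inherits(fitted, "error")) {
      met <- rbind(met, data.frame(model = sp$name, failed = TRUE, n_events = NA,
        aic = NA, cindex = NA, cindex_truncated = NA, iauc = NA, auc_last = NA,
        ibs_apparent = NA, cv_ibs = NA, cv_cindex = NA))
      next
    }
    fits[[sp$name]] <- fitted
    lp <- .lpZero(fitted$cox$fit, fitted$rows)
    auc <- incidentDynamicAUC(lp, fitted$rows$start, fitted$rows$stop,
                              fitted$rows$event, horizon)
    aucs[[sp$name]] <- auc
    ev <- .evalOnRows(fitted$cox$fit, fitted$rows, horizon)
    pecs[[sp$name]] <- data.frame(time = ev$grid, brier = ev$brier)
    cv <- list(cv_ibs = NA_real_, cv_cindex = NA_real_)
    if (B > 0L) {
      cv <- bootstrapCV(sp, table, B = B, horizon = horizon, seed = seed)
      repl[[sp$name]] <- cv$replicates
    }
    met <- rbind(met, data.frame(model = sp$name, failed = FALSE,
      n_events = fitted$cox$n_events, aic = fitted$cox$aic,
      cindex = ev$cindex, cindex_truncated = ev$cindex_truncated,
      iauc = auc$iauc, auc_last = auc$auc_last, ibs_apparent = ev$ibs,
      cv_ibs = cv$cv_ibs, cv_cindex = cv$cv_cindex))
  }
  ok <- !met$failed
  best <- if (any(ok)) met$model[ok][which.max(met$iauc[ok])] else NA_character_
  structure(list(metrics = met, fits = fits, auc_curves = aucs,
                 brier_curves = pecs, replicates = repl, best = best,
                 horizon = horizon, B = B, seed = seed),
            class = "modelComparison")
}

#' @export
print.modelComparison <- function(x, digits = 3, ...) {
  cat(sprintf("Model comparison at %g-year horizon (B=%d):\n", x$horizon, x$B))
  print(format(x$metrics[, c("model", "n_events", "aic", "cindex", "iauc",
                             "ibs_apparent", "cv_ibs", "cv_cindex")],
               digits = digits), row.names = FALSE)
  cat(sprintf("Best model by integrated AUC: %s\n", x$best))
  invisible(x)
}
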