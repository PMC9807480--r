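#' @importFrom survival Surv survfit survdiff coxph concordance basehaz
NULL

#' Kaplan-Meier estimate with Greenwood standard errors
#'
#' Product-limit estimator via \code{survival::survfit}; the returned
#' standard error is the Greenwood standard error of the survival estimate
#' itself (the quantity survival software displays as the +/- band).
#'
#' @param time follow-up times (> 0)
#' @param event logical/0-1 event indicators
#' @return object of class \code{kmCurve} with \code{time}, \code{n_risk},
#'   \code{n_event}, \code{surv}, \code{se}
#' @export
kmEstimate <- function(time, event) {
  if (length(time) == 0L) mbStop("kmEstimate: no subjects")
  if (any(!is.finite(time)) || any(time <= 0)) {
    mbStop("kmEstimate: times must be positive and finite")
  }
  event <- as.integer(as.logical(event))
  fit <- survfit(Surv(time, event) ~ 1, conf.type = "plain",
                 error = "greenwood")
  se <- fit$surv * fit$std.err
  se[fit$surv == 0] <- 0      # Greenwood limit once the curve reaches zero
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv, se = se,
                 n = length(time), n_events = sum(event)),
            class = "kmCurve")
}

#' @export
print.kmCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n=%d, events=%d, final S=%.3f\n",
              x$n, x$n_events, x$surv[length(x$surv)]))
  invisible(x)
}

#' Survival probability at a time point
#'
#' Right-continuous step lookup of a \code{\link{kmEstimate}} curve; returns
#' the estimate and its Greenwood standard error at the last event time not
#' exceeding \code{t}.
#'
#' @param km a \code{kmCurve}
#' @param t time point(s)
#' @return data.frame with \code{time}, \code{surv}, \code{se}
#' @export
survivalAt <- function(km, t) {
  idx <- findInterval(t, km$time)
  data.frame(time = t,
             surv = ifelse(idx == 0L, 1, km$surv[pmax(idx, 1L)]),
             se = ifelse(idx == 0L, 0, km$se[pmax(idx, 1L)]))
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank statistic over two or more
#' groups with chi-square reference distribution on (groups - 1) degrees of
#' freedom.
#'
#' @param time follow-up times
#' @param event event indicators
#' @param group group labels (>= 2 non-empty groups)
#' @return list with \code{chi2}, \code{df}, \code{p}
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(group)
  tab <- table(droplevels(group))
  if (nlevels(group) < 2L || any(table(group) == 0L)) {
    mbStop("logrankTest: need >= 2 non-empty groups (empty level present or single group)")
  }
  fit <- survdiff(Surv(time, as.integer(as.logical(event))) ~ group)
  df <- length(fit$n) - 1L
  list(chi2 = as.numeric(fit$chisq), df = df,
       p = stats::pchisq(as.numeric(fit$chisq), df, lower.tail = FALSE))
}

#' Counting-process dataset with radiotherapy as time-dependent exposure
#'
#' Each patient becomes one or two (start, stop] rows.  A radiotherapy start
#' time strictly inside the follow-up interval splits the patient into an
#' unexposed row (0, rt_start] and an exposed row (rt_start, exit]; RT at or
#' after exit, or absent, leaves a single unexposed row; RT at time 0 gives a
#' single exposed row.
#'
#' @param patients data.frame with \code{patient_id}, \code{rt_start_years}
#'   (NA allowed) and the endpoint columns (\code{pfs_years}/\code{pfs_event}
#'   or \code{os_years}/\code{os_event}); any further columns are carried
#'   through unchanged.
#' @param endpoint \code{"PFS"} or \code{"OS"}
#' @return data.frame with \code{patient_id}, \code{start}, \code{stop},
#'   \code{event}, \code{rt}, plus carried covariates
#' @export
buildTdDataset <- function(patients, endpoint = c("PFS", "OS")) {
  endpoint <- match.arg(endpoint)
  tcol <- if (endpoint == "PFS") "pfs_years" else "os_years"
  ecol <- if (endpoint == "PFS") "pfs_event" else "os_event"
  if (!all(c("patient_id", tcol, ecol) %in% names(patients))) {
    mbStop("buildTdDataset: missing required columns")
  }
  time <- patients[[tcol]]
  event <- as.logical(patients[[ecol]])
  rt0 <- patients[["rt_start_years"]] %||% rep(NA_real_, nrow(patients))
  if (any(!is.finite(time)) || any(time <= 0)) {
    mbStop("buildTdDataset: follow-up times must be positive")
  }
  if (any(rt0 < 0, na.rm = TRUE)) mbStop("buildTdDataset: negative rt start time")
  split2 <- !is.na(rt0) & rt0 > 0 & rt0 < time
  exposed1 <- !is.na(rt0) & rt0 <= 0
  keep <- setdiff(names(patients), c(tcol, ecol, "rt_start_years"))
  base <- patients[, keep, drop = FALSE]
  n1 <- sum(!split2); n2 <- sum(split2)
  one <- cbind(base[!split2, , drop = FALSE],
               start = rep(0, n1), stop = time[!split2],
               event = event[!split2],
               rt = as.integer(exposed1[!split2]))
  pre <- cbind(base[split2, , drop = FALSE],
               start = rep(0, n2), stop = rt0[split2],
               event = rep(FALSE, n2), rt = rep(0L, n2))
  post <- cbind(base[split2, , drop = FALSE],
                start = rt0[split2], stop = time[split2],
                event = event[split2], rt = rep(1L, n2))
  out <- rbind(one, pre, post)
  out <- out[order(match(out$patient_id, patients$patient_id), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cox proportional-hazards fit on counting-process data
#'
#' Maximizes the Cox partial likelihood with Efron tie handling over risk
#' sets defined by (start, stop] intervals.  Reports hazard ratios with Wald
#' 95\% confidence intervals on the log scale, AIC, Harrell concordance, and
#' the global score (log-rank) test.
#'
#' @param rows counting-process data.frame from \code{\link{buildTdDataset}}
#'   (or any data.frame with \code{start}, \code{stop}, \code{event})
#' @param covariates character vector of covariate column names
#' @param ties tie-handling method, \code{"efron"} by default
#' @return object of class \code{coxFit}: coefficient table, \code{loglik},
#'   \code{aic}, \code{concordance}, \code{sctest} (statistic, df, p),
#'   \code{n_events}, and the underlying \code{coxph} fit
#' @export
coxFit <- function(rows, covariates, ties = "efron") {
  stopifnot(all(c("start", "stop", "event") %in% names(rows)))
  if (sum(rows$event) < 1L) mbStop("coxFit: no events")
  fml <- stats::reformulate(covariates, response = quote(Surv(start, stop, event)))
  fit <- coxph(fml, data = rows, ties = ties)
  if (any(is.na(stats::coef(fit)))) {
    mbStop("coxFit: design matrix rank-deficient (constant or aliased covariate): ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  s <- summary(fit)
  co <- s$coefficients
  tab <- data.frame(term = rownames(co), coef = co[, "coef"],
    se = co[, "se(coef)"], hr = exp(co[, "coef"]),
    hr_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    hr_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    z = co[, "z"], p = co[, "Pr(>|z|)"], row.names = NULL)
  ll <- fit$loglik[length(fit$loglik)]
  structure(list(coefficients = tab, loglik = ll,
                 aic = 2 * nrow(tab) - 2 * ll,
                 concordance = as.numeric(fit$concordance["concordance"]),
                 sctest = s$sctest, n = fit$n, n_events = fit$nevent,
                 fit = fit), class = "coxFit")
}

#' @export
print.coxFit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox model: n=%d, events=%d, AIC=%.2f, concordance=%.3f\n",
              x$n, x$n_events, x$aic, x$concordance))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat(sprintf("Global score (log-rank) test: p=%.3g\n", x$sctest["pvalue"]))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic without continuity correction (switchable), as
#' used for cohort-composition comparisons.
#'
#' @param tab contingency table of non-negative counts (>= 2x2)
#' @param correct apply Yates continuity correction (default FALSE)
#' @return list with \code{statistic}, \code{df}, \code{p}
#' @export
pearsonChisq <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) mbStop("pearsonChisq: need at least a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    mbStop("pearsonChisq: counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    mbStop("pearsonChisq: zero marginal row or column")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = as.numeric(ct$statistic), df = as.numeric(ct$parameter),
       p = ct$p.value)
}

#' Cohen's kappa for inter-rater agreement
#'
#' kappa = (p_o - p_e) / (1 - p_e) with chance agreement from the marginals
#' of a square confusion matrix.
#'
#' @param confusion square matrix of counts (raters in rows/columns)
#' @return numeric kappa
#' @export
cohensKappa <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) mbStop("cohensKappa: confusion matrix must be square")
  if (any(m < 0)) mbStop("cohensKappa: negative counts")
  n <- sum(m)
  if (n == 0) mbStop("cohensKappa: empty matrix")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    if (abs(po - 1) < .Machine$double.eps^0.5) return(1)
    mbStop("cohensKappa: degenerate marginals (chance agreement = 1)")
  }
  (po - pe) / (1 - pe)
}
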