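# End-to-end pipeline driver: simulate -> call-cnv -> stratify -> survfit ->
# compare-models, with persisted outputs, a consort-style filter log, and the
# effective configuration (plus its hash and seed) written next to the
# results.

#' Pipeline configuration
#'
#' Single source of truth for a pipeline run: either a synthetic cohort
#' (\code{cohort = NULL}) generated from \code{cohort_config}, or file paths
#' to an existing cohort/labels/calls triple.
#'
#' @param cohort_config a \code{\link{cohortConfig}} for synthetic input
#' @param cohort_file,labels_file,calls_file optional input paths overriding
#'   simulation
#' @param thresholds a \code{\link{callingThresholds}}
#' @param horizon evaluation horizon in years (> 0)
#' @param bootstrap_B bootstrap resamples for model cross-validation
#' @param seed seed for the model-evaluation bootstrap
#' @param endpoint \code{"PFS"} or \code{"OS"}
#' @return list of class \code{pipelineConfig}
#' @export
pipelineConfig <- function(cohort_config = cohortConfig(),
                           cohort_file = NULL, labels_file = NULL,
                           calls_file = NULL,
                           thresholds = callingThresholds(),
                           horizon = 5, bootstrap_B = 100L, seed = 17L,
                           endpoint = "PFS") {
  if (horizon <= 0) mbStop("pipelineConfig: horizon must be > 0")
  for (p in c(cohort_file, labels_file, calls_file)) {
    if (!is.null(p) && !file.exists(p)) mbStop(sprintf("pipelineConfig: missing input file %s", p))
  }
  structure(list(cohort_config = cohort_config, cohort_file = cohort_file,
                 labels_file = labels_file, calls_file = calls_file,
                 thresholds = thresholds, horizon = horizon,
                 bootstrap_B = as.integer(bootstrap_B), seed = as.integer(seed),
                 endpoint = endpoint),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Top-level keys mirror the \code{\link{pipelineConfig}} arguments;
#' \code{cohort} and \code{thresholds} blocks map onto
#' \code{\link{cohortConfig}} and \code{\link{callingThresholds}} arguments.
#'
#' @param path YAML file path
#' @return a \code{pipelineConfig}
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cc <- do.call(cohortConfig, y$cohort %||% list())
  th <- do.call(callingThresholds, y$thresholds %||% list())
  pipelineConfig(cohort_config = cc,
                 cohort_file = y$cohort_file, labels_file = y$labels_file,
                 calls_file = y$calls_file, thresholds = th,
                 horizon = y$horizon %||% 5,
                 bootstrap_B = y$bootstrap_B %||% 100L,
                 seed = y$seed %||% 17L,
                 endpoint = y$endpoint %||% "PFS")
}

.serializeConfig <- function(config) {
  flat <- list(
    horizon = config$horizon, bootstrap_B = config$bootstrap_B,
    seed = config$seed, endpoint = config$endpoint,
    cohort_file = config$cohort_file, labels_file = config$labels_file,
    calls_file = config$calls_file,
    thresholds = unclass(config$thresholds),
    cohort = lapply(unclass(config$cohort_config), function(v)
      if (is.numeric(v) && !is.null(names(v))) as.list(v) else v))
  yaml::as.yaml(flat)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain a cohort (simulated or read from the configured
#' files), render and call copy-number profiles (synthetic route) or read
#' calls, apply the eligibility filter and risk stratification, estimate
#' per-stratum survival curves, and compare the clinical against the
#' clinico-molecular model with bootstrap cross-validation.  All tables are
#' written under \code{out_dir}; the effective configuration, its MD5 hash,
#' and the seed are persisted alongside, and a consort-style log records the
#' patient count entering and leaving each stage.  Any stage failure aborts
#' with the stage name; outputs of completed stages remain on disk.
#'
#' @param config a \code{\link{pipelineConfig}} (or path to a YAML file)
#' @param out_dir output directory (created if needed)
#' @return invisible list with \code{tables} (cohort, strata, ...),
#'   \code{comparison}, \code{log}, \code{out_dir}
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "curves"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "comparison"), showWarnings = FALSE)
  logLines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    logLines <<- c(logLines, line)
    message("[mbrisk] ", line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(logLines, file.path(out_dir, "pipeline_log.txt"))
      mbStop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  cfgYaml <- .serializeConfig(config)
  cfgPath <- file.path(out_dir, "config_used.yaml")
  writeLines(cfgYaml, cfgPath)
  cfgHash <- unname(tools::md5sum(cfgPath))
  note("config hash %s, seed %d", cfgHash, config$seed)

  synthetic <- is.null(config$cohort_file)
  if (synthetic) {
    sim <- stage("simulate", generateCohort(config$cohort_config))
    patients <- sim$patients; labels <- sim$labels
    note("simulate: n=%d patients (seed %d)", nrow(patients),
         config$cohort_config$seed)
    se <- stage("render", renderProfiles(sim$truth, config$cohort_config))
    calls <- stage("call-cnv", callCohort(se, thresholds = config$thresholds))
    note("call-cnv: %d profiles called (%d bins each)", ncol(se), nrow(se))
  } else {
    patients <- stage("read-cohort", readCohort(config$cohort_file))
    labels <- stage("read-labels", readLabels(config$labels_file))
    calls <- stage("read-calls", readCalls(config$calls_file))
    note("input: n=%d patients read", nrow(patients))
  }
  writeCohort(patients, file.path(out_dir, "cohort.csv"))
  writeLabels(labels, file.path(out_dir, "labels.csv"))
  writeCalls(calls, file.path(out_dir, "calls.tsv"))

  strata <- stage("stratify", stratifyCohort(patients, labels, calls))
  nElig <- sum(strata$eligible, na.rm = TRUE)
  nClass <- sum(!is.na(strata$cm) & strata$cm != "unclassifiable")
  note("stratify: input n=%d, eligible n=%d, classified n=%d",
       nrow(patients), nElig, nClass)
  utils::write.table(strata, file.path(out_dir, "strata.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)

  tab <- assembleAnalysisTable(patients, labels, calls, strata)
  tab <- tab[!is.na(tab$cm_stratum), , drop = FALSE]
  tcol <- if (config$endpoint == "PFS") "pfs_years" else "os_years"
  ecol <- if (config$endpoint == "PFS") "pfs_event" else "os_event"
  curves <- stage("survfit", {
    lapply(split(tab, tab$cm_stratum), function(g) {
      if (nrow(g) == 0L) return(NULL)
      km <- kmEstimate(g[[tcol]], g[[ecol]])
      data.frame(time = km$time, n_risk = km$n_risk, surv = km$surv, se = km$se)
    })
  })
  for (s in names(curves)) {
    if (is.null(curves[[s]])) next
    utils::write.table(curves[[s]],
      file.path(out_dir, "curves", sprintf("km_%s_%s.tsv", config$endpoint, s)),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  lr <- stage("survfit", logrankTest(tab[[tcol]], tab[[ecol]], tab$cm_stratum))
  note("survfit: %d strata curves, log-rank chi2=%.2f (df=%d, p=%.3g)",
       sum(!vapply(curves, is.null, logical(1))), lr$chi2, lr$df, lr$p)

  cmp <- stage("compare-models", compareModels(
    list(clinicalStratumSpec(config$endpoint), cmStratumSpec(config$endpoint)),
    tab, horizon = config$horizon, B = config$bootstrap_B, seed = config$seed))
  utils::write.table(cbind(config_hash = cfgHash, cmp$metrics),
                     file.path(out_dir, "comparison", "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (m in names(cmp$replicates)) {
    utils::write.table(cmp$replicates[[m]],
      file.path(out_dir, "comparison", sprintf("replicates_%s.tsv", gsub("[^A-Za-z0-9]+", "_", m))),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (m in names(cmp$brier_curves)) {
    utils::write.table(cmp$brier_curves[[m]],
      file.path(out_dir, "comparison", sprintf("pec_%s.tsv", gsub("[^A-Za-z0-9]+", "_", m))),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  note("compare-models: best by integrated AUC = %s", cmp$best)

  writeLines(logLines, file.path(out_dir, "pipeline_log.txt"))
  invisible(list(tables = list(patients = patients, labels = labels,
                               calls = calls, strata = strata, analysis = tab),
                 curves = curves, logrank = lr, comparison = cmp,
                 config_hash = cfgHash, log = logLines, out_dir = out_dir))
}
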