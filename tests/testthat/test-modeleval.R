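test_that("integrated Brier score is the normalized trapezoid", {
  expect_equal(integratedBrier(rep(0.25, 6), seq(0, 5)), 0.25)
  # linear 0 -> 0.2 over [0, 5]: time-average 0.1
  expect_equal(integratedBrier(seq(0, 0.2, length.out = 11), seq(0, 5, length.out = 11)), 0.1)
  expect_error(integratedBrier(numeric(0), numeric(0)), "empty grid")
  expect_error(integratedBrier(c(.1, .2), c(0, 2), horizon = 5), "beyond last grid")
})

test_that("Brier curve reproduces closed-form uncensored cases", {
  time <- c(1, 2, 3, 4, 6, 7)
  ev <- rep(TRUE, 6)
  grid <- c(0, 1.5, 3.5, 5)
  # all predictions 1/2 everywhere: Brier = 1/4 at every time
  S <- matrix(0.5, 6, length(grid))
  expect_equal(brierCurve(S, time, ev, grid), rep(0.25, 4))
  # perfect oracle predictions: 0 everywhere
  Sperf <- outer(time, grid, function(ti, t) as.numeric(ti > t))
  expect_equal(brierCurve(Sperf, time, ev, grid), rep(0, 4))
  expect_error(brierCurve(S * 3, time, ev, grid), "probabilities")
})

test_that("IPCW Brier equals the brute-force estimator, censored and not", {
  set.seed(14)
  n <- 40
  time <- round(stats::rexp(n, 0.4), 3) + 0.01
  ev <- stats::runif(n) < 0.8            # ~20% censoring
  grid <- c(0, sort(stats::runif(4, 0.2, 3)))
  S <- matrix(stats::runif(n * length(grid)), n, length(grid))
  S <- t(apply(S, 1, function(z) rev(sort(z))))  # non-increasing per subject
  expect_equal(brierCurve(S, time, ev, grid), bruteBrier(S, time, ev, grid),
               tolerance = 1e-12)
  # with no censoring the IPCW weights vanish: plain mean squared error
  evAll <- rep(TRUE, n)
  mse <- vapply(seq_along(grid), function(k)
    mean(((time > grid[k]) - S[, k])^2), numeric(1))
  expect_equal(brierCurve(S, time, evAll, grid), mse, tolerance = 1e-12)
})

test_that("incident/dynamic AUC agrees with exhaustive pair counting at n = 8", {
  start <- rep(0, 8)
  stop <- c(1, 1, 2, 3, 4, 5, 6, 7)       # tied failure at t = 1
  event <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  lp <- c(2.0, 0.5, 1.5, 0.0, 1.5, -0.5, 0.3, -1.0)  # includes a tie
  res <- incidentDynamicAUC(lp, start, stop, event, horizon = 10)
  oracle <- brutePairAUC(lp, start, stop, event, horizon = 10)
  expect_equal(res$times, oracle$times)
  expect_equal(res$auc, oracle$auc, tolerance = 1e-12)
  expect_equal(res$iauc, oracle$iauc, tolerance = 1e-12)
})

test_that("AUC is 1 for a perfect predictor and errors with no events", {
  # linear predictor that ranks every failure above every survivor at each
  # risk set; one late censored subject keeps the final risk set non-trivial
  stop <- c(1:10, 12)
  event <- c(rep(TRUE, 10), FALSE)
  lp <- c(10:1, -5)  # earlier failure = higher risk
  res <- incidentDynamicAUC(lp, rep(0, 11), stop, event, horizon = 10)
  expect_true(all(res$auc == 1))
  expect_equal(res$iauc, 1)
  expect_error(incidentDynamicAUC(lp, rep(0, 11), stop, rep(FALSE, 11), 10),
               "no events")
})

test_that("bootstrap cross-validation is seed-reproducible and guards inputs", {
  tab <- smallAnalysisTable(n = 250, seed = 19)
  a <- bootstrapCV(cmStratumSpec(), tab, B = 3, horizon = 5, seed = 7)
  b <- bootstrapCV(cmStratumSpec(), tab, B = 3, horizon = 5, seed = 7)
  expect_identical(a, b)
  expect_error(bootstrapCV(cmStratumSpec(), tab[1, ], B = 3), "degenerate")
  expect_error(bootstrapCV(cmStratumSpec(), tab, B = 1), "B must be")
})

test_that("a strongly prognostic model cross-validates better than noise", {
  set.seed(23)
  n <- 500
  x <- stats::rbinom(n, 1, 0.5)
  noise <- stats::rnorm(n)
  t0 <- stats::rexp(n, 0.1 * exp(log(4) * x))
  cens <- stats::runif(n, 0, 15)
  tab <- data.frame(patient_id = sprintf("p%03d", 1:n),
                    rt_start_years = NA_real_,
                    pfs_years = pmin(t0, cens) + 1e-6,
                    pfs_event = t0 <= cens,
                    os_years = pmin(t0, cens) + 1e-6, os_event = t0 <= cens,
                    x = x, noise = noise)
  cvX <- bootstrapCV(modelSpec("signal", "x"), tab, B = 20, horizon = 5, seed = 2)
  cvN <- bootstrapCV(modelSpec("noise", "noise"), tab, B = 20, horizon = 5, seed = 2)
  expect_gt(cvX$cv_cindex, cvN$cv_cindex)
  expect_lt(cvX$cv_ibs, cvN$cv_ibs)
})

test_that("external validation is frozen: identical cohort reproduces apparent metrics", {
  tab <- smallAnalysisTable(n = 250, seed = 29)
  fitted <- suppressWarnings(fitModel(cmStratumSpec(), tab))
  appar <- suppressWarnings(mbrisk:::.evalOnRows(fitted$cox$fit, fitted$rows, 5))
  ext <- suppressWarnings(externalValidate(fitted, tab, horizon = 5))
  expect_equal(ext$ibs, appar$ibs, tolerance = 1e-12)
  expect_equal(ext$cindex, appar$cindex, tolerance = 1e-12)
})

test_that("external validation rejects factor levels unseen in discovery", {
  tab <- smallAnalysisTable(n = 300, seed = 33)
  disc <- tab[tab$subgroup != "VIII", ]
  disc$subgroup <- factor(disc$subgroup, levels = setdiff(levels(tab$subgroup), "VIII"))
  fitted <- suppressWarnings(fitModel(modelSpec("sg", c("m_stage", "subgroup")), disc))
  expect_error(externalValidate(fitted, tab, 5), "unseen level.*VIII")
})

test_that("external metrics transfer between exchangeable cohorts", {
  cfgA <- cohortConfig(n_patients = 2000, seed = 41)
  cfgB <- cohortConfig(n_patients = 2000, seed = 42)
  mk <- function(cfg) {
    sim <- generateCohort(cfg)
    calls <- callCohort(renderProfiles(sim$truth, cfg))
    strata <- stratifyCohort(sim$patients, sim$labels, calls)
    assembleAnalysisTable(sim$patients, sim$labels, calls, strata)
  }
  discovery <- mk(cfgA); validation <- mk(cfgB)
  fitted <- fitModel(cmStratumSpec(), discovery)
  appar <- mbrisk:::.evalOnRows(fitted$cox$fit, fitted$rows, 5)
  ext <- externalValidate(fitted, validation, horizon = 5)
  expect_lt(abs(ext$cindex - appar$cindex), 0.05)
})

test_that("model comparison reports every spec and picks the top AUC", {
  tab <- smallAnalysisTable(n = 400, seed = 37)
  cmp <- suppressWarnings(compareModels(
    list(clinicalStratumSpec(), cmStratumSpec()), tab, horizon = 5, B = 0))
  expect_equal(nrow(cmp$metrics), 2L)
  expect_false(any(cmp$metrics$failed))
  # the clinico-molecular strata should dominate the 2-level clinical split
  expect_gt(cmp$metrics$iauc[2], cmp$metrics$iauc[1])
  expect_equal(cmp$best, "clinico-molecular")
  # identical specs give identical metrics
  cmp2 <- suppressWarnings(compareModels(
    list(cmStratumSpec(), cmStratumSpec()), tab, horizon = 5, B = 0))
  expect_equal(cmp2$metrics$iauc[1], cmp2$metrics$iauc[2])
  expect_equal(cmp2$metrics$ibs_apparent[1], cmp2$metrics$ibs_apparent[2])
  expect_error(compareModels(list(cmStratumSpec()), tab), "at least two")
})
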