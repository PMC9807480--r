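test_that("Kaplan-Meier matches hand product-limit computations", {
  # no censoring: empirical survival
  km <- kmEstimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(survivalAt(km, 2.5)$surv, 1 / 3)
  # censored hand example: 6+, 7, 9+, 10, 11+
  km <- kmEstimate(c(6, 7, 9, 10, 11), c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(survivalAt(km, 7)$surv, 3 / 4)
  expect_equal(survivalAt(km, 10)$surv, 3 / 8)
  expect_equal(survivalAt(km, 6.5)$surv, 1)  # before the first event
  # no events at all
  km <- kmEstimate(c(2, 4, 8), c(FALSE, FALSE, FALSE))
  expect_true(all(survivalAt(km, c(1, 5, 10))$surv == 1))
  expect_true(all(survivalAt(km, c(1, 5, 10))$se == 0))
  expect_error(kmEstimate(c(-1, 2), c(TRUE, TRUE)), "positive")
})

test_that("Greenwood variance reduces to S(1-S)/n without censoring", {
  set.seed(4)
  time <- round(stats::rexp(60, 0.2), 3)
  km <- kmEstimate(time, rep(TRUE, 60))
  expect_equal(km$se^2, km$surv * (1 - km$surv) / 60, tolerance = 1e-10)
  # and the KM curve equals the empirical survival function
  emp <- vapply(km$time, function(t) mean(time > t), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("log-rank statistic is null on duplicated groups and errors on one group", {
  time <- c(1, 2, 3, 4, 5)
  ev <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  res <- logrankTest(c(time, time), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_error(logrankTest(time, ev, rep("a", 5)), "2 non-empty groups")
  g3 <- factor(rep(c("a", "b"), c(3, 2)), levels = c("a", "b", "c"))
  expect_error(logrankTest(time, ev, g3), "empty")
})

test_that("log-rank p is consistent with its exhaustive permutation distribution", {
  # n = 6, two groups of three, all events, untied
  time <- c(1, 4, 6, 2, 3, 9)
  ev <- rep(TRUE, 6)
  grp <- rep(c("a", "b"), each = 3)
  obs <- logrankTest(time, ev, grp)
  combos <- utils::combn(6, 3)
  stats_perm <- apply(combos, 2, function(ix) {
    gg <- rep("b", 6); gg[ix] <- "a"
    logrankTest(time, ev, gg)$chi2
  })
  p_perm <- mean(stats_perm >= obs$chi2 - 1e-12)
  # the asymptotic chi-square p approximates the exact permutation p; at n=6
  # the permutation distribution has resolution 1/20
  expect_lt(abs(obs$p - p_perm), 0.15)
  # the observed statistic is a member of its own permutation distribution
  expect_true(any(abs(stats_perm - obs$chi2) < 1e-9))
})

test_that("log-rank equals the squared Cox score test on untied two-group data", {
  set.seed(11)
  time <- round(stats::rexp(40, 0.3), 6)
  while (anyDuplicated(time)) time <- time + stats::runif(40, 0, 1e-4)
  ev <- stats::runif(40) < 0.8
  x <- rep(0:1, 20)
  lr <- logrankTest(time, ev, x)
  fit <- survival::coxph(survival::Surv(time, ev) ~ x)
  expect_equal(lr$chi2, unname(summary(fit)$sctest["test"]), tolerance = 1e-8)
})

test_that("counting-process construction splits at the RT start time", {
  p <- data.frame(patient_id = c("a", "b", "c", "d"),
                  rt_start_years = c(0.25, NA, 6, 0),
                  pfs_years = c(2, 5, 2, 3),
                  pfs_event = c(TRUE, FALSE, TRUE, TRUE),
                  os_years = c(2, 5, 2, 3),
                  os_event = c(TRUE, FALSE, TRUE, TRUE))
  rows <- buildTdDataset(p, "PFS")
  a <- rows[rows$patient_id == "a", ]
  expect_equal(a$start, c(0, 0.25))
  expect_equal(a$stop, c(0.25, 2))
  expect_equal(a$rt, c(0L, 1L))
  expect_equal(a$event, c(FALSE, TRUE))
  b <- rows[rows$patient_id == "b", ]  # no RT, censored
  expect_equal(unlist(b[, c("start", "stop", "rt")], use.names = FALSE), c(0, 5, 0))
  expect_false(b$event)
  cc <- rows[rows$patient_id == "c", ]  # RT after exit never counts
  expect_equal(unlist(cc[, c("start", "stop", "rt")], use.names = FALSE), c(0, 2, 0))
  d <- rows[rows$patient_id == "d", ]  # RT at time zero: exposed throughout
  expect_equal(unlist(d[, c("start", "stop", "rt")], use.names = FALSE), c(0, 3, 1))
  p$pfs_years[1] <- -1
  expect_error(buildTdDataset(p, "PFS"), "positive")
})

test_that("Cox coefficient matches brute-force partial-likelihood maximization", {
  d <- data.frame(patient_id = letters[1:6], rt_start_years = NA_real_,
                  pfs_years = c(1.1, 2.4, 3.2, 4.7, 5.1, 6.3),
                  pfs_event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
                  os_years = c(1.1, 2.4, 3.2, 4.7, 5.1, 6.3),
                  os_event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
                  x = c(0.5, 1.2, -0.3, 0.8, -1.1, 0.2))
  rows <- buildTdDataset(d, "PFS")
  cf <- coxFit(rows, "x")
  beta_hat <- stats::optimize(function(b) bruteCoxLoglik(b, d$pfs_years, d$pfs_event, d$x),
                              c(-8, 8), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(cf$coefficients$coef, beta_hat, tolerance = 1e-6)
  expect_equal(cf$aic, 2 - 2 * cf$loglik)
  expect_equal(cf$coefficients$hr, exp(cf$coefficients$coef))
  # a constant covariate cannot be estimated
  d$x <- 1
  expect_error(coxFit(buildTdDataset(d, "PFS"), "x"), "rank-deficient")
  # no events at all
  d$pfs_event <- FALSE
  expect_error(coxFit(buildTdDataset(d, "PFS"), "x"), "no events")
})

test_that("a trivial counting-process split leaves the Cox fit unchanged", {
  set.seed(6)
  n <- 80
  d <- data.frame(patient_id = sprintf("p%02d", 1:n), rt_start_years = NA_real_,
                  pfs_years = stats::rexp(n, 0.3) + 0.01,
                  pfs_event = stats::runif(n) < 0.7,
                  os_years = 99, os_event = FALSE,
                  x = stats::rnorm(n))
  rows1 <- buildTdDataset(d, "PFS")
  fit1 <- coxFit(rows1, "x")
  # split every subject at an arbitrary interior time
  cut <- pmin(d$pfs_years / 2, 0.5)
  rows2 <- rbind(
    data.frame(patient_id = d$patient_id, start = 0, stop = cut,
               event = FALSE, rt = 0L, x = d$x),
    data.frame(patient_id = d$patient_id, start = cut, stop = d$pfs_years,
               event = d$pfs_event, rt = 0L, x = d$x))
  fit2 <- coxFit(rows2, "x")
  expect_equal(fit1$coefficients$coef, fit2$coefficients$coef, tolerance = 1e-10)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-10)
})

test_that("Pearson chi-square matches hand computation and flags bad tables", {
  same <- rbind(c(30, 60), c(10, 20))  # identical row distributions
  res <- pearsonChisq(same)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  res <- pearsonChisq(rbind(c(10, 20), c(20, 10)))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  # published staging contrast (3 x 2): clearly dependent
  staging <- rbind(c(86, 110), c(12, 90), c(196, 223))
  expect_lt(pearsonChisq(staging)$p, 0.05)
  expect_error(pearsonChisq(rbind(c(0, 0), c(1, 2))), "zero marginal")
  expect_error(pearsonChisq(matrix(1:3, 3, 1)), "2x2")
})

test_that("Cohen's kappa matches its closed form", {
  expect_equal(cohensKappa(diag(c(5, 9, 2))), 1)
  expect_equal(cohensKappa(rbind(c(40, 10), c(10, 40))), 0.6)
  set.seed(2)
  a <- sample(1:3, 1e5, TRUE); b <- sample(1:3, 1e5, TRUE)
  expect_lt(abs(cohensKappa(table(a, b))), 0.02)
  expect_error(cohensKappa(matrix(1:6, 2, 3)), "square")
  # degenerate marginals (all mass in one cell): perfect agreement by definition
  expect_equal(cohensKappa(matrix(c(10, 0, 0, 0), 2, 2)), 1)
})
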