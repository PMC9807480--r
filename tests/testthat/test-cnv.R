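g <- hg19ArmModel()
th <- callingThresholds()

arm7q <- arms(g)[arms(g)$arm == "7q"]
arm11p <- arms(g)[arms(g)$arm == "11p"]

# split an arm interval into two bins at a length fraction
splitArm <- function(armGr, frac, v1, v2) {
  cut <- start(armGr) + round(frac * width(armGr)) - 1
  GRanges(as.character(seqnames(armGr)),
          IRanges(c(start(armGr), cut + 1), c(cut, end(armGr))),
          log2 = c(v1, v2))
}

test_that("baseline is the length-weighted autosomal median", {
  flat <- mkProfile("s", "chr1", 1, 1000, 0)
  expect_equal(estimateBaseline(flat), 0)
  # 90% of profiled genome neutral, 10% at +1 -> baseline stays 0
  p <- mkProfile("s", c("chr1", "chr2"), c(1, 1), c(9000, 1000), c(0, 1))
  expect_equal(estimateBaseline(p), 0)
  # a global shift moves the baseline with it
  shifted <- mkProfile("s", c("chr1", "chr2"), c(1, 1), c(9000, 1000), c(0.1, 1.1))
  expect_equal(estimateBaseline(shifted), 0.1)
  expect_error(estimateBaseline(mkProfile("s", "chrX", 1, 100, 0)),
               "no autosomal bins")
})

test_that("arm status follows the 0.2 / 80%-of-arm rule", {
  # saturated gain: +0.3 across the whole of 7q
  p <- CNProfile("s", GRanges("chr7", IRanges(start(arm7q), end(arm7q)), log2 = 0.3))
  st <- callArmStatus(p, "7q", baseline = 0, thresholds = th, genome = g)
  expect_equal(st$status, "gain")
  expect_equal(st$gain_fraction, 1.0)

  # +0.3 on half the arm length only: 0.5 < 0.8 -> neutral
  p <- CNProfile("s", splitArm(arm7q, 0.5, 0.3, 0))
  st <- callArmStatus(p, "7q", 0, th, g)
  expect_equal(st$status, "neutral")
  expect_equal(st$gain_fraction, 0.5, tolerance = 1e-6)

  # -0.25 on 90% of 11p -> loss with fraction 0.9
  p <- CNProfile("s", splitArm(arm11p, 0.9, -0.25, 0))
  st <- callArmStatus(p, "11p", 0, th, g)
  expect_equal(st$status, "loss")
  expect_equal(st$loss_fraction, 0.9, tolerance = 1e-6)

  # no bins on the arm: missing-data outcome, not neutral
  p <- mkProfile("s", "chr1", 1, 1000, 0)
  st <- callArmStatus(p, "7q", 0, th, g)
  expect_true(is.na(st$status))
  expect_equal(st$n_bins, 0L)
})

test_that("arm fractions agree with a per-basepair oracle on a toy genome", {
  tg <- toyGenome()
  armAq <- arms(tg)[arms(tg)$arm == "Aq"]
  set.seed(91)
  for (rep in 1:5) {
    # random small bins over chrA, values near the thresholds
    starts <- sort(sample(seq(1, 2500, by = 37), 40))
    ends <- pmin(starts + sample(10:60, 40, TRUE), 2600)
    keep <- c(TRUE, ends[-40] < starts[-1])  # drop overlaps
    gr <- GRanges("chrA", IRanges(starts[keep], ends[keep]),
                  log2 = round(stats::runif(sum(keep), -0.5, 0.5), 2))
    p <- CNProfile("s", gr)
    st <- callArmStatus(p, "Aq", baseline = 0.05, thresholds = th, genome = tg)
    oracle <- bpArmFractions(p, armAq, baseline = 0.05, arm_log2 = th$arm_log2)
    expect_equal(st$gain_fraction, unname(oracle["gain"]), tolerance = 1e-12)
    expect_equal(st$loss_fraction, unname(oracle["loss"]), tolerance = 1e-12)
  }
})

test_that("amplification calling uses the locus median against baseline + 0.4", {
  myc <- loci(g)["MYC"]
  mkLocus <- function(v, baselineBins = 0) {
    CNProfile("s", GRanges(c("chr8", "chr1"),
                           IRanges(c(start(myc) - 100, 1), c(end(myc) + 100, 1e6)),
                           log2 = c(v, baselineBins)))
  }
  expect_true(callAmplification(mkLocus(1.5), "MYC", 0, th, g))
  expect_false(callAmplification(mkLocus(0.3), "MYC", 0, th, g))
  # 0.45 at MYCN inside a +0.25 2p gain, baseline 0: 0.45 >= 0.4 -> amplified
  mycn <- loci(g)["MYCN"]
  arm2p <- arms(g)[arms(g)$arm == "2p"]
  bins <- GRanges(c("chr2", "chr2", "chr2"),
                  IRanges(c(start(arm2p), start(mycn), end(mycn) + 1),
                          c(start(mycn) - 1, end(mycn), end(arm2p))),
                  log2 = c(0.25, 0.45, 0.25))
  expect_true(callAmplification(CNProfile("s", bins), "MYCN", 0, th, g))
  # no bin overlaps the locus -> missing outcome
  expect_true(is.na(callAmplification(mkProfile("s", "chr1", 1, 100, 0), "MYC", 0, th, g)))
})

test_that("sample-level calls derive WCA, phenotype, i17q and amplifications", {
  cfg <- cohortConfig(n_patients = 1, noise_sd = 0)
  tr <- data.frame(patient_id = "s1", chr7_gain = TRUE, chr8_loss = FALSE,
                   chr11_loss = TRUE, i17q = FALSE, myc_amp = FALSE,
                   mycn_amp = FALSE)
  mc <- callSample(renderProfile(tr, cfg, g), g, th)
  expect_equal(mc@wcaCount, 2L)
  expect_equal(mc@wcaPhenotype, "FR")
  expect_false(mc@i17q)

  flat <- data.frame(patient_id = "s2", chr7_gain = FALSE, chr8_loss = FALSE,
                     chr11_loss = FALSE, i17q = FALSE, myc_amp = FALSE,
                     mycn_amp = FALSE)
  mc <- callSample(renderProfile(flat, cfg, g), g, th)
  expect_equal(mc@wcaCount, 0L)
  expect_equal(mc@wcaPhenotype, "SR")
  expect_false(any(armCalls(mc)$status != "neutral"))
  expect_false(mc@i17q || mc@mycAmp || mc@mycnAmp)
})

test_that("i17q requires 17p loss AND 17q gain (all 4 combinations)", {
  arm17p <- arms(g)[arms(g)$arm == "17p"]
  arm17q <- arms(g)[arms(g)$arm == "17q"]
  for (pLoss in c(FALSE, TRUE)) for (qGain in c(FALSE, TRUE)) {
    bins <- GRanges(c("chr17", "chr17", "chr1"),
                    IRanges(c(start(arm17p), start(arm17q), 1),
                            c(end(arm17p), end(arm17q), 2e8)),
                    log2 = c(if (pLoss) -0.3 else 0, if (qGain) 0.3 else 0, 0))
    mc <- callSample(CNProfile("s", bins), g, th)
    expect_equal(mc@i17q, pLoss && qGain,
                 info = sprintf("17p loss=%s, 17q gain=%s", pLoss, qGain))
  }
})

test_that("calls are invariant to a uniform baseline shift", {
  cfg <- cohortConfig(n_patients = 12, seed = 31, noise_sd = 0.05)
  tr <- randomTruth(12, 31)
  se <- renderProfiles(tr, cfg, g, seed = 99)
  shifted <- se
  SummarizedExperiment::assay(shifted, "log2") <-
    SummarizedExperiment::assay(se, "log2") + 0.1
  c1 <- callCohort(se, g, th)
  c2 <- callCohort(shifted, g, th)
  expect_equal(c2$baseline, c1$baseline + 0.1, tolerance = 1e-9)
  c2$baseline <- c1$baseline
  expect_identical(c1, c2)
})

test_that("matrix and per-sample calling paths agree", {
  cfg <- cohortConfig(n_patients = 8, seed = 8, noise_sd = 0.1, bin_size_bp = 4e6)
  tr <- randomTruth(8, 8)
  se <- renderProfiles(tr, cfg, g, seed = 8)
  fast <- callCohort(se, g, th)
  slow <- callCohort(lapply(seq_len(ncol(se)), function(j) profileFromSE(se, j)),
                     g, th)
  expect_equal(fast, slow, tolerance = 1e-12)
})
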