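#' Calling thresholds for copy-number interpretation
#'
#' The published rule set: an amplification needs a log2 ratio of at least
#' \code{amp_log2} above baseline, an arm gain/loss needs at least
#' \code{arm_log2} deviation over at least \code{arm_fraction} of the
#' (profiled) arm length.  Comparisons are closed (\code{>=}) exactly as the
#' thresholds are stated.
#'
#' @param amp_log2 amplification threshold (default 0.4).
#' @param arm_log2 arm gain/loss threshold (default 0.2).
#' @param arm_fraction minimum affected fraction of the arm (default 0.8).
#' @param baseline_estimator \code{"median"} (length-weighted median) or
#'   \code{"trimmed_mean"} (length-weighted 25\%-trimmed mean).
#' @param full_arm_denominator if TRUE, fractions are relative to the full arm
#'   length rather than the profiled arm length.
#' @return list of class \code{callingThresholds}
#' @export
callingThresholds <- function(amp_log2 = 0.4, arm_log2 = 0.2, arm_fraction = 0.8,
                              baseline_estimator = c("median", "trimmed_mean"),
                              full_arm_denominator = FALSE) {
  baseline_estimator <- match.arg(baseline_estimator)
  if (!(amp_log2 > arm_log2 && arm_log2 > 0)) {
    mbStop("callingThresholds: need amp_log2 > arm_log2 > 0")
  }
  if (!(arm_fraction > 0 && arm_fraction <= 1)) {
    mbStop("callingThresholds: arm_fraction must be in (0, 1]")
  }
  structure(list(amp_log2 = amp_log2, arm_log2 = arm_log2,
                 arm_fraction = arm_fraction,
                 baseline_estimator = baseline_estimator,
                 full_arm_denominator = full_arm_denominator),
            class = "callingThresholds")
}

#' Estimate the diploid baseline of a profile
#'
#' Length-weighted median (or trimmed mean) of the autosomal log2 ratios.  A
#' uniform shift of the whole profile shifts the baseline identically, so
#' calls are invariant to global offsets; the median is robust to up to half
#' of the genome being aberrant.
#'
#' @param profile a \linkS4class{CNProfile}
#' @param thresholds a \code{\link{callingThresholds}} object
#' @return numeric baseline log2 ratio
#' @export
estimateBaseline <- function(profile, thresholds = callingThresholds()) {
  b <- profileBins(profile)
  b <- b[as.character(seqnames(b)) %in% paste0("chr", 1:22)]
  if (length(b) == 0L) mbStop("estimateBaseline: profile has no autosomal bins")
  if (thresholds$baseline_estimator == "median") {
    weightedMedian(b$log2, width(b))
  } else {
    w <- width(b)
    qs <- stats::quantile(rep(b$log2, times = pmax(1L, round(w / min(w)))),
                          c(0.25, 0.75), names = FALSE, type = 1)
    keep <- b$log2 >= qs[1] & b$log2 <= qs[2]
    sum(b$log2[keep] * w[keep]) / sum(w[keep])
  }
}

.armRange <- function(genome, arm) {
  a <- arms(genome)
  hit <- a[a$arm == arm]
  if (length(hit) != 1L) mbStop(sprintf("unknown arm '%s'", arm))
  hit
}

#' Call gain/loss status of one chromosome arm
#'
#' Bins overlapping the arm are clipped to the arm boundaries; the gain
#' (loss) fraction is the length-weighted fraction of profiled arm bases with
#' log2 ratio at least \code{arm_log2} above (below) baseline.  An arm is
#' called gained (lost) when the fraction reaches \code{arm_fraction}.
#'
#' @param profile a \linkS4class{CNProfile}
#' @param arm arm identifier, e.g. \code{"17q"}
#' @param baseline baseline log2 ratio (see \code{\link{estimateBaseline}})
#' @param thresholds a \code{\link{callingThresholds}} object
#' @param genome a \linkS4class{GenomeModel}
#' @return list with \code{arm}, \code{status} (\code{"gain"}, \code{"loss"},
#'   \code{"neutral"}, or \code{NA} when no bins cover the arm),
#'   \code{gain_fraction}, \code{loss_fraction}, \code{mean_log2}, \code{n_bins}
#' @export
callArmStatus <- function(profile, arm, baseline = 0,
                          thresholds = callingThresholds(),
                          genome = hg19ArmModel()) {
  ar <- .armRange(genome, arm)
  b <- profileBins(profile)
  hits <- findOverlaps(b, ar)
  if (length(hits) == 0L) {
    return(list(arm = arm, status = NA_character_, gain_fraction = NA_real_,
                loss_fraction = NA_real_, mean_log2 = NA_real_, n_bins = 0L))
  }
  bb <- pintersect(b[queryHits(hits)], rep(ar, length(hits)))
  w <- width(bb)
  dev <- bb$log2 - baseline
  denom <- if (thresholds$full_arm_denominator) width(ar) else sum(w)
  gf <- sum(w[dev >= thresholds$arm_log2]) / denom
  lf <- sum(w[dev <= -thresholds$arm_log2]) / denom
  status <- if (gf >= thresholds$arm_fraction) "gain"
            else if (lf >= thresholds$arm_fraction) "loss" else "neutral"
  list(arm = arm, status = status, gain_fraction = gf, loss_fraction = lf,
       mean_log2 = sum(bb$log2 * w) / sum(w), n_bins = length(bb))
}

#' Call focal amplification at a named locus
#'
#' The length-weighted median log2 ratio of the bins overlapping the locus is
#' compared against \code{baseline + amp_log2} (closed comparison).  The
#' locus median, not the single maximal bin, is used for noise robustness.
#'
#' @param profile a \linkS4class{CNProfile}
#' @param locus a GRanges of length 1, or the name of a genome-model locus
#' @param baseline baseline log2 ratio
#' @param thresholds a \code{\link{callingThresholds}} object
#' @param genome a \linkS4class{GenomeModel}
#' @return TRUE/FALSE, or NA when no bin overlaps the locus
#' @export
callAmplification <- function(profile, locus, baseline = 0,
                              thresholds = callingThresholds(),
                              genome = hg19ArmModel()) {
  if (is.character(locus)) {
    if (!locus %in% names(loci(genome))) mbStop(sprintf("unknown locus '%s'", locus))
    locus <- loci(genome)[locus]
  }
  b <- profileBins(profile)
  hits <- findOverlaps(b, locus)
  if (length(hits) == 0L) return(NA)
  bb <- pintersect(b[queryHits(hits)], rep(locus, length(hits)))
  weightedMedian(bb$log2, width(bb)) >= baseline + thresholds$amp_log2
}

#' Molecular calls for one sample
#'
#' Arm statuses plus the derived flags: whole-chromosomal aberrations
#' (chr7 gain, chr8 loss, chr11 loss — each requires both arms), the WCA
#' phenotype (favorable risk \code{"FR"} when at least two of the three WCA
#' markers are present, else \code{"SR"}), isochromosome 17q (17p loss and
#' 17q gain), and MYC/MYCN amplification.
#'
#' @slot sampleId sample identifier.
#' @slot armCalls data.frame of per-arm calls.
#' @slot chr7Gain,chr8Loss,chr11Loss,i17q,mycAmp,mycnAmp logical flags.
#' @slot wcaCount integer count of WCA markers (0-3).
#' @slot wcaPhenotype \code{"FR"} or \code{"SR"}.
#' @slot baseline numeric baseline used.
#' @export
setClass("MolecularCalls",
  representation(sampleId = "character", armCalls = "data.frame",
    chr7Gain = "logical", chr8Loss = "logical", chr11Loss = "logical",
    wcaCount = "integer", wcaPhenotype = "character", i17q = "logical",
    mycAmp = "logical", mycnAmp = "logical", baseline = "numeric"))

#' @export
setMethod("show", "MolecularCalls", function(object) {
  cat(sprintf(
    "MolecularCalls '%s': WCA %s (chr7+ %s, chr8- %s, chr11- %s), i17q %s, MYC %s, MYCN %s\n",
    object@sampleId, object@wcaPhenotype, object@chr7Gain, object@chr8Loss,
    object@chr11Loss, object@i17q, object@mycAmp, object@mycnAmp))
})

#' @describeIn MolecularCalls one-row data.frame of the sample-level flags
#' @param x a MolecularCalls object
#' @param row.names,optional,... ignored, for generic consistency
#' @export
as.data.frame.MolecularCalls <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(sample_id = x@sampleId, baseline = x@baseline,
    chr7_gain = x@chr7Gain, chr8_loss = x@chr8Loss, chr11_loss = x@chr11Loss,
    wca_count = x@wcaCount, wca_phenotype = x@wcaPhenotype, i17q = x@i17q,
    myc_amp = x@mycAmp, mycn_amp = x@mycnAmp, stringsAsFactors = FALSE)
}

#' Per-arm calls of a MolecularCalls object
#' @param x a MolecularCalls object
#' @export
armCalls <- function(x) x@armCalls

.wcaFromArms <- function(status) {
  st <- function(a) status[[a]]
  eq <- function(a, v) !is.na(st(a)) & st(a) == v
  chr7 <- eq("7p", "gain") & eq("7q", "gain")
  chr8 <- eq("8p", "loss") & eq("8q", "loss")
  chr11 <- eq("11p", "loss") & eq("11q", "loss")
  i17 <- eq("17p", "loss") & eq("17q", "gain")
  n <- as.integer(chr7) + as.integer(chr8) + as.integer(chr11)
  list(chr7_gain = chr7, chr8_loss = chr8, chr11_loss = chr11,
       wca_count = n, wca_phenotype = ifelse(n >= 2L, "FR", "SR"), i17q = i17)
}

#' Full molecular calling for one sample
#'
#' Estimates the baseline, calls every arm of the genome model, derives the
#' WCA markers and phenotype, i17q, and MYC/MYCN amplification.
#'
#' @param profile a \linkS4class{CNProfile}
#' @param genome a \linkS4class{GenomeModel}
#' @param thresholds a \code{\link{callingThresholds}} object
#' @return a \linkS4class{MolecularCalls}
#' @export
callSample <- function(profile, genome = hg19ArmModel(),
                       thresholds = callingThresholds()) {
  bl <- estimateBaseline(profile, thresholds)
  ac <- lapply(armNames(genome), function(a)
    callArmStatus(profile, a, bl, thresholds, genome))
  acdf <- do.call(rbind, lapply(ac, function(x)
    data.frame(arm = x$arm, status = x$status, gain_fraction = x$gain_fraction,
               loss_fraction = x$loss_fraction, mean_log2 = x$mean_log2,
               n_bins = x$n_bins, stringsAsFactors = FALSE)))
  status <- stats::setNames(acdf$status, acdf$arm)
  w <- .wcaFromArms(as.list(status))
  myc <- if ("MYC" %in% names(loci(genome)))
    callAmplification(profile, "MYC", bl, thresholds, genome) else NA
  mycn <- if ("MYCN" %in% names(loci(genome)))
    callAmplification(profile, "MYCN", bl, thresholds, genome) else NA
  new("MolecularCalls", sampleId = sampleId(profile), armCalls = acdf,
      chr7Gain = w$chr7_gain, chr8Loss = w$chr8_loss, chr11Loss = w$chr11_loss,
      wcaCount = w$wca_count, wcaPhenotype = w$wca_phenotype, i17q = w$i17q,
      mycAmp = as.logical(myc), mycnAmp = as.logical(mycn), baseline = bl)
}

#' Molecular calling for a whole cohort
#'
#' Accepts either a list of \linkS4class{CNProfile}s (looped through
#' \code{\link{callSample}}) or a \code{RangedSummarizedExperiment} of
#' bins x samples with assay \code{log2} (as produced by
#' \code{\link{renderProfiles}}), for which a vectorised matrix path computes
#' identical calls orders of magnitude faster.
#'
#' @param x list of CNProfile, or RangedSummarizedExperiment with assay "log2"
#' @param genome a \linkS4class{GenomeModel}
#' @param thresholds a \code{\link{callingThresholds}} object
#' @return data.frame, one row per sample, with columns \code{sample_id},
#'   \code{baseline}, \code{chr7_gain}, \code{chr8_loss}, \code{chr11_loss},
#'   \code{wca_count}, \code{wca_phenotype}, \code{i17q}, \code{myc_amp},
#'   \code{mycn_amp}
#' @export
callCohort <- function(x, genome = hg19ArmModel(), thresholds = callingThresholds()) {
  if (is.list(x)) {
    out <- do.call(rbind, lapply(x, function(p)
      as.data.frame(callSample(p, genome, thresholds))))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(methods::is(x, "RangedSummarizedExperiment"))
  bins <- SummarizedExperiment::rowRanges(x)
  X <- SummarizedExperiment::assay(x, "log2")
  w <- width(bins)
  auto <- as.character(seqnames(bins)) %in% paste0("chr", 1:22)
  Xa <- X[auto, , drop = FALSE]
  wa <- w[auto]
  bl <- vapply(seq_len(ncol(Xa)), function(j) weightedMedian(Xa[, j], wa),
               numeric(1))

  # per-(bin, arm) assignment with clipped weights
  a <- arms(genome)
  hits <- findOverlaps(bins, a)
  bi <- queryHits(hits); ai <- subjectHits(hits)
  wov <- width(pintersect(bins[bi], a[ai]))
  armv <- a$arm[ai]
  tot <- if (thresholds$full_arm_denominator) {
    stats::setNames(width(a), a$arm)[sort(unique(armv))]
  } else {
    tapply(wov, armv, sum)
  }
  Xbi <- X[bi, , drop = FALSE]
  dev <- Xbi - rep(bl, each = nrow(Xbi))
  gainLen <- rowsum((dev >= thresholds$arm_log2) * wov, group = armv)
  lossLen <- rowsum((dev <= -thresholds$arm_log2) * wov, group = armv)
  gf <- gainLen / as.numeric(tot[rownames(gainLen)])
  lf <- lossLen / as.numeric(tot[rownames(lossLen)])
  statusOf <- function(arm) {
    g <- gf[arm, ]; l <- lf[arm, ]
    ifelse(g >= thresholds$arm_fraction, "gain",
      ifelse(l >= thresholds$arm_fraction, "loss", "neutral"))
  }
  st <- lapply(stats::setNames(nm = rownames(gf)), statusOf)
  wca <- .wcaFromArms(st)

  ampAt <- function(name) {
    if (!name %in% names(loci(genome))) return(rep(NA, ncol(X)))
    lc <- loci(genome)[name]
    h <- findOverlaps(bins, lc)
    if (length(h) == 0L) return(rep(NA, ncol(X)))
    idx <- queryHits(h)
    wl <- width(pintersect(bins[idx], rep(lc, length(idx))))
    med <- apply(X[idx, , drop = FALSE], 2L, weightedMedian, w = wl)
    med >= bl + thresholds$amp_log2
  }
  data.frame(sample_id = colnames(x), baseline = as.numeric(bl),
    chr7_gain = wca$chr7_gain, chr8_loss = wca$chr8_loss,
    chr11_loss = wca$chr11_loss, wca_count = wca$wca_count,
    wca_phenotype = wca$wca_phenotype, i17q = wca$i17q,
    myc_amp = ampAt("MYC"), mycn_amp = ampAt("MYCN"),
    stringsAsFactors = FALSE, row.names = NULL)
}
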