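---
title: "Clinico-molecular risk stratification for Group 3/4 medulloblastoma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinico-molecular risk stratification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbrisk)
```

## Scope and rationale

Non-WNT/non-SHH (Group 3/4) medulloblastoma spans a wide prognostic range
that clinical staging alone captures poorly. Two molecular layers sharpen
it: DNA-methylation subgroups I–VIII, and the whole-chromosomal aberration
(WCA) signature — gain of chromosome 7, loss of chromosome 8, loss of
chromosome 11. `mbrisk` implements the full analysis chain that turns these
layers into a risk model and quantifies what they add: copy-number calling
from binned log2 ratios, rule-based stratification, and survival-model
comparison. Because patient-level data of this kind are not publicly
distributable, the package also ships a calibrated synthetic cohort
generator so that every stage is exercised end to end by tests rather than
by a frozen dataset.

## Copy-number calling

Input is one log2 copy-number ratio per genomic bin or segment per sample
(the kind of profile produced by methylation-array CNV tools), held in a
`GRanges`-backed `CNProfile` or, for whole cohorts, a
`RangedSummarizedExperiment` of bins × samples. Calling is deterministic
and threshold-based, replacing the visual inspection used when such calls
are made by eye; the thresholds are the ones conventionally printed with
such calls, applied as closed (≥) comparisons:

* **Baseline.** Length-weighted median of all autosomal bins. A uniform
  shift of the whole profile moves the baseline identically, so calls are
  invariant to global offsets; the median tolerates up to half the genome
  being aberrant. Sex chromosomes are excluded so the estimate does not
  depend on patient sex. A trimmed-mean alternative is available via
  `callingThresholds(baseline_estimator = "trimmed_mean")`.
* **Arm gain/loss.** An arm is gained (lost) when bins covering at least
  80% of the *profiled* arm length deviate by at least +0.2 (−0.2) from
  baseline. The denominator is the profiled arm length because array bins
  never tile an arm completely; `full_arm_denominator = TRUE` switches to
  the full arm length.
* **Amplification.** The length-weighted median log2 of the bins
  overlapping the *MYC* (8q24) or *MYCN* (2p24) locus must reach baseline
  + 0.4. The locus median, not the maximal bin, is used for noise
  robustness.
* **Derived flags.** chr7 gain requires both 7p and 7q gained; chr8/chr11
  loss require both arms lost; WCA phenotype is favorable risk (FR) with ≥ 2
  of the three markers, standard risk (SR) otherwise; i17q is 17p loss
  together with 17q gain.

Arms with no covering bins yield an explicit missing status, never a
neutral call. The genome model is an hg19 arm table derived from the UCSC
cytoband/gap coordinates (centromeres excluded, acrocentric p-arms
flagged); any other build can be supplied as a `GenomeModel` or read from a
BED file. Internally all intervals are `GRanges` (1-based, closed), the
Bioconductor convention; SEG files (1-based inclusive) map onto it directly
and binned TSV/BED files (0-based half-open) are converted at the file
boundary.

## Risk stratification

Two nested rule sets, both pure functions of the patient's covariates:

* **Clinical (SR/HR).** Standard risk requires age ≥ 4 years at diagnosis,
  M0, complete resection (residual < 1.5 cm², "R0"), non-anaplastic
  histology, no *MYC* amplification, and no *MYCN* amplification unless the
  tumor is Group 4. Any failed condition gives high risk. The published
  wording "older than 4 years" is implemented as age ≥ 4.0, matching the
  cohort tables' category boundary; the cut is a parameter. Desmoplastic
  histology counts as non-anaplastic, since only large-cell/anaplastic
  histology is exclusionary.
* **Clinico-molecular (LR/SR/HR/VHR).** Within clinical SR, subgroup VII
  and/or WCA-FR demote to low risk; within clinical HR, subgroups II, III
  or V promote to very high risk. By construction no clinical-HR patient
  can reach LR and no clinical-SR patient can reach VHR. Whether a
  clinical-HR patient with subgroup VII/WCA-FR could ever be demoted is not
  settled in the literature this rule set comes from; the implementation
  adopts the strict reading (no demotion), which the flow-constraint tests
  pin down.

Patients whose classifier scores fail the eligibility thresholds (≥ 0.9
methylation class family, ≥ 0.8 group, ≥ 0.8 subgroup, all closed) are kept
with the sentinel stratum `"unclassifiable"` rather than dropped, since a
deployable stratification scheme has to account for them. Missing
covariates propagate as missing outcomes; nothing is imputed.

## Survival machinery

Kaplan–Meier estimation, log-rank testing, and Cox regression are delegated
to the `survival` package behind thin, typed wrappers. Conventions:

* Time unit is years since first tumor surgery. PFS events are progression,
  relapse, or death from any cause; OS events are deaths.
* The "± SD" displayed with survival rates is the Greenwood standard error
  of the Kaplan–Meier estimate — the quantity survival software displays —
  set to 0 once the curve reaches zero.
* Craniospinal irradiation is a time-dependent exposure:
  `buildTdDataset()` splits each irradiated patient into an unexposed
  (0, t~RT~] and an exposed (t~RT~, T] counting-process row. RT at or after
  exit never counts; RT at time zero means exposed throughout.
* Cox models use Efron tie handling (the ecosystem default; switchable),
  Wald 95% intervals on the log-hazard scale, and report AIC = 2k − 2ℓ,
  Harrell concordance, and the global score test. A constant or aliased
  covariate is an explicit error rather than a silent NA coefficient.
* No multiple-testing adjustment is applied anywhere, deliberately.

## Model evaluation

The model-comparison layer is implemented in the package itself:

* **Incident/dynamic AUC.** At each event time, the probability that the
  failing subject's linear predictor exceeds that of a random at-risk
  subject (ties ½), with risk sets honouring counting-process intervals so
  time-dependent covariates contribute row-level predictors. The integrated
  AUC is the event-count-weighted mean up to the horizon. The phrase "ROC
  AUC at five years" is ambiguous between AUC(5) and the integrated value;
  both are reported and the integrated value is primary.
* **Prediction-error curves.** The Graf IPCW Brier estimator: subjects
  failed by *t* contribute S(t)² weighted by 1/G(T−), subjects still under
  observation contribute (1 − S(t))² weighted by 1/G(t), subjects censored
  before *t* contribute zero; G is the marginal Kaplan–Meier of the
  censoring distribution (covariate-conditional weighting is out of scope).
  The evaluation grid is all event times up to the horizon plus the horizon;
  the integrated Brier score is the trapezoid time-average normalized by the
  horizon. A censoring survival of zero at a required time is an error that
  names the time.
* **Predicted curves under time-dependent covariates.** Per-subject
  survival is exp of minus the accumulated baseline hazard along the
  subject's own covariate path: each counting-process row contributes
  exp(lp) · [H₀(min(t, stop)) − H₀(start)]₊.
* **Bootstrap cross-validation.** Resample patients with replacement, refit
  everything including the counting-process construction, evaluate IBS and
  concordance on the out-of-bag patients, and average. Out-of-bag
  evaluation is the simplest scheme consistent with bootstrap
  cross-validation; .632-type corrections are deliberately not applied.
  Replicates with no events or a degenerate design are skipped and counted,
  with a warning above 5%. Everything is reproducible from one seed.
* **External validation.** Models fitted on the discovery cohort are frozen
  and applied to the validation cohort; factor levels unseen at training
  time raise an error listing them. Whether concordance "at 5 years"
  truncates comparable pairs at the horizon is not standardized, so both
  the truncated and untruncated versions are computed.
* **Model selection.** `compareModels()` fits every specification on the
  same counting-process data and declares the highest integrated AUC the
  best model. The clinico-molecular stratum enters models as a 4-level
  factor with LR as reference.

## The synthetic cohort generator

`cohortConfig()`/`generateCohort()` emulate the structure of a discovery
cohort of 294 Group 3/4 medulloblastomas:

* Subgroup frequencies default to the published cohort composition;
  subgroup-conditional M+ rates are anchored at the printed extremes
  (72.5% for III, 80.8% for V, 48.3% for IV) with the remaining subgroups
  chosen once so the marginal M+ rate is ≈ 66.7%. MYC amplification
  concentrates in subgroups II/III, MYCN in V/VI, WCA markers in IV/VI/VII,
  matching the reported association patterns. Subgroups II–IV map to
  Group 3; I and V–VIII map to Group 4, with VIII mostly-but-not-exclusively
  Group 4 (default 90%, configurable), as observed.
* Survival is exponential per true clinico-molecular stratum, calibrated so
  S(5) equals the configured 5-year PFS target (defaults 0.94 / 0.65 /
  0.62 / 0.29 for LR/SR/HR/VHR; the LR and VHR anchors are printed values,
  the SR/HR defaults follow the reported ≈ 65% CM-SR survival and the
  observation that CM-HR is comparable). A single-rate exponential is the
  simplest model consistent with calibrating to one printed time point.
  Death time is progression time plus an exponential post-progression
  delay whose rate is solved (hypoexponential closed form) so that marginal
  S~OS~(5) hits the OS target; when the OS target does not exceed the PFS
  target the delay is zero.
* Censoring is independent of the event process: a configurable fraction
  receives a uniform early-censoring time on (0, followup~max~), the rest
  are administratively censored at followup~max~ (default 12 years). The
  source cohorts do not state their censoring or accrual pattern, so this
  is a convention, not a reconstruction.
* Radiotherapy: patients ≥ 4 years follow primary-CSI therapy with RT
  starting 0.25 years after surgery; infants follow radiation-sparing
  therapy, with a salvage fraction (default 15%) receiving late RT between
  0.5 and 3 years. The offset is invented — its purpose is to create
  genuine time-dependence that exercises the counting-process machinery,
  not to model RT scheduling.
* Profiles are rendered by tiling arms at 1 Mb (configurable), shifting
  bins inside planted aberrations by +0.35 (gain), −0.35 (loss) or +1.0
  (amplification) and adding i.i.d. Gaussian noise (default SD 0.1). These
  effect sizes put the signal-to-threshold margin (0.15 per bin) at 1.5
  noise SDs, which reproduces the regime where calling is reliable but not
  trivial. i17q is planted at its marginal frequency so the i17q caller is
  exercised end to end.

What the generator deliberately does **not** emulate: probe-level
methylation data, segmentation artefacts, wavy baselines or GC effects,
polyploidy (where a diploid baseline is genuinely ambiguous), subclonal
aberrations, informative censoring, and relapse-salvage dynamics. Passing
tests therefore demonstrate the correctness of the calling rules,
stratification logic and evaluation statistics — not robustness to every
artefact of real array data, which is why amplification calls in practice
still warrant orthogonal validation (e.g. FISH).

## Numerical choices and degenerate inputs

* Weighted medians are lower weighted medians (smallest value whose
  cumulative weight reaches half the total); fraction comparisons are
  closed, mirroring the ≥ thresholds.
* With strata that have near-zero event counts (the LR stratum in small
  cohorts), Cox coefficients can diverge (monotone likelihood); `survival`
  issues its standard warning, predictions remain usable (S ≈ 1 for the
  affected stratum), and bootstrap replicates that fail outright are
  skipped and counted.
* `brierCurve` refuses grids where the censoring KM is zero while subjects
  are still being weighted; `integratedBrier` refuses horizons beyond the
  grid.
* Profile bins must be non-overlapping within a chromosome and finite;
  readers reject malformed rows naming file, row and field, rather than
  coercing.

## Problem sizes used by the test suite

The suite validates estimators against brute-force oracles at small n
(exhaustive permutation at n = 6, risk-set pair counting at n = 8,
per-basepair arm fractions on a toy genome), convergence properties at
n = 10⁴ (generator marginals, Kolmogorov distance of survival times), Cox
parameter recovery over 200 replicates at n = 2000 with the time-dependent
RT covariate active, and the end-to-end discrimination claim — the
clinico-molecular model beating the clinical model on out-of-bag IBS and
concordance — over 50 pipeline repetitions at n = 2000 with 50 bootstrap
resamples each. These sizes were chosen as the smallest at which the
corresponding Monte-Carlo tolerances (±0.02 on frequencies, ±0.03 on the
null AUC, ±0.1 on log-hazard recovery) are comfortably stable.

## Known limitations

* The deterministic fraction rule is a reproducible surrogate for manual
  calling; concordance with any individual reviewer's visual calls is not
  knowable from thresholds alone.
* Whether the 80% rule should be assessed against full or profiled arm
  length is unstated in the source material; profiled length is the
  default and the alternative is a switch.
* "Clearly distinct from baseline" for amplifications is operationalized
  as the same ≥ 0.4 margin; a sample passing 0.4 that a reviewer would
  reject cannot be distinguished here.
* The generator's stratum-specific hazards make the clinico-molecular
  stratum prognostic *by construction*; the end-to-end discrimination test
  therefore validates the machinery (calling → stratification → evaluation
  ordering), not the clinical effect size itself, which only real cohorts
  can establish.
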