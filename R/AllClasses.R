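#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' SurvCohort: expression plus recurrence-free survival
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] whose single assay
#' holds z-scored expression (genes in rows, samples in columns) and whose
#' `colData` carries the per-sample survival outcome (`time` in months,
#' `event` 0/1) and optional clinical covariates (`age`, `gs`, `t_category`,
#' `ipsa`, `therapy`).
#'
#' @seealso [SurvCohort()] for the validating constructor,
#'   [screenGenes()] for the genome-wide cutpoint screen.
#' @export
setClass("SurvCohort", contains = "SummarizedExperiment")

setValidity("SurvCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  msgs <- character()
  if (!all(c("time", "event") %in% colnames(cd))) {
    return("colData must contain 'time' and 'event' columns")
  }
  time <- cd$time
  event <- cd$event
  if (anyNA(time) || anyNA(event)) {
    msgs <- c(msgs, "'time' and 'event' must not contain NA")
  } else {
    if (any(time < 0)) msgs <- c(msgs, "'time' must be >= 0")
    if (!all(event %in% c(0, 1))) msgs <- c(msgs, "'event' must be 0 or 1")
  }
  if (anyDuplicated(colnames(object))) {
    msgs <- c(msgs, "sample identifiers must be unique")
  }
  if (anyDuplicated(rownames(object))) {
    msgs <- c(msgs, "gene symbols must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of a survival function under right censoring,
#' evaluated at every distinct observed time. `survival` steps down only at
#' event times; censoring times are retained so curves can be exported and
#' plotted with the at-risk counts the estimate used.
#'
#' @slot time distinct observed times (months), increasing.
#' @slot survival estimated survival probability at each time.
#' @slot atRisk number at risk just before each time.
#' @slot nEvents events at each time.
#' @slot nCensored censorings at each time.
#' @export
setClass("KMCurve", representation(
  time = "numeric",
  survival = "numeric",
  atRisk = "integer",
  nEvents = "integer",
  nCensored = "integer"
))

setValidity("KMCurve", function(object) {
  n <- length(object@time)
  if (length(object@survival) != n || length(object@atRisk) != n ||
      length(object@nEvents) != n || length(object@nCensored) != n) {
    return("all slots must have equal length")
  }
  if (n > 0) {
    if (is.unsorted(object@time, strictly = TRUE)) {
      return("'time' must be strictly increasing")
    }
    if (any(diff(object@survival) > 1e-12)) {
      return("'survival' must be non-increasing")
    }
    if (any(object@survival > 1 + 1e-12) || any(object@survival < -1e-12)) {
      return("'survival' must lie in [0, 1]")
    }
    if (any(diff(object@atRisk) > 0L)) {
      return("'atRisk' must be non-increasing")
    }
  }
  TRUE
})

#' Cox proportional hazards fit
#'
#' Result of maximizing the Cox partial likelihood by Newton-Raphson
#' (Efron tie correction by default). Hazard ratios are `exp(beta)` with
#' Wald 95% confidence intervals and Wald p-values; `pAdjusted` carries the
#' Bonferroni correction across the model's covariates.
#'
#' @slot coefficients named log hazard ratios.
#' @slot se standard errors (inverse observed information).
#' @slot hr hazard ratios, `exp(coefficients)`.
#' @slot ciLow,ciHigh Wald 95% interval bounds on the hazard-ratio scale.
#' @slot pValues two-sided Wald p-values.
#' @slot pAdjusted Bonferroni-adjusted p-values (m = number of covariates).
#' @slot n,nEvents subjects and events used.
#' @slot loglik partial log-likelihood at beta = 0 and at the maximum.
#' @slot scoreChisq score chi-squared statistic at beta = 0.
#' @slot iterations Newton-Raphson iterations used.
#' @slot converged FALSE flags non-convergence or likely monotone
#'   likelihood (separation); estimates are then diagnostic only.
#' @export
setClass("CoxFit", representation(
  coefficients = "numeric",
  se = "numeric",
  hr = "numeric",
  ciLow = "numeric",
  ciHigh = "numeric",
  pValues = "numeric",
  pAdjusted = "numeric",
  n = "integer",
  nEvents = "integer",
  loglik = "numeric",
  scoreChisq = "numeric",
  iterations = "integer",
  converged = "logical"
))

setValidity("CoxFit", function(object) {
  p <- length(object@coefficients)
  lens <- c(length(object@se), length(object@hr), length(object@ciLow),
            length(object@ciHigh), length(object@pValues),
            length(object@pAdjusted))
  if (any(lens != p)) return("per-covariate slots must have equal length")
  if (any(object@hr <= 0)) return("hazard ratios must be > 0")
  if (any(object@pAdjusted + 1e-12 < object@pValues)) {
    return("adjusted p-values cannot be smaller than raw p-values")
  }
  TRUE
})

#' Optimal survival cutpoint for one marker
#'
#' The cutoff that maximizes the absolute two-group log-rank score over the
#' admissible candidate set, with the Contal-O'Quigley standardized supremum
#' statistic `Q`, its supremum-Brownian-bridge p-value, and the hazard ratio
#' of the above-cutoff versus below-cutoff group from a univariate Cox fit.
#'
#' @slot gene marker name (may be `NA`).
#' @slot candidates admissible candidate cutoffs (midpoints between
#'   consecutive distinct values respecting the minimum group size).
#' @slot scores log-rank score S(c) of the above-cutoff group at each
#'   candidate.
#' @slot bestCutoff the selected cutoff c*.
#' @slot scale the standardization scale s.
#' @slot nEvents total event count D.
#' @slot Q standardized supremum statistic, `max|S| / (s * sqrt(D - 1))`.
#' @slot pValue supremum-Brownian-bridge p-value for Q.
#' @slot hr,ciLow,ciHigh,hrP univariate Cox hazard ratio (above vs below
#'   cutoff), Wald 95% CI and p-value.
#' @slot direction `"high_worse"` if hr > 1 else `"high_better"`.
#' @slot nHigh,nLow group sizes at the selected cutoff.
#' @slot converged Cox convergence flag for the dichotomy at c*.
#' @export
setClass("CutpointResult", representation(
  gene = "character",
  candidates = "numeric",
  scores = "numeric",
  bestCutoff = "numeric",
  scale = "numeric",
  nEvents = "integer",
  Q = "numeric",
  pValue = "numeric",
  hr = "numeric",
  ciLow = "numeric",
  ciHigh = "numeric",
  hrP = "numeric",
  direction = "character",
  nHigh = "integer",
  nLow = "integer",
  converged = "logical"
))

setValidity("CutpointResult", function(object) {
  msgs <- character()
  if (length(object@candidates) < 1L) msgs <- c(msgs, "no candidates stored")
  if (length(object@bestCutoff) != 1L ||
      !any(abs(object@candidates - object@bestCutoff) < 1e-12)) {
    msgs <- c(msgs, "bestCutoff must be one of the candidates")
  }
  if (object@Q < 0) msgs <- c(msgs, "Q must be >= 0")
  if (object@pValue < 0 || object@pValue > 1) {
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  }
  if (object@hr <= 0) msgs <- c(msgs, "hr must be > 0")
  if (!object@direction %in% c("high_worse", "high_better")) {
    msgs <- c(msgs, "direction must be 'high_worse' or 'high_better'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Genome-wide cutpoint screen result
#'
#' Per-gene cutpoint statistics plus the filtered gene lists: genes
#' associated with survival (p < alpha), the over-/under-expression bands
#' (cutoff z-score >= zHi or <= zLo), and the partition into shorter- and
#' longer-survival lists.
#'
#' @slot table per-gene [S4Vectors::DataFrame] with columns gene, cutoff,
#'   cutoffZ, Q, p, pBH, hr, ciLow, ciHigh, direction, nHigh, nLow, class.
#' @slot skipped data.frame of genes that could not be analyzed, with a
#'   reason each.
#' @slot alpha,zHi,zLo thresholds used.
#' @slot directionRule `"hazard"` (default) or `"zsign"`; see
#'   [classifyGene()].
#' @export
setClass("ScreenResult", representation(
  table = "DataFrame",
  skipped = "data.frame",
  alpha = "numeric",
  zHi = "numeric",
  zLo = "numeric",
  directionRule = "character"
))

#' H-score summary over microscope fields
#'
#' Per-field H-scores (each in \[0, 300\]) and the field selected by the
#' highest-field rule.
#'
#' @slot perField named numeric vector of per-field H-scores.
#' @slot selectedField name (or index as character) of the winning field;
#'   ties go to the first field.
#' @slot hSelected the maximum H-score.
#' @export
setClass("HScoreResult", representation(
  perField = "numeric",
  selectedField = "character",
  hSelected = "numeric"
))

setValidity("HScoreResult", function(object) {
  if (length(object@perField) < 1L) return("need at least one field")
  if (any(object@perField < 0 | object@perField > 300)) {
    return("H-scores must lie in [0, 300]")
  }
  if (abs(object@hSelected - max(object@perField)) > 1e-9) {
    return("hSelected must equal the maximum per-field H-score")
  }
  TRUE
})
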