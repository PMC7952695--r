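#' Construct a SurvCohort
#'
#' Aligns a z-scored expression matrix with a clinical table on their shared
#' sample identifiers (see [alignSamples()]) and bundles them into a
#' validated [SurvCohort-class] object.
#'
#' @param expression numeric matrix, genes in rows (rownames = gene
#'   symbols), samples in columns (colnames = sample IDs).
#' @param clinical data.frame with columns `sample`, `time` (months),
#'   `event` (0/1) and optional covariates; or a data.frame whose rownames
#'   are the sample IDs and which already contains `time` and `event`.
#' @return a `SurvCohort`.
#' @examples
#' expr <- matrix(rnorm(20), 4, 5,
#'                dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' clin <- data.frame(sample = paste0("S", 1:5),
#'                    time = c(10, 20, 30, 40, 50),
#'                    event = c(1, 0, 1, 0, 1))
#' SurvCohort(expr, clin)
#' @export
SurvCohort <- function(expression, clinical) {
  if (!is.matrix(expression) || !is.numeric(expression)) {
    stop("'expression' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop("'expression' needs gene symbols as rownames and sample IDs as ",
         "colnames", call. = FALSE)
  }
  clinical <- as.data.frame(clinical)
  if ("sample" %in% colnames(clinical)) {
    rownames(clinical) <- as.character(clinical$sample)
    clinical$sample <- NULL
  }
  if (!all(c("time", "event") %in% colnames(clinical))) {
    stop("'clinical' must contain 'time' and 'event'", call. = FALSE)
  }
  shared <- intersect(colnames(expression), rownames(clinical))
  if (length(shared) == 0L) {
    stop("no sample IDs shared between expression and clinical data",
         call. = FALSE)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(zscore = expression[, shared, drop = FALSE]),
    colData = S4Vectors::DataFrame(clinical[shared, , drop = FALSE])
  )
  methods::new("SurvCohort", se)
}

#' @rdname SurvCohort-class
#' @export
setMethod("survTime", "SurvCohort", function(x) {
  as.numeric(SummarizedExperiment::colData(x)$time)
})

#' @rdname SurvCohort-class
#' @export
setMethod("survEvent", "SurvCohort", function(x) {
  as.integer(SummarizedExperiment::colData(x)$event)
})

#' @rdname SurvCohort-class
#' @export
setMethod("clinicalData", "SurvCohort", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

setMethod("show", "SurvCohort", function(object) {
  callNextMethod()
  ev <- sum(survEvent(object))
  cat(sprintf("survival: %d samples, %d events (%.1f%%)\n",
              ncol(object), ev, 100 * ev / max(1L, ncol(object))))
})

#' @rdname KMCurve-class
#' @param x a `KMCurve`.
#' @param ... unused.
#' @export
as.data.frame.KMCurve <- function(x, ...) {
  data.frame(time = x@time, survival = x@survival, atRisk = x@atRisk,
             nEvents = x@nEvents, nCensored = x@nCensored)
}

setMethod("show", "KMCurve", function(object) {
  cat(sprintf("KMCurve: %d time points, %d events\n",
              length(object@time), sum(object@nEvents)))
  print(utils::head(as.data.frame(object), 8))
  if (length(object@time) > 8) cat("...\n")
})

#' @rdname CoxFit-class
#' @param object a `CoxFit`.
#' @param ... unused.
#' @export
setMethod("coef", "CoxFit", function(object, ...) object@coefficients)

#' Tabulate a Cox fit
#'
#' One row per covariate: hazard ratio, Wald 95% CI, p-value and
#' Bonferroni-adjusted p-value — the presentation used for multivariate
#' prognostic-factor tables.
#'
#' @param fit a [CoxFit-class].
#' @return data.frame with columns covariate, coef, se, HR, CI_low,
#'   CI_high, p, p_bonferroni.
#' @export
coefTable <- function(fit) {
  stopifnot(methods::is(fit, "CoxFit"))
  data.frame(
    covariate = names(fit@coefficients),
    coef = unname(fit@coefficients),
    se = unname(fit@se),
    HR = unname(fit@hr),
    CI_low = unname(fit@ciLow),
    CI_high = unname(fit@ciHigh),
    p = unname(fit@pValues),
    p_bonferroni = unname(fit@pAdjusted),
    row.names = NULL
  )
}

setMethod("show", "CoxFit", function(object) {
  cat(sprintf("CoxFit: n = %d, events = %d, %sconverged (%d iterations)\n",
              object@n, object@nEvents,
              if (object@converged) "" else "NOT ", object@iterations))
  print(coefTable(object), digits = 4)
})

#' @rdname CutpointResult-class
#' @export
setMethod("bestCutoff", "CutpointResult", function(x) x@bestCutoff)

#' @rdname CutpointResult-class
#' @export
setMethod("hazardRatio", "CutpointResult", function(x) x@hr)

#' @rdname CutpointResult-class
#' @param x a `CutpointResult`.
#' @param ... unused.
#' @export
as.data.frame.CutpointResult <- function(x, ...) {
  data.frame(
    gene = x@gene, cutoff = x@bestCutoff, Q = x@Q, p = x@pValue,
    hr = x@hr, ciLow = x@ciLow, ciHigh = x@ciHigh,
    direction = x@direction, nHigh = x@nHigh, nLow = x@nLow,
    converged = x@converged, row.names = NULL
  )
}

setMethod("show", "CutpointResult", function(object) {
  cat(sprintf(
    "CutpointResult%s: cutoff = %.4f (Q = %.3f, p = %.3g)\n",
    if (is.na(object@gene)) "" else paste0(" [", object@gene, "]"),
    object@bestCutoff, object@Q, object@pValue))
  cat(sprintf("  HR (high vs low) = %.3f [%.3f, %.3f], %s; n = %d/%d\n",
              object@hr, object@ciLow, object@ciHigh, object@direction,
              object@nHigh, object@nLow))
})

#' @rdname ScreenResult-class
#' @export
setMethod("screenTable", "ScreenResult", function(x) x@table)

#' @rdname ScreenResult-class
#' @export
setMethod("survivalAssociated", "ScreenResult", function(x) {
  tab <- x@table
  as.character(tab$gene[!is.na(tab$p) & tab$p < x@alpha])
})

#' @rdname ScreenResult-class
#' @export
setMethod("shorterSurvivalGenes", "ScreenResult", function(x) {
  tab <- x@table
  as.character(tab$gene[tab$class %in%
                          c("shorter_survival_over", "shorter_survival_under")])
})

#' @rdname ScreenResult-class
#' @export
setMethod("longerSurvivalGenes", "ScreenResult", function(x) {
  tab <- x@table
  as.character(tab$gene[tab$class %in%
                          c("longer_survival_over", "longer_survival_under")])
})

#' @rdname ScreenResult-class
#' @export
setMethod("cascadeCounts", "ScreenResult", function(x) {
  tab <- x@table
  assoc <- survivalAssociated(x)
  banded <- tab$gene[tab$gene %in% assoc &
                       (tab$cutoffZ >= x@zHi | tab$cutoffZ <= x@zLo)]
  c(total = nrow(tab) + nrow(x@skipped),
    skipped = nrow(x@skipped),
    analyzed = nrow(tab),
    associated = length(assoc),
    banded = length(banded),
    shorter = length(shorterSurvivalGenes(x)),
    longer = length(longerSurvivalGenes(x)))
})

setMethod("show", "ScreenResult", function(object) {
  cc <- cascadeCounts(object)
  cat("ScreenResult (optimal-cutpoint survival screen)\n")
  cat(sprintf("  analyzed %d genes (%d skipped)\n",
              cc[["analyzed"]], cc[["skipped"]]))
  cat(sprintf("  associated with survival (p < %g): %d\n",
              object@alpha, cc[["associated"]]))
  cat(sprintf("  in cutoff z band (>= %g or <= %g): %d\n",
              object@zHi, object@zLo, cc[["banded"]]))
  cat(sprintf("  shorter survival: %d, longer survival: %d\n",
              cc[["shorter"]], cc[["longer"]]))
})

#' @rdname HScoreResult-class
#' @export
setMethod("hSelected", "HScoreResult", function(x) x@hSelected)

#' @rdname HScoreResult-class
#' @export
setMethod("selectedField", "HScoreResult", function(x) x@selectedField)

setMethod("show", "HScoreResult", function(object) {
  cat(sprintf("HScoreResult: %d fields, selected '%s' (H = %.2f)\n",
              length(object@perField), object@selectedField,
              object@hSelected))
})
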