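## Genome-wide screen: best cutpoint per gene, significance and
## z-band filters, partition into shorter-/longer-survival lists.

#' Classify one gene from its cutpoint result
#'
#' Applies the two screening filters and the direction mapping. A gene is
#' `excluded` when its cutpoint p-value is not below `alpha` or its cutoff
#' z-score lies strictly inside the `(zLo, zHi)` band (a cutoff near zero
#' sits near the cohort average and defines neither over- nor
#' under-expression). Band membership uses `>= zHi` / `<= zLo`, so exact
#' ties are included.
#'
#' Direction mapping (`rule = "hazard"`, default): the banded expression
#' class is the *above*-cutoff group when `cutoffZ >= zHi` (overexpression)
#' and the *below*-cutoff group when `cutoffZ <= zLo` (under-expression);
#' the gene is labelled `shorter_survival_*` when that class has the worse
#' outcome (HR of high vs low > 1 for overexpression, < 1 for
#' under-expression), else `longer_survival_*`. The alternative
#' `rule = "zsign"` labels purely by band: overexpression band -> shorter,
#' under-expression band -> longer.
#'
#' @param res a [CutpointResult-class].
#' @param zHi,zLo z-score band limits (defaults 1, -1).
#' @param alpha significance threshold (default 0.05).
#' @param cutoffZ the cutoff on the z-score scale; defaults to
#'   `bestCutoff(res)`, correct when the marker values are already
#'   z-scores.
#' @param rule direction mapping, `"hazard"` (default) or `"zsign"`.
#' @return one of `"shorter_survival_over"`, `"longer_survival_over"`,
#'   `"shorter_survival_under"`, `"longer_survival_under"`, `"excluded"`.
#' @export
classifyGene <- function(res, zHi = 1, zLo = -1, alpha = 0.05,
                         cutoffZ = bestCutoff(res),
                         rule = c("hazard", "zsign")) {
  stopifnot(methods::is(res, "CutpointResult"))
  rule <- match.arg(rule)
  if (is.na(res@pValue) || res@pValue >= alpha) return("excluded")
  if (cutoffZ < zHi && cutoffZ > zLo) return("excluded")
  over <- cutoffZ >= zHi
  if (rule == "zsign") {
    return(if (over) "shorter_survival_over" else "longer_survival_under")
  }
  highWorse <- res@hr > 1
  if (over) {
    if (highWorse) "shorter_survival_over" else "longer_survival_over"
  } else {
    if (highWorse) "longer_survival_under" else "shorter_survival_under"
  }
}

#' Genome-wide optimal-cutpoint survival screen
#'
#' Runs [bestCutpoint()] for every gene (pairwise deletion of samples with
#' missing expression), then applies the screening cascade: keep genes with
#' cutpoint p-value below `alpha`, restrict to those whose cutoff z-score
#' falls in the over-expression (`>= zHi`) or under-expression (`<= zLo`)
#' band, and partition the survivors into shorter- and longer-survival
#' lists via [classifyGene()]. A Benjamini-Hochberg column (`pBH`) is
#' emitted for reference but plays no part in the cascade filters.
#'
#' @param cohort a [SurvCohort-class] (samples already aligned).
#' @param alpha significance threshold on the cutpoint p-value.
#' @param zHi,zLo cutoff z-score band limits.
#' @param minGroup minimum group size per side (see [bestCutpoint()]).
#' @param zscored if `TRUE` (default) the assay is taken to be z-scores and
#'   the cutoff is its own z-score; otherwise the cutoff z-score is
#'   `(c* - mean) / sd` per gene.
#' @param rule direction mapping passed to [classifyGene()].
#' @return a [ScreenResult-class]; genes failing candidate generation
#'   (constant expression, too few events, ...) are recorded in its
#'   `skipped` slot with a reason each.
#' @export
screenGenes <- function(cohort, alpha = 0.05, zHi = 1, zLo = -1,
                        minGroup = NULL, zscored = TRUE,
                        rule = c("hazard", "zsign")) {
  stopifnot(methods::is(cohort, "SurvCohort"))
  rule <- match.arg(rule)
  if (!(alpha >= 0 && alpha <= 1)) stop("'alpha' must be in [0, 1]")
  if (zLo >= zHi) stop("'zLo' must be below 'zHi'")
  expr <- SummarizedExperiment::assay(cohort)
  if (nrow(expr) < 1L) stop("no genes to screen", call. = FALSE)
  time <- survTime(cohort)
  event <- survEvent(cohort)

  rows <- vector("list", nrow(expr))
  skipped <- list()
  for (i in seq_len(nrow(expr))) {
    g <- rownames(expr)[i]
    vals <- expr[i, ]
    res <- tryCatch(
      bestCutpoint(vals, time, event, minGroup = minGroup, gene = g),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <- data.frame(gene = g, reason = res)
      next
    }
    cz <- if (zscored) {
      res@bestCutoff
    } else {
      (res@bestCutoff - mean(vals, na.rm = TRUE)) / stats::sd(vals, na.rm = TRUE)
    }
    rows[[i]] <- data.frame(
      gene = g, cutoff = res@bestCutoff, cutoffZ = cz, Q = res@Q,
      p = res@pValue, hr = res@hr, ciLow = res@ciLow, ciHigh = res@ciHigh,
      direction = res@direction, nHigh = res@nHigh, nLow = res@nLow,
      converged = res@converged,
      class = classifyGene(res, zHi = zHi, zLo = zLo, alpha = alpha,
                           cutoffZ = cz, rule = rule)
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no analyzable genes (all skipped)", call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$pBH <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[, c("gene", "cutoff", "cutoffZ", "Q", "p", "pBH", "hr",
                 "ciLow", "ciHigh", "direction", "nHigh", "nLow",
                 "converged", "class")]
  skippedDf <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    data.frame(gene = character(), reason = character())
  }
  methods::new("ScreenResult", table = S4Vectors::DataFrame(tab),
               skipped = skippedDf, alpha = alpha, zHi = zHi, zLo = zLo,
               directionRule = rule)
}

#' Per-gene survival report
#'
#' Dichotomizes one gene at the supplied cutoff (or at its optimal
#' cutpoint) and returns everything the single-biomarker figures and tables
#' report: Kaplan-Meier curves for the high and low group, the univariate
#' Cox hazard ratio of the dichotomy, a covariate-adjusted multivariate Cox
#' fit with Bonferroni-corrected p-values across its covariates, and the
#' mean observed time to event per group.
#'
#' @param cohort a [SurvCohort-class].
#' @param gene gene symbol (must be a rowname of the cohort).
#' @param cutoff optional fixed cutoff; `NULL` computes [bestCutpoint()].
#' @param covariates colData columns for the multivariate model; defaults
#'   to the intersection of `c("age", "gs", "t_category", "ipsa")` with the
#'   available columns. Rows missing a covariate are dropped from the
#'   multivariate fit only.
#' @param minGroup passed to [bestCutpoint()] when `cutoff` is `NULL`.
#' @return list with elements `cutoff`, `cutpoint` (a
#'   [CutpointResult-class] or `NULL` when a cutoff was supplied), `kmHigh`,
#'   `kmLow`, `coxUnivariate`, `coxMultivariate`, `meanTime`.
#' @export
geneReport <- function(cohort, gene, cutoff = NULL, covariates = NULL,
                       minGroup = NULL) {
  stopifnot(methods::is(cohort, "SurvCohort"))
  expr <- SummarizedExperiment::assay(cohort)
  if (!gene %in% rownames(expr)) {
    stop("gene '", gene, "' not found in the cohort", call. = FALSE)
  }
  vals <- expr[gene, ]
  time <- survTime(cohort)
  event <- survEvent(cohort)
  cd <- clinicalData(cohort)
  keep <- !is.na(vals)
  vals <- vals[keep]
  time <- time[keep]
  event <- event[keep]
  cd <- cd[keep, , drop = FALSE]

  cp <- NULL
  if (is.null(cutoff)) {
    cp <- bestCutpoint(vals, time, event, minGroup = minGroup, gene = gene)
    cutoff <- cp@bestCutoff
  }
  high <- vals > cutoff
  if (!any(high) || all(high)) {
    stop("cutoff leaves an empty group", call. = FALSE)
  }

  kmHigh <- kmEstimate(time[high], event[high])
  kmLow <- kmEstimate(time[!high], event[!high])
  uni <- coxFit(matrix(as.numeric(high), ncol = 1,
                       dimnames = list(NULL, gene)),
                time, event)

  if (is.null(covariates)) {
    covariates <- intersect(c("age", "gs", "t_category", "ipsa"),
                            colnames(cd))
  }
  multi <- NULL
  if (length(covariates)) {
    missingCov <- setdiff(covariates, colnames(cd))
    if (length(missingCov)) {
      stop("covariate(s) not in clinical data: ",
           paste(missingCov, collapse = ", "), call. = FALSE)
    }
    Xc <- as.matrix(cd[, covariates, drop = FALSE])
    storage.mode(Xc) <- "double"
    ok <- stats::complete.cases(Xc)
    X <- cbind(as.numeric(high), Xc)[ok, , drop = FALSE]
    colnames(X) <- c(gene, covariates)
    multi <- coxFit(X, time[ok], event[ok])
  }

  mt <- withCallingHandlers(
    meanTimeToEvent(time, event,
                    ifelse(high, "high", "low")),
    warning = function(w) invokeRestart("muffleWarning")
  )
  list(cutoff = cutoff, cutpoint = cp, kmHigh = kmHigh, kmLow = kmLow,
       coxUnivariate = uni, coxMultivariate = multi, meanTime = mt)
}
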