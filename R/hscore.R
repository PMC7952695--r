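## H-score quantification of immunohistochemistry staining: per-field
## intensity-category counts -> H-score in [0, 300], highest-field rule,
## and linkage to survival via the optimal cutpoint machinery.

.hscoreCategories <- c("negative", "low", "positive", "high")

#' H-score from intensity-category counts
#'
#' \deqn{H = \sum_{k=0}^{3} k \times 100 \times n_k / N}
#' where `n_k` is the number of cells in intensity category k (0 =
#' negative, 1 = low, 2 = positive, 3 = high) and N the total cell count.
#' Equivalently, the intensity-weighted sum of category percentages; range
#' \[0, 300\].
#'
#' @param counts numeric vector of 4 non-negative cell counts in category
#'   order negative, low, positive, high (names optional).
#' @return the H-score.
#' @examples
#' computeHScore(c(40, 30, 20, 10))  # percentages (40,30,20,10) -> 100
#' @export
computeHScore <- function(counts) {
  if (length(counts) != 4L || anyNA(counts) || any(counts < 0)) {
    stop("'counts' must be 4 non-negative cell counts", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("all counts are zero", call. = FALSE)
  sum((0:3) * 100 * counts / n)
}

#' Bin a grayscale histogram into staining-intensity categories
#'
#' Assigns the 256 grayscale levels to four staining zones by configurable
#' upper bounds; darker pixels mean stronger DAB staining, so low gray
#' levels map to the "high" category. Default zones: high 0-60, positive
#' 61-120, low 121-180, negative 181-255. The bounds are a documented,
#' non-authoritative approximation of published profiler zones.
#'
#' @param grayHist numeric vector of 256 non-negative pixel (or cell)
#'   counts for gray levels 0..255.
#' @param zoneBounds strictly increasing upper gray levels (inclusive) of
#'   the high, positive and low zones, within 0..254.
#' @return named counts in category order negative, low, positive, high,
#'   usable with [computeHScore()].
#' @export
binIntensityHistogram <- function(grayHist, zoneBounds = c(60, 120, 180)) {
  if (length(grayHist) != 256L || anyNA(grayHist) || any(grayHist < 0)) {
    stop("'grayHist' must be 256 non-negative counts", call. = FALSE)
  }
  if (length(zoneBounds) != 3L || anyNA(zoneBounds) ||
      is.unsorted(zoneBounds, strictly = TRUE) ||
      zoneBounds[1] < 0 || zoneBounds[3] > 254) {
    stop("'zoneBounds' must be 3 strictly increasing levels in [0, 254]",
         call. = FALSE)
  }
  lev <- 0:255
  zone <- findInterval(lev, zoneBounds + 1L) + 1L  # 1=high .. 4=negative
  counts <- vapply(1:4, function(z) sum(grayHist[zone == z]), numeric(1))
  out <- rev(counts)  # reorder to negative, low, positive, high
  names(out) <- .hscoreCategories
  out
}

#' Highest-field rule
#'
#' Selects the field with the highest H-score among the evaluated
#' high-power fields; ties are broken toward the first field.
#'
#' @param hscores numeric vector of per-field H-scores (optionally named
#'   with field IDs).
#' @return an [HScoreResult-class].
#' @export
selectField <- function(hscores) {
  if (length(hscores) < 1L || anyNA(hscores)) {
    stop("'hscores' must be a non-empty numeric vector", call. = FALSE)
  }
  if (is.null(names(hscores))) {
    names(hscores) <- as.character(seq_along(hscores))
  }
  i <- which.max(hscores)  # first maximum on ties
  methods::new("HScoreResult", perField = hscores,
               selectedField = names(hscores)[i],
               hSelected = unname(hscores[i]))
}

#' Link patient H-scores to recurrence-free survival
#'
#' Runs [bestCutpoint()] on raw H-scores, reports the selected cutoff also
#' on the cohort z-score scale (`(c* - mean) / sd`) so cutoffs from
#' different cohorts are comparable, and additionally evaluates the
#' conventional fixed dichotomy at H-score z-score >= 1 (a second analysis
#' alongside the optimal cutoff).
#'
#' @param hscores per-patient H-scores (highest-field values).
#' @param time,event survival outcome, aligned with `hscores`.
#' @param minGroup passed to [bestCutpoint()].
#' @return list with `cutpoint` (a [CutpointResult-class] on the H-score
#'   scale), `cutoffZ`, `kmHigh`/`kmLow` at the optimal cutoff, and
#'   `fixedZ`: list with the z >= 1 indicator's `coxFit`, `fractionHigh`,
#'   `kmHigh`, `kmLow` (Cox/KM `NULL` when the dichotomy is degenerate).
#' @export
hscoreSurvival <- function(hscores, time, event, minGroup = NULL) {
  cp <- bestCutpoint(hscores, time, event, minGroup = minGroup,
                     gene = "H-score")
  keep <- !is.na(hscores)
  h <- hscores[keep]
  tt <- time[keep]
  ev <- as.integer(event[keep])
  cz <- (cp@bestCutoff - mean(h)) / stats::sd(h)
  high <- h > cp@bestCutoff
  kmHigh <- kmEstimate(tt[high], ev[high])
  kmLow <- kmEstimate(tt[!high], ev[!high])

  z <- (h - mean(h)) / stats::sd(h)
  zHigh <- z >= 1
  fixed <- list(fractionHigh = mean(zHigh), coxFit = NULL,
                kmHigh = NULL, kmLow = NULL)
  if (any(zHigh) && !all(zHigh)) {
    fixed$coxFit <- withCallingHandlers(
      coxFit(matrix(as.numeric(zHigh), ncol = 1,
                    dimnames = list(NULL, "z_ge_1")), tt, ev),
      warning = function(w) invokeRestart("muffleWarning")
    )
    fixed$kmHigh <- kmEstimate(tt[zHigh], ev[zHigh])
    fixed$kmLow <- kmEstimate(tt[!zHigh], ev[!zHigh])
  }
  list(cutpoint = cp, cutoffZ = cz, kmHigh = kmHigh, kmLow = kmLow,
       fixedZ = fixed)
}
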