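## Optimal survival cutpoint selection: maximally selected log-rank
## statistic with Contal-O'Quigley standardization and the
## sup-Brownian-bridge p-value.

#' Admissible candidate cutoffs
#'
#' Midpoints between consecutive distinct sorted values, restricted so that
#' dichotomizing at any candidate leaves at least `minGroup` subjects on
#' each side.
#'
#' @param values numeric marker values (e.g. expression z-scores).
#' @param minGroup minimum group size per side (default 1).
#' @return sorted numeric vector of candidates.
#' @examples
#' candidateCutoffs(c(1, 2, 3, 4), minGroup = 1)       # 1.5 2.5 3.5
#' candidateCutoffs(c(1, 2, 3, 4, 5, 6), minGroup = 2) # 2.5 3.5 4.5
#' @export
candidateCutoffs <- function(values, minGroup = 1L) {
  if (anyNA(values)) values <- values[!is.na(values)]
  minGroup <- checkScalarCount(minGroup, "minGroup")
  n <- length(values)
  if (n < 2L * minGroup) {
    stop("too few observations for minGroup = ", minGroup, call. = FALSE)
  }
  u <- sort(unique(values))
  if (length(u) < 2L) {
    stop("no candidate cutoffs: values are constant", call. = FALSE)
  }
  nBelow <- cumsum(tabulate(match(sort(values), u), nbins = length(u)))
  mid <- (u[-length(u)] + u[-1L]) / 2
  keep <- nBelow[-length(u)] >= minGroup & (n - nBelow[-length(u)]) >= minGroup
  out <- mid[keep]
  if (length(out) == 0L) {
    stop("no candidate cutoffs satisfy the minimum group size", call. = FALSE)
  }
  out
}

## Per-subject log-rank (martingale-residual) scores at beta = 0:
## L_s = delta_s - NelsonAalen(t_s). The log-rank O - E of any "high" group
## is the sum of L_s over its members, which lets S(c) for every candidate
## be computed by one sorted cumulative sum.
.subjectScores <- function(time, event) {
  ut <- sort(unique(time[event == 1L]))
  r <- vapply(ut, function(t) sum(time >= t), numeric(1))
  d <- vapply(ut, function(t) sum(time == t & event == 1L), numeric(1))
  cumhaz <- cumsum(d / r)
  idx <- findInterval(time, ut)                # events with ut <= t_s
  lam <- c(0, cumhaz)[idx + 1L]
  event - lam
}

#' Log-rank score of the above-cutoff group
#'
#' The observed-minus-expected log-rank score
#' \deqn{S(c) = \sum_i \left(d_i^+ - d_i r_i^+ / r_i\right)}
#' summed over distinct event times, where \eqn{d_i^+} and \eqn{r_i^+} are
#' events and at-risk counts in the group with `values > cutoff`. Positive
#' `S` means the high group experienced more events than expected under
#' exchangeability.
#'
#' @param values marker values.
#' @param cutoff dichotomizing threshold; both sides must be non-empty.
#' @param time,event survival outcome.
#' @return the scalar score S(cutoff).
#' @export
logrankScore <- function(values, cutoff, time, event) {
  event <- checkSurvival(time, event)
  if (length(values) != length(time)) {
    stop("'values' must match the number of subjects", call. = FALSE)
  }
  high <- values > cutoff
  if (!any(high) || all(high)) {
    stop("cutoff must split the sample into two non-empty groups",
         call. = FALSE)
  }
  s <- 0
  for (t in sort(unique(time[event == 1L]))) {
    risk <- time >= t
    r <- sum(risk)
    rp <- sum(risk & high)
    d <- sum(time == t & event == 1L)
    dp <- sum(time == t & event == 1L & high)
    s <- s + dp - d * rp / r
  }
  s
}

## Contal-O'Quigley standardization scale:
## s^2 = (1 / (D - 1)) * sum_{i=1..D} (1 - sum_{j=1..i} 1/(D - j + 1))^2
.coScale <- function(D) {
  a <- cumsum(1 / (D - seq_len(D) + 1))
  sqrt(sum((1 - a)^2) / (D - 1))
}

#' Supremum-Brownian-bridge p-value for the standardized cutpoint statistic
#'
#' Limiting tail probability of the supremum of the absolute Brownian
#' bridge:
#' \deqn{p(Q) = 2 \sum_{j \ge 1} (-1)^{j+1} e^{-2 j^2 Q^2}}
#' summed until terms fall below 1e-12 in absolute value or `terms` terms
#' have been used, then clipped to \[0, 1\]. This corrects the p-value for
#' having searched over all candidate cutoffs.
#'
#' @param Q standardized supremum statistic, `>= 0`.
#' @param terms maximum number of series terms.
#' @return p-value in \[0, 1\].
#' @examples
#' cutpointPvalue(1.358)   # ~0.05: the classical 5% critical value
#' @export
cutpointPvalue <- function(Q, terms = 100L) {
  if (!is.numeric(Q) || length(Q) != 1L || is.na(Q)) {
    stop("'Q' must be a single number", call. = FALSE)
  }
  if (Q < 0) stop("'Q' must be >= 0", call. = FALSE)
  terms <- checkScalarCount(terms, "terms")
  if (Q < sqrt(.Machine$double.eps)) return(1)
  p <- 0
  for (j in seq_len(terms)) {
    term <- (-1)^(j + 1) * exp(-2 * j^2 * Q^2)
    p <- p + term
    if (abs(term) < 1e-12) break
  }
  min(1, max(0, 2 * p))
}

#' Optimal survival cutpoint for a marker
#'
#' Selects the cutoff `c*` maximizing `|S(c)|` (the absolute log-rank score
#' of the above-cutoff group, [logrankScore()]) over the admissible
#' candidates, standardizes the supremum as
#' \deqn{Q = \max_c |S(c)| / (s \sqrt{D - 1})}
#' with the Contal-O'Quigley scale
#' \deqn{s^2 = \frac{1}{D-1} \sum_{i=1}^{D}
#'   \Big(1 - \sum_{j=1}^{i} \frac{1}{D - j + 1}\Big)^2,}
#' where `D` is the total event count, and converts `Q` to a p-value via
#' [cutpointPvalue()], which accounts for the cutoff search. The hazard
#' ratio of the above- vs below-cutoff group comes from a univariate
#' [coxFit()] on the dichotomy at `c*`.
#'
#' Candidates whose scores tie for the maximum (within 1e-10) are resolved
#' toward the candidate closest to the median marker value, for stability.
#' Missing marker values are dropped together with their survival rows
#' (pairwise deletion).
#'
#' @param values marker values (expression z-scores, H-scores, ...).
#' @param time,event survival outcome.
#' @param minGroup minimum group size per side; `NULL` (default) uses
#'   `max(10, ceiling(0.1 * n))`, configurable down to 1.
#' @param gene optional marker name carried into the result.
#' @return a [CutpointResult-class].
#' @export
bestCutpoint <- function(values, time, event, minGroup = NULL,
                         gene = NA_character_) {
  if (length(values) != length(time)) {
    stop("'values' must match the number of subjects", call. = FALSE)
  }
  keep <- !is.na(values)
  values <- values[keep]
  time <- time[keep]
  event <- checkSurvival(time, event[keep])
  n <- length(values)
  if (is.null(minGroup)) minGroup <- max(10L, as.integer(ceiling(0.1 * n)))
  D <- sum(event)
  if (D < 2L) stop("need at least two events", call. = FALSE)
  cand <- candidateCutoffs(values, minGroup)

  ## S(c) for all candidates at once: sort subject scores by marker value
  ## descending; S(c) is the running sum over subjects with value > c.
  L <- .subjectScores(time, event)
  ord <- order(values, decreasing = TRUE)
  csum <- cumsum(L[ord])
  sortedVals <- values[ord]
  ## number of subjects strictly above each candidate
  nAbove <- length(values) - findInterval(cand, sort(values))
  scores <- csum[nAbove]

  absS <- abs(scores)
  top <- which(absS >= max(absS) - 1e-10)
  if (length(top) > 1L) {
    med <- stats::median(values)
    top <- top[which.min(abs(cand[top] - med))]
  }
  best <- cand[top]
  s <- .coScale(D)
  Q <- max(absS) / (s * sqrt(D - 1))
  p <- cutpointPvalue(Q)

  high <- as.numeric(values > best)
  fit <- withCallingHandlers(
    coxFit(matrix(high, ncol = 1, dimnames = list(NULL, "high")),
           time, event),
    warning = function(w) invokeRestart("muffleWarning")
  )
  methods::new(
    "CutpointResult",
    gene = as.character(gene), candidates = cand, scores = scores,
    bestCutoff = best, scale = s, nEvents = as.integer(D), Q = Q,
    pValue = p, hr = unname(fit@hr), ciLow = unname(fit@ciLow),
    ciHigh = unname(fit@ciHigh), hrP = unname(fit@pValues),
    direction = if (fit@hr > 1) "high_worse" else "high_better",
    nHigh = as.integer(sum(high)), nLow = as.integer(sum(high == 0)),
    converged = fit@converged
  )
}

#' Naive minimal-p dichotomization (uncorrected contrast)
#'
#' For every admissible candidate cutoff, computes the ordinary log-rank
#' chi-squared p-value of the resulting dichotomy and returns the minimum —
#' the "try every cutoff, report the best p" practice. Because it ignores
#' the multiplicity of the cutoff search its type-I error is badly
#' inflated; it is provided as the contrast that motivates the maximal
#' selection correction in [bestCutpoint()].
#'
#' @inheritParams bestCutpoint
#' @return list with `p` (the minimal p-value), `cutoff` (its candidate)
#'   and `nCandidates`.
#' @export
naiveMinPvalue <- function(values, time, event, minGroup = NULL) {
  keep <- !is.na(values)
  values <- values[keep]
  time <- time[keep]
  event <- checkSurvival(time, event[keep])
  n <- length(values)
  if (is.null(minGroup)) minGroup <- max(10L, as.integer(ceiling(0.1 * n)))
  cand <- candidateCutoffs(values, minGroup)
  L <- .subjectScores(time, event)
  ord <- order(values, decreasing = TRUE)
  csum <- cumsum(L[ord])
  nAbove <- n - findInterval(cand, sort(values))
  scores <- csum[nAbove]

  ut <- sort(unique(time[event == 1L]))
  ordT <- order(time)
  tSorted <- time[ordT]
  ## first position in the time-ascending order at risk at each event time
  firstAtRisk <- findInterval(ut, tSorted, left.open = TRUE) + 1L
  r <- n - firstAtRisk + 1L
  d <- vapply(ut, function(t) sum(time == t & event == 1L), numeric(1))
  denom <- ifelse(r > 1, r - 1, 1)

  pbest <- 1
  cbest <- cand[1L]
  for (i in seq_along(cand)) {
    high <- values > cand[i]
    hs <- rev(cumsum(rev(high[ordT])))      # at-risk highs from each position
    rp <- hs[firstAtRisk]
    v <- sum(d * (rp / r) * (1 - rp / r) * (r - d) / denom)
    chisq <- if (v > 0) scores[i]^2 / v else 0
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    if (p < pbest) {
      pbest <- p
      cbest <- cand[i]
    }
  }
  list(p = pbest, cutoff = cbest, nCandidates = length(cand))
}
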