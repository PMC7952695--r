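## From-scratch survival core: Kaplan-Meier, log-rank, Cox partial
## likelihood (Efron / Breslow ties), Bonferroni, mean time to event,
## Pearson correlation utility.

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator
#' \deqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' over distinct event times, with `d_i` events among `n_i` at risk.
#' Subjects censored at an event time are counted in the risk set at that
#' time (the usual convention).
#'
#' @param time observed times (months), `>= 0`.
#' @param event event indicator: 1 = event, 0 = censored.
#' @return a [KMCurve-class] evaluated at every distinct observed time.
#' @examples
#' km <- kmEstimate(c(5, 8, 12, 15), c(1, 1, 0, 1))
#' as.data.frame(km)   # survival steps 0.75, 0.50, 0.50, 0.00
#' @export
kmEstimate <- function(time, event) {
  event <- checkSurvival(time, event)
  ut <- sort(unique(time))
  atRisk <- vapply(ut, function(t) sum(time >= t), integer(1))
  nEv <- vapply(ut, function(t) sum(time == t & event == 1L), integer(1))
  nCn <- vapply(ut, function(t) sum(time == t & event == 0L), integer(1))
  surv <- cumprod(1 - nEv / atRisk)
  methods::new("KMCurve", time = as.numeric(ut), survival = surv,
               atRisk = atRisk, nEvents = nEv, nCensored = nCn)
}

## Log-rank O - E and hypergeometric variance for group A vs pooled data.
## Returns observed-minus-expected for group A and its variance.
.logrankOE <- function(timeA, eventA, timeB, eventB) {
  time <- c(timeA, timeB)
  event <- c(eventA, eventB)
  grp <- rep(c(TRUE, FALSE), c(length(timeA), length(timeB)))
  ut <- sort(unique(time[event == 1L]))
  oe <- 0
  v <- 0
  for (t in ut) {
    risk <- time >= t
    r <- sum(risk)
    rA <- sum(risk & grp)
    d <- sum(time == t & event == 1L)
    dA <- sum(time == t & event == 1L & grp)
    oe <- oe + dA - d * rA / r
    if (r > 1) {
      v <- v + d * (rA / r) * (1 - rA / r) * (r - d) / (r - 1)
    }
  }
  c(oe = oe, var = v)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-squared statistic (1 df) with the
#' hypergeometric variance, testing equality of the two survival curves.
#'
#' @param timeA,eventA times and event indicators for group A.
#' @param timeB,eventB times and event indicators for group B.
#' @return list with `chisq`, `p` (upper chi-squared tail, 1 df), and the
#'   group-A observed-minus-expected `oe` with its variance `var`.
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
  if (length(timeA) < 1L || length(timeB) < 1L) {
    stop("each group needs at least one subject", call. = FALSE)
  }
  eventA <- checkSurvival(timeA, eventA)
  eventB <- checkSurvival(timeB, eventB)
  if (sum(eventA) + sum(eventB) < 1L) {
    stop("need at least one event overall", call. = FALSE)
  }
  oe <- .logrankOE(timeA, eventA, timeB, eventB)
  chisq <- if (oe[["var"]] > 0) oe[["oe"]]^2 / oe[["var"]] else 0
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       oe = oe[["oe"]], var = oe[["var"]])
}

## Partial log-likelihood, gradient and observed information of the Cox
## model at beta, with Efron or Breslow handling of tied event times.
.coxEngine <- function(beta, X, time, event, ties) {
  n <- nrow(X)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)            # guard exp() overflow; PL is shift-invariant
  w <- exp(eta)
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (t in sort(unique(time[event == 1L]))) {
    risk <- which(time >= t)
    dead <- which(time == t & event == 1L)
    d <- length(dead)
    wr <- w[risk]
    Xr <- X[risk, , drop = FALSE]
    S0 <- sum(wr)
    S1 <- colSums(wr * Xr)
    S2 <- crossprod(Xr, wr * Xr)
    ll <- ll + sum(eta[dead])
    grad <- grad + colSums(X[dead, , drop = FALSE])
    if (ties == "breslow" || d == 1L) {
      ll <- ll - d * log(S0)
      grad <- grad - d * S1 / S0
      info <- info + d * (S2 / S0 - tcrossprod(S1 / S0))
    } else {
      wd <- w[dead]
      Xd <- X[dead, , drop = FALSE]
      S0d <- sum(wd)
      S1d <- colSums(wd * Xd)
      S2d <- crossprod(Xd, wd * Xd)
      for (k in seq_len(d) - 1L) {
        f <- k / d
        S0k <- S0 - f * S0d
        S1k <- S1 - f * S1d
        S2k <- S2 - f * S2d
        ll <- ll - log(S0k)
        grad <- grad - S1k / S0k
        info <- info + S2k / S0k - tcrossprod(S1k / S0k)
      }
    }
  }
  list(loglik = ll, grad = grad, info = info)
}

#' Cox proportional hazards regression
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson from `beta = 0`,
#' with step-halving whenever a step would decrease the likelihood.
#' Convergence requires the gradient max-norm below `tol` (default 1e-9)
#' within `maxIter` iterations. Efron's correction for tied event times is
#' the default; Breslow's is available for cross-checks. Confidence
#' intervals and p-values are Wald-based; `pAdjusted` applies a Bonferroni
#' correction with m = number of covariates.
#'
#' @param x covariate matrix (n x p) or a vector for a single covariate.
#' @param time,event survival outcome as in [kmEstimate()].
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param maxIter,tol Newton-Raphson controls.
#' @return a [CoxFit-class]. Diverging coefficients (|beta| > 15, monotone
#'   likelihood / separation) or failure to reach `tol` produce a warning
#'   and `converged = FALSE` rather than an error.
#' @export
coxFit <- function(x, time, event, ties = c("efron", "breslow"),
                   maxIter = 50L, tol = 1e-9) {
  ties <- match.arg(ties)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  event <- checkSurvival(time, event)
  if (nrow(X) != length(time)) {
    stop("covariate rows must match the number of subjects", call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("covariates must be finite and non-missing", call. = FALSE)
  }
  if (sum(event) < 1L) stop("need at least one event", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant covariate(s): ",
         paste(which(sds == 0), collapse = ", "), call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  ## center covariates for numerical stability; beta is shift-invariant
  Xc <- sweep(X, 2L, colMeans(X))
  p <- ncol(Xc)
  beta <- numeric(p)
  eng <- .coxEngine(beta, Xc, time, event, ties)
  loglik0 <- eng$loglik
  scoreChisq <- tryCatch(
    drop(t(eng$grad) %*% solve(eng$info, eng$grad)),
    error = function(e) NA_real_
  )
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    step <- tryCatch(solve(eng$info, eng$grad), error = function(e) NULL)
    if (is.null(step)) break
    newBeta <- beta + step
    newEng <- .coxEngine(newBeta, Xc, time, event, ties)
    ## halve only on a genuine decrease, not floating-point noise near
    ## the optimum
    noise <- 1e-11 * (1 + abs(eng$loglik))
    halvings <- 0L
    while (newEng$loglik < eng$loglik - noise && halvings < 30L) {
      halvings <- halvings + 1L
      newBeta <- beta + step / 2^halvings
      newEng <- .coxEngine(newBeta, Xc, time, event, ties)
    }
    beta <- newBeta
    eng <- newEng
    if (max(abs(eng$grad)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (any(abs(beta) > 15)) {
    warning("diverging coefficient(s); likely monotone likelihood ",
            "(separation) - fit flagged as non-converged", call. = FALSE)
    converged <- FALSE
  }
  if (!converged && all(abs(beta) <= 15)) {
    warning("Cox fit did not reach gradient tolerance in ", maxIter,
            " iterations", call. = FALSE)
  }
  covBeta <- tryCatch(solve(eng$info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(covBeta), 0))
  zq <- stats::qnorm(0.975)
  pvals <- 2 * stats::pnorm(-abs(beta / se))
  names(beta) <- colnames(X)
  methods::new(
    "CoxFit",
    coefficients = beta, se = se, hr = exp(beta),
    ciLow = exp(beta - zq * se), ciHigh = exp(beta + zq * se),
    pValues = pvals, pAdjusted = bonferroniAdjust(pvals, m = p),
    n = nrow(X), nEvents = sum(event),
    loglik = c(null = loglik0, final = eng$loglik),
    scoreChisq = scoreChisq, iterations = iter, converged = converged
  )
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` per test. `m` defaults to the number of p-values but may
#' be larger when the family of tests exceeds those supplied.
#'
#' @param p p-values in \[0, 1\].
#' @param m family size; must be at least `length(p)`.
#' @return adjusted p-values, capped at 1.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- checkScalarCount(m, "m")
  if (m < length(p)) {
    stop("'m' must be at least the number of tests", call. = FALSE)
  }
  pmin(1, m * p)
}

#' Mean observed time to event per group
#'
#' Arithmetic mean of observed times among subjects who experienced the
#' event, per binary group — the "average time to recurrence" summary for a
#' dichotomized cohort. Groups with no events yield `NA` with a warning.
#'
#' @param time,event survival outcome.
#' @param group binary group labels (two levels).
#' @return named numeric vector of per-group means (names = group levels).
#' @export
meanTimeToEvent <- function(time, event, group) {
  event <- checkSurvival(time, event)
  if (length(group) != length(time)) {
    stop("'group' must match the number of subjects", call. = FALSE)
  }
  lv <- unique(group)
  if (length(lv) > 2L) stop("'group' must be binary", call. = FALSE)
  out <- vapply(lv, function(g) {
    sel <- group == g & event == 1L
    if (!any(sel)) return(NA_real_)
    mean(time[sel])
  }, numeric(1))
  names(out) <- as.character(lv)
  if (anyNA(out)) {
    warning("group(s) with zero events: mean time to event undefined",
            call. = FALSE)
  }
  out
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation with the two-sided p-value from the
#' t-distribution on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, `n >= 3`, finite, non-constant.
#' @return list with `r` and `p`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("'x' and 'y' must have equal length >= 3", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("'x' and 'y' must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in 'x' or 'y'", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
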