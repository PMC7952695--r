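## Independent oracles and fixture builders. These deliberately use the
## slowest, most literal formulations so they stay independent of the
## package's optimized code paths.

## Direct O-E log-rank score of the above-cutoff group, from the 2xK table.
bruteLogrankScore <- function(values, cutoff, time, event) {
  high <- values > cutoff
  s <- 0
  for (t in sort(unique(time[event == 1]))) {
    r <- sum(time >= t)
    rp <- sum(time >= t & high)
    d <- sum(time == t & event == 1)
    dp <- sum(time == t & event == 1 & high)
    s <- s + dp - d * rp / r
  }
  s
}

## Exhaustive-split maximization: score every admissible candidate with the
## brute-force score, apply the same argmax tie rule (closest to median).
bruteBestSplit <- function(values, time, event, minGroup) {
  cand <- candidateCutoffs(values, minGroup)
  sc <- vapply(cand, function(c) bruteLogrankScore(values, c, time, event),
               numeric(1))
  top <- which(abs(sc) >= max(abs(sc)) - 1e-10)
  if (length(top) > 1L) {
    top <- top[which.min(abs(cand[top] - stats::median(values)))]
  }
  D <- sum(event)
  a <- cumsum(1 / (D - seq_len(D) + 1))
  s <- sqrt(sum((1 - a)^2) / (D - 1))
  list(cutoff = cand[top], scores = sc,
       Q = max(abs(sc)) / (s * sqrt(D - 1)))
}

## Brute-force Cox partial log-likelihood for one covariate, no ties.
brutePartialLoglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

## Upper-tail hypergeometric by direct summation of binomial coefficients.
bruteHyperTail <- function(k, setSize, universeSize, listSize) {
  j <- k:min(setSize, listSize)
  sum(choose(setSize, j) * choose(universeSize - setSize, listSize - j)) /
    choose(universeSize, listSize)
}

## Small random survival fixture with ties.
randomSurvFixture <- function(n, seed) {
  set.seed(seed)
  list(values = rnorm(n),
       time = sample(1:15, n, replace = TRUE),
       event = rbinom(n, 1, 0.7))
}
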