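test_that("Kaplan-Meier matches the hand product-limit calculation", {
  km <- kmEstimate(c(5, 8, 12, 15), c(1, 1, 0, 1))
  df <- as.data.frame(km)
  expect_equal(df$time, c(5, 8, 12, 15))
  expect_equal(df$survival, c(0.75, 0.50, 0.50, 0.00))
  expect_equal(df$atRisk, c(4L, 3L, 2L, 1L))

  # no events: survival stays at 1
  km0 <- kmEstimate(c(3, 7, 9), c(0, 0, 0))
  expect_true(all(km0@survival == 1))

  # single subject with an event drops to 0
  km1 <- kmEstimate(1, 1)
  expect_equal(km1@survival, 0)

  expect_error(kmEstimate(c(-1, 2), c(1, 0)), ">= 0")
})

test_that("KM without censoring is the empirical survival function", {
  set.seed(21)
  tt <- sort(sample(1:40, 25, replace = TRUE))
  km <- kmEstimate(tt, rep(1, 25))
  emp <- vapply(km@time, function(t) mean(tt > t), numeric(1))
  expect_equal(km@survival, emp)
})

test_that("log-rank test behaves on exchangeable and separated groups", {
  tt <- c(2, 5, 7, 11, 13)
  ev <- c(1, 0, 1, 1, 0)
  same <- logrankTest(tt, ev, tt, ev)
  expect_lt(same$chisq, 1e-10)
  expect_gt(same$p, 0.999)

  # extreme separation: all events in A, all censored later in B
  sep <- logrankTest(1:10, rep(1, 10), rep(20, 10), rep(0, 10))
  expect_gt(sep$chisq, 3.84)
  expect_lt(sep$p, 0.05)

  expect_error(logrankTest(numeric(0), integer(0), tt, ev), "at least one")
  expect_error(logrankTest(tt, rep(0, 5), tt, rep(0, 5)), "one event")
})

test_that("log-rank chi-squared agrees with survdiff and the permutation law", {
  fx <- randomSurvFixture(24, 31)
  grp <- rep(c(TRUE, FALSE), 12)
  ours <- logrankTest(fx$time[grp], fx$event[grp],
                      fx$time[!grp], fx$event[!grp])
  ref <- survival::survdiff(
    survival::Surv(fx$time, fx$event) ~ grp)
  expect_equal(ours$chisq, unname(ref$chisq), tolerance = 1e-8)

  # exact permutation oracle on a 12-subject fixture
  tt <- c(1, 3, 4, 6, 8, 10, 12, 13, 15, 18, 20, 22)
  ev <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0, 1, 1)
  g <- rep(c(1, 0), each = 6)
  obs <- logrankTest(tt[g == 1], ev[g == 1], tt[g == 0], ev[g == 0])
  splits <- utils::combn(12, 6)
  permChisq <- apply(splits, 2, function(idx) {
    gg <- rep(0, 12); gg[idx] <- 1
    logrankTest(tt[gg == 1], ev[gg == 1], tt[gg == 0], ev[gg == 0])$chisq
  })
  permP <- mean(permChisq >= obs$chisq - 1e-12)
  expect_lt(abs(obs$p - permP), 0.02)
})

test_that("Cox fit maximizes the partial likelihood (grid-search oracle)", {
  # 6 subjects, all events; the covariate must interleave the death order,
  # otherwise the partial likelihood is monotone (see the separation test)
  tt <- 1:6
  ev <- rep(1L, 6)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- coxFit(cbind(x = x), tt, ev)
  oracle <- stats::optimize(function(b) brutePartialLoglik(b, x, tt, ev),
                            c(-5, 5), maximum = TRUE)
  expect_lt(abs(unname(coef(fit)) - oracle$maximum), 1e-4)
})

test_that("Cox score test at beta = 0 equals the log-rank chi-squared", {
  set.seed(8)
  n <- 40
  tt <- rexp(n, 0.1) + cumsum(rep(1e-4, n))   # no ties
  ev <- rbinom(n, 1, 0.8)
  x <- rep(c(0, 1), n / 2)
  if (sum(ev) < 2) skip("degenerate draw")
  fit <- suppressWarnings(coxFit(cbind(x = x), tt, ev))
  lr <- logrankTest(tt[x == 1], ev[x == 1], tt[x == 0], ev[x == 0])
  expect_lt(abs(fit@scoreChisq - lr$chisq), 1e-6)
})

test_that("Cox fit agrees with the reference implementation on random fixtures", {
  set.seed(99)
  checked <- 0
  for (i in 1:50) {
    n <- sample(30:70, 1)
    X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
    tt <- rexp(n, 0.05 * exp(0.4 * X[, "a"]))
    if (i %% 2 == 0) tt <- ceiling(tt)           # tied times half the time
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) < 3 || stats::sd(X[, "b"]) == 0) next
    fit <- suppressWarnings(coxFit(X, tt, ev))
    ref <- survival::coxph(survival::Surv(tt, ev) ~ a + b,
                           data = data.frame(a = X[, "a"], b = X[, "b"]),
                           ties = "efron")
    expect_lt(max(abs(coef(fit) - coef(ref))), 1e-6)
    checked <- checked + 1
  }
  expect_gte(checked, 40)
})

test_that("Cox fit validates input and flags separation", {
  expect_error(coxFit(cbind(rep(0, 5)), 1:5, rep(1, 5)), "constant")
  expect_error(coxFit(cbind(1:4), 1:4, rep(0, 4)), "at least one event")
  # perfectly separating covariate: diverging beta must be flagged
  tt <- c(1, 2, 3, 10, 11, 12)
  ev <- rep(1L, 6)
  x <- c(1, 1, 1, 0, 0, 0)
  expect_warning(fit <- coxFit(cbind(x = x), tt, ev), "monotone|tolerance")
  expect_false(fit@converged)
})

test_that("Bonferroni adjustment follows min(1, m*p) and is monotone", {
  expect_equal(bonferroniAdjust(0.01, m = 3), 0.03)
  expect_equal(bonferroniAdjust(0.5, m = 4), 1.0)
  expect_equal(bonferroniAdjust(c(0.2, 0.7)), c(0.4, 1.0))
  expect_equal(bonferroniAdjust(0.37, m = 1), 0.37)
  p <- c(0.001, 0.2, 0.04, 0.9)
  adj <- bonferroniAdjust(p, m = 10)
  expect_equal(order(adj), order(p))
  expect_true(all(adj >= p))
  expect_error(bonferroniAdjust(1.2), "\\[0, 1\\]")
  expect_error(bonferroniAdjust(c(0.1, 0.2), m = 1), "at least")
})

test_that("mean time to event averages event times per group", {
  expect_equal(
    unname(meanTimeToEvent(c(10, 14), c(1, 1), c("a", "a"))["a"]), 12)
  # mixed 6-subject fixture: events at 4, 8 in g1 (mean 6); 10 in g2
  tt <- c(4, 8, 20, 10, 15, 30)
  ev <- c(1, 1, 0, 1, 0, 0)
  g <- c("g1", "g1", "g1", "g2", "g2", "g2")
  mt <- meanTimeToEvent(tt, ev, g)
  expect_equal(unname(mt["g1"]), 6)
  expect_equal(unname(mt["g2"]), 10)
  expect_warning(
    mt0 <- meanTimeToEvent(c(5, 7), c(0, 1), c("a", "b")), "zero events")
  expect_true(is.na(mt0["a"]))
})

test_that("Pearson correlation handles exact and null relationships", {
  x <- c(1, 2, 3, 5, 9)
  expect_equal(pearsonR(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearsonR(x, -x)$r, -1.0)
  set.seed(12)
  nullR <- pearsonR(rnorm(1000), rnorm(1000))
  expect_lt(abs(nullR$r), 0.1)
  expect_error(pearsonR(x, rep(2, 5)), "variance")
  expect_error(pearsonR(1:2, 1:2), "length >= 3")
})
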