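test_that("candidate cutoffs are midpoints respecting the group floor", {
  expect_equal(candidateCutoffs(c(1, 2, 3, 4), minGroup = 1),
               c(1.5, 2.5, 3.5))
  expect_equal(candidateCutoffs(c(1, 2, 3, 4, 5, 6), minGroup = 2),
               c(2.5, 3.5, 4.5))
  # ties collapse to distinct values before taking midpoints
  expect_equal(candidateCutoffs(c(1, 1, 2, 2, 3), minGroup = 2), 1.5)
  expect_error(candidateCutoffs(rep(2, 8)), "constant")
  expect_error(candidateCutoffs(c(1, 2), minGroup = 2), "too few")
})

test_that("log-rank score matches the hand O-E table and is antisymmetric", {
  # 8-subject fixture, hand-summed O-E table for the high group
  # (subjects 1-4 above the 4.5 cutoff):
  #   t=1: d+=1, d=1, r+=4, r=8 -> 1 - 4/8 = 1/2
  #   t=2: d+=0, d=1, r+=3, r=7 -> 0 - 3/7
  #   t=3: d+=1, d=1, r+=3, r=6 -> 1 - 3/6 = 1/2
  #   t=5: d+=1, d=2, r+=2, r=5 -> 1 - 4/5 = 1/5
  vals <- c(5, 6, 7, 8, 1, 2, 3, 4)
  tt <- c(1, 3, 5, 9, 2, 5, 6, 7)
  ev <- c(1, 1, 1, 0, 1, 1, 0, 0)
  hand <- 0.5 - 3 / 7 + 0.5 + 0.2
  expect_equal(logrankScore(vals, 4.5, tt, ev), hand)
  expect_equal(logrankScore(vals, 4.5, tt, ev),
               bruteLogrankScore(vals, 4.5, tt, ev))

  # identical survival experience in both groups: O = E
  v2 <- rep(c(0, 1), 5)
  t2 <- rep(c(2, 4, 6, 8, 10), each = 2)
  e2 <- rep(c(1, 1, 0, 1, 0), each = 2)
  expect_lt(abs(logrankScore(v2, 0.5, t2, e2)), 1e-12)

  # flipping group labels flips the sign
  expect_equal(logrankScore(-vals, -4.5, tt, ev),
               -logrankScore(vals, 4.5, tt, ev))

  expect_error(logrankScore(vals, 100, tt, ev), "non-empty")
})

test_that("bestCutpoint equals the exhaustive-split oracle on small fixtures", {
  checked <- 0
  for (i in 1:40) {
    fx <- randomSurvFixture(sample(10:30, 1), 400 + i)
    if (sum(fx$event) < 2) next
    mg <- sample(1:3, 1)
    cand <- tryCatch(candidateCutoffs(fx$values, mg),
                     error = function(e) NULL)
    if (is.null(cand)) next
    res <- bestCutpoint(fx$values, fx$time, fx$event, minGroup = mg)
    oracle <- bruteBestSplit(fx$values, fx$time, fx$event, mg)
    expect_equal(res@bestCutoff, oracle$cutoff, tolerance = 1e-12)
    expect_equal(res@Q, oracle$Q, tolerance = 1e-12)
    expect_equal(res@scores, oracle$scores, tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gte(checked, 30)
})

test_that("bestCutpoint is scale/shift and time-relabeling invariant", {
  fx <- randomSurvFixture(60, 77)
  res <- bestCutpoint(fx$values, fx$time, fx$event, minGroup = 8)

  # affine transform of the marker: cutoff maps along, Q and p unchanged
  res2 <- bestCutpoint(3.5 * fx$values + 2, fx$time, fx$event, minGroup = 8)
  expect_equal(res2@bestCutoff, 3.5 * res@bestCutoff + 2, tolerance = 1e-9)
  expect_equal(res2@Q, res@Q)
  expect_equal(res2@pValue, res@pValue)

  # strictly increasing time transform: rank statistic unchanged
  res3 <- bestCutpoint(fx$values, fx$time^2 + fx$time, fx$event,
                       minGroup = 8)
  expect_equal(res3@bestCutoff, res@bestCutoff)
  expect_equal(res3@Q, res@Q)
  expect_equal(res3@pValue, res@pValue)

  expect_error(bestCutpoint(rep(1, 60), fx$time, fx$event), "constant")
  expect_error(bestCutpoint(fx$values, fx$time, rep(0, 60)), "two events")
})

test_that("the supremum-Brownian-bridge series evaluates correctly", {
  # 1.358 is the classical 5% critical value of the sup-bridge law
  expect_equal(cutpointPvalue(1.358), 0.0503, tolerance = 1e-2)
  # direct series evaluation frozen from the formula
  expect_equal(cutpointPvalue(1.358),
               2 * sum((-1)^(1:20 + 1) * exp(-2 * (1:20)^2 * 1.358^2)))
  expect_equal(cutpointPvalue(0), 1)
  expect_lt(cutpointPvalue(5), 1e-10)
  expect_error(cutpointPvalue(-1), ">= 0")
})

test_that("naive minimal-p is never above the corrected p-value's naive part", {
  fx <- randomSurvFixture(80, 55)
  naive <- naiveMinPvalue(fx$values, fx$time, fx$event, minGroup = 10)
  expect_true(naive$p >= 0 && naive$p <= 1)
  expect_equal(naive$nCandidates,
               length(candidateCutoffs(fx$values, 10)))
  # the naive minimum cannot exceed the single-cutoff p at its own cutoff
  high <- fx$values > naive$cutoff
  lr <- logrankTest(fx$time[high], fx$event[high],
                    fx$time[!high], fx$event[!high])
  expect_equal(naive$p, lr$p, tolerance = 1e-9)
})
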