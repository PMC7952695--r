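test_that("cohort simulation is deterministic and leaves global RNG alone", {
  cfg <- simulationConfig(nSamples = 40, nGenes = 10,
                          planted = list(plantedEffect(3, 1, 2)), seed = 5)
  set.seed(999)
  before <- .Random.seed
  a <- simulateCohort(cfg)
  expect_identical(.Random.seed, before)
  b <- simulateCohort(cfg)
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  expect_identical(clinicalData(a), clinicalData(b))
  # different seed changes the draw
  c2 <- simulateCohort(simulationConfig(nSamples = 40, nGenes = 10,
                                        seed = 6))
  expect_false(identical(SummarizedExperiment::assay(a)[1, ],
                         SummarizedExperiment::assay(c2)[1, ]))
})

test_that("simulated expression is on the z-score scale", {
  cfg <- simulationConfig(nSamples = 500, nGenes = 20, seed = 11)
  expr <- SummarizedExperiment::assay(simulateCohort(cfg))
  expect_lt(max(abs(rowMeans(expr))), 0.2)
  expect_lt(max(abs(apply(expr, 1, sd) - 1)), 0.2)
})

test_that("simulation config validates its invariants", {
  expect_error(simulationConfig(nSamples = 1), ">= 2")
  expect_error(simulationConfig(baselineHazard = 0), "positive")
  expect_error(simulationConfig(censoringRate = -1), "positive")
  expect_error(
    simulationConfig(nGenes = 5,
                     planted = list(plantedEffect(9, 1, 2))), "exceeds")
  expect_error(
    simulationConfig(planted = list(plantedEffect(1, 1, 2),
                                    plantedEffect(1, 0, 3))), "distinct")
  expect_error(plantedEffect(1, hr = -2), "positive")
})

test_that("planted hazard ratio is recovered by a Cox fit on the true split", {
  # Monte-Carlo recovery: median estimated HR across replicates near truth
  hrs <- vapply(1:100, function(r) {
    cfg <- simulationConfig(nSamples = 400, nGenes = 1,
                            planted = list(plantedEffect(1, 1.0, 3.0)),
                            seed = 100 + r)
    ch <- simulateCohort(cfg)
    x <- SummarizedExperiment::assay(ch)[1, ]
    fit <- suppressWarnings(
      coxFit(cbind(g = as.numeric(x > 1)), survTime(ch), survEvent(ch)))
    unname(fit@hr)
  }, numeric(1))
  expect_lt(abs(median(hrs) - 3.0), 0.45)   # within 15% of 3.0
})

test_that("null cohorts give approximately uniform cutpoint p-values", {
  # The supremum-bridge p-value is mildly conservative at this design
  # (the group-size floor restricts the candidate range while the limiting
  # law assumes the full bridge), so strict KS uniformity is not attainable
  # at 500 genes; the quantiles sit within ~0.1 of nominal and the
  # rejection rate at 0.05 is calibrated.
  cfg <- simulationConfig(nSamples = 200, nGenes = 500, seed = 2024)
  ch <- simulateCohort(cfg)
  expr <- SummarizedExperiment::assay(ch)
  tt <- survTime(ch)
  ev <- survEvent(ch)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    bestCutpoint(expr[i, ], tt, ev)@pValue
  }, numeric(1))
  q <- stats::quantile(p, c(0.25, 0.5, 0.75))
  expect_lt(max(abs(q - c(0.25, 0.5, 0.75))), 0.12)
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.08)
})

test_that("IHC field simulation conserves cell counts", {
  m <- simulateIhcFields(nFields = 3, nCells = 200,
                         categoryProbs = c(0.4, 0.3, 0.2, 0.1), seed = 1)
  expect_equal(dim(m), c(4L, 3L))
  expect_true(all(colSums(m) == 200))
  # determinism
  expect_identical(m, simulateIhcFields(3, 200, c(0.4, 0.3, 0.2, 0.1), 1))

  # degenerate multinomial: every cell negative
  m0 <- simulateIhcFields(5, 100, c(1, 0, 0, 0), seed = 2)
  expect_true(all(m0["negative", ] == 100))
  expect_true(all(m0[c("low", "positive", "high"), ] == 0))

  # multinomial expectation: mean per-category count near n * p
  mm <- simulateIhcFields(1000, 200, rep(0.25, 4), seed = 3)
  expect_true(all(abs(rowMeans(mm) - 50) < 3))

  expect_error(simulateIhcFields(3, 200, c(0.5, 0.5, 0.1, 0.1), 1),
               "sum to 1")
})

test_that("PSA recurrence rules follow the therapy-specific criteria", {
  # RP: first value > 0.2 that also rises above its predecessor
  rp <- recurrenceFromPsa(c(3, 6, 9), c(0.10, 0.25, 0.30), "RP")
  expect_equal(rp, list(time = 6, event = 1L))
  # RT: first value > nadir + 2 (event at the last measurement is an event)
  rt <- recurrenceFromPsa(c(6, 12, 18), c(1.0, 2.0, 3.1), "RT", nadir = 0.5)
  expect_equal(rt, list(time = 18, event = 1L))
  # criterion never met: censored at the last measurement
  cn <- recurrenceFromPsa(c(3, 6), c(0.05, 0.04), "RP")
  expect_equal(cn, list(time = 6, event = 0L))
  # a first measurement alone is never "rising"
  first <- recurrenceFromPsa(c(3, 6), c(0.5, 0.4), "RP")
  expect_equal(first$event, 0L)
  # HT: rising PSA only counts at castrate testosterone
  ht <- recurrenceFromPsa(c(3, 6), c(1, 2), "HT", testosterone = 20)
  expect_equal(ht, list(time = 6, event = 1L))
  htHigh <- recurrenceFromPsa(c(3, 6), c(1, 2), "HT", testosterone = 300)
  expect_equal(htHigh$event, 0L)

  expect_error(recurrenceFromPsa(c(6, 3), c(1, 2), "RP"), "increasing")
  expect_error(recurrenceFromPsa(c(3, 6), c(1, 2), "RT"), "nadir")
  expect_error(recurrenceFromPsa(c(3, 6), c(1, 2), "HT"), "testosterone")
})
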