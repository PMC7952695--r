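makeCpRes <- function(cutoff, p, hr) {
  methods::new("CutpointResult", gene = "X", candidates = cutoff,
               scores = 1, bestCutoff = cutoff, scale = 1, nEvents = 10L,
               Q = 1, pValue = p, hr = hr, ciLow = hr / 2, ciHigh = hr * 2,
               hrP = 0.01,
               direction = if (hr > 1) "high_worse" else "high_better",
               nHigh = 5L, nLow = 5L, converged = TRUE)
}

screenFixture <- function(seed = 77) {
  planted <- lapply(c(5, 20, 40, 60, 80), plantedEffect,
                    cutoffZ = 1.2, hr = 3)
  simulateCohort(simulationConfig(nSamples = 300, nGenes = 100,
                                  planted = planted, seed = seed))
}

test_that("gene classification maps band and hazard direction correctly", {
  # overexpression cutoff with worse outcome above: the canonical
  # poor-prognosis overexpression call (cutoff z = 1.0951, HR > 1)
  expect_equal(classifyGene(makeCpRes(1.0951, 0.001, 3.2)),
               "shorter_survival_over")
  # cutoff at the cohort mean: no expression class, excluded
  expect_equal(classifyGene(makeCpRes(0, 0.001, 3)), "excluded")
  # non-significant genes are excluded regardless of the cutoff
  expect_equal(classifyGene(makeCpRes(1.5, 0.2, 3)), "excluded")
  # under-expression cutoff where the low group fares worse
  expect_equal(classifyGene(makeCpRes(-1.3, 0.01, 0.4)),
               "shorter_survival_under")
  # remaining quadrants of the 2x2 mapping
  expect_equal(classifyGene(makeCpRes(1.2, 0.01, 0.5)),
               "longer_survival_over")
  expect_equal(classifyGene(makeCpRes(-1.2, 0.01, 2.0)),
               "longer_survival_under")
  # band edges are inclusive
  expect_equal(classifyGene(makeCpRes(1.0, 0.01, 2.0)),
               "shorter_survival_over")
  # z-sign rule ignores the hazard direction
  expect_equal(classifyGene(makeCpRes(1.2, 0.01, 0.5), rule = "zsign"),
               "shorter_survival_over")
})

test_that("screen counts conserve and lists partition correctly", {
  ch <- screenFixture()
  sc <- screenGenes(ch)
  cc <- cascadeCounts(sc)
  expect_equal(cc[["analyzed"]] + cc[["skipped"]], cc[["total"]])
  expect_equal(cc[["total"]], 100L)
  expect_lte(cc[["associated"]], cc[["analyzed"]])
  expect_lte(cc[["banded"]], cc[["associated"]])
  expect_equal(cc[["shorter"]] + cc[["longer"]], cc[["banded"]])
  expect_length(intersect(shorterSurvivalGenes(sc),
                          longerSurvivalGenes(sc)), 0)
  # per-row class agrees with the filters
  tab <- as.data.frame(screenTable(sc))
  banded <- tab$p < 0.05 & (tab$cutoffZ >= 1 | tab$cutoffZ <= -1)
  expect_equal(tab$class != "excluded", banded)
})

test_that("screen is invariant to gene and sample ordering", {
  ch <- screenFixture()
  sc <- screenGenes(ch)
  perm <- ch[sample(nrow(ch)), sample(ncol(ch))]
  sc2 <- screenGenes(perm)
  t1 <- as.data.frame(screenTable(sc))
  t2 <- as.data.frame(screenTable(sc2))
  t2 <- t2[match(t1$gene, t2$gene), ]
  rownames(t2) <- NULL
  expect_equal(t1[, setdiff(names(t1), "pBH")],
               t2[, setdiff(names(t2), "pBH")], tolerance = 1e-10)
})

test_that("tightening thresholds never adds genes to the output lists", {
  ch <- screenFixture()
  loose <- screenGenes(ch, alpha = 0.05, zHi = 1, zLo = -1)
  tight <- screenGenes(ch, alpha = 0.01, zHi = 1.2, zLo = -1.2)
  expect_true(all(survivalAssociated(tight) %in% survivalAssociated(loose)))
  expect_true(all(shorterSurvivalGenes(tight) %in%
                    shorterSurvivalGenes(loose)))
  expect_true(all(longerSurvivalGenes(tight) %in%
                    longerSurvivalGenes(loose)))
  # impossible threshold empties everything
  none <- screenGenes(ch, alpha = 0)
  expect_length(survivalAssociated(none), 0)
  expect_length(shorterSurvivalGenes(none), 0)
  expect_length(longerSurvivalGenes(none), 0)
})

test_that("a dominant planted effect tops the screen", {
  ch <- simulateCohort(simulationConfig(
    nSamples = 250, nGenes = 20,
    planted = list(plantedEffect(7, cutoffZ = 0.5, hr = 6)), seed = 9))
  sc <- screenGenes(ch)
  tab <- as.data.frame(screenTable(sc))
  expect_equal(tab$gene[which.min(tab$p)], "G0007")
  expect_gt(tab$hr[tab$gene == "G0007"], 1)
})

test_that("constant genes are skipped with a reason, not dropped silently", {
  ch <- screenFixture()
  SummarizedExperiment::assay(ch)[3, ] <- 0
  sc <- screenGenes(ch)
  expect_equal(sc@skipped$gene, "G0003")
  expect_match(sc@skipped$reason, "constant")
  expect_equal(cascadeCounts(sc)[["analyzed"]], 99L)
})

test_that("gene report returns KM curves, Cox tables and mean times", {
  ch <- screenFixture()
  rep <- suppressWarnings(geneReport(ch, "G0005"))
  expect_s4_class(rep$kmHigh, "KMCurve")
  expect_s4_class(rep$kmLow, "KMCurve")
  expect_s4_class(rep$coxUnivariate, "CoxFit")
  expect_s4_class(rep$coxMultivariate, "CoxFit")
  # adjusted model: gene + age + gs + t_category + ipsa
  expect_equal(names(coef(rep$coxMultivariate)),
               c("G0005", "age", "gs", "t_category", "ipsa"))
  # Bonferroni across the model's m covariates
  m <- length(coef(rep$coxMultivariate))
  expect_equal(rep$coxMultivariate@pAdjusted,
               pmin(1, m * rep$coxMultivariate@pValues))
  expect_named(rep$meanTime, c("high", "low"), ignore.order = TRUE)

  expect_error(geneReport(ch, "NOPE"), "not found")
  expect_error(suppressWarnings(geneReport(ch, "G0005", cutoff = -99)),
               "empty group")
})

test_that("adjusting for a planted confounder attenuates the gene's HR", {
  # gene 1 has no causal effect; it is correlated (rho 0.7) with Gleason
  # score, which drives the hazard. The multivariate HR must shrink
  # toward 1 relative to the univariate HR.
  cfg <- simulationConfig(
    nSamples = 400, nGenes = 2,
    covariateBetas = c(gs = 0.8),
    confound = list(geneIndex = 1L, covariate = "gs", rho = 0.7),
    seed = 314)
  ch <- simulateCohort(cfg)
  rep <- suppressWarnings(
    geneReport(ch, "G0001", cutoff = 0, covariates = "gs"))
  bUni <- abs(coef(rep$coxUnivariate)[["G0001"]])
  bAdj <- abs(coef(rep$coxMultivariate)[["G0001"]])
  expect_gt(bUni, 0.2)          # confounding induces a marginal effect
  expect_lt(bAdj, bUni)         # adjustment attenuates it
})
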