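## Synthetic cohorts with the statistical structure the screen assumes:
## z-scored expression, proportional-hazards recurrence with planted
## cutpoint effects, independent censoring, clinical covariates, and
## multinomial IHC fields.

#' Planted cutpoint effect
#'
#' Ground truth for one prognostic gene in a simulated cohort: subjects
#' whose expression exceeds `cutoffZ` have their hazard multiplied by `hr`.
#'
#' @param geneIndex 1-based row index of the affected gene.
#' @param cutoffZ true expression cutoff on the z-score scale.
#' @param hr true hazard ratio (> 0) of above- vs below-cutoff subjects.
#' @return a validated list of class `PlantedEffect`.
#' @export
plantedEffect <- function(geneIndex, cutoffZ = 1, hr = 3) {
  geneIndex <- checkScalarCount(geneIndex, "geneIndex")
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0) {
    stop("'hr' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(cutoffZ) || length(cutoffZ) != 1L || !is.finite(cutoffZ)) {
    stop("'cutoffZ' must be a single finite number", call. = FALSE)
  }
  structure(list(geneIndex = geneIndex, cutoffZ = cutoffZ, hr = hr),
            class = "PlantedEffect")
}

#' Simulation configuration
#'
#' Defines a synthetic cohort emulating a TCGA-style high-risk prostate
#' cancer sub-cohort: z-scored expression, exponential recurrence hazard
#' under proportional hazards, independent exponential censoring truncated
#' at an administrative follow-up limit, and clinical covariates (age in
#' years, Gleason score 8-10, ordinal T category, initial PSA).
#'
#' Defaults mirror the high-risk cohort the screen is designed for:
#' 201 samples; baseline recurrence hazard 0.015 / month and censoring
#' rate 0.02 / month over a 120-month follow-up window, giving roughly 40%
#' observed events with event times on the scale of a few years.
#'
#' @param nSamples number of samples (>= 2).
#' @param nGenes number of genes (>= 1).
#' @param planted list of [plantedEffect()] objects; gene indices must be
#'   distinct and `<= nGenes`.
#' @param baselineHazard baseline recurrence rate per month (> 0).
#' @param censoringRate censoring rate per month (> 0).
#' @param maxFollowup administrative censoring time in months (> 0).
#' @param covariateBetas optional named numeric vector of log-hazard
#'   effects of standardized covariates (names among `age`, `gs`,
#'   `t_category`, `ipsa`) — used to plant confounding.
#' @param confound optional list `(geneIndex, covariate, rho)`: the
#'   expression of that gene is given correlation `rho` with the
#'   standardized covariate (and remains ~ N(0, 1)).
#' @param seed integer seed; the generator never touches global RNG state.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nSamples = 201L, nGenes = 300L,
                             planted = list(), baselineHazard = 0.015,
                             censoringRate = 0.02, maxFollowup = 120,
                             covariateBetas = NULL, confound = NULL,
                             seed = 1L) {
  nSamples <- checkScalarCount(nSamples, "nSamples", min = 2L)
  nGenes <- checkScalarCount(nGenes, "nGenes", min = 1L)
  for (nm in c("baselineHazard", "censoringRate", "maxFollowup")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("'", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  if (!is.list(planted) ||
      !all(vapply(planted, inherits, logical(1), "PlantedEffect"))) {
    stop("'planted' must be a list of plantedEffect() objects",
         call. = FALSE)
  }
  idx <- vapply(planted, `[[`, integer(1), "geneIndex")
  if (anyDuplicated(idx)) {
    stop("planted gene indices must be distinct", call. = FALSE)
  }
  if (length(idx) && max(idx) > nGenes) {
    stop("planted gene index exceeds nGenes", call. = FALSE)
  }
  if (!is.null(covariateBetas)) {
    if (is.null(names(covariateBetas)) ||
        !all(names(covariateBetas) %in% c("age", "gs", "t_category",
                                          "ipsa"))) {
      stop("'covariateBetas' must be named with clinical covariates",
           call. = FALSE)
    }
  }
  if (!is.null(confound)) {
    stopifnot(is.list(confound),
              all(c("geneIndex", "covariate", "rho") %in% names(confound)))
    if (abs(confound$rho) >= 1) stop("'rho' must be in (-1, 1)",
                                     call. = FALSE)
  }
  structure(
    list(nSamples = nSamples, nGenes = nGenes, planted = planted,
         baselineHazard = baselineHazard, censoringRate = censoringRate,
         maxFollowup = maxFollowup, covariateBetas = covariateBetas,
         confound = confound, seed = as.integer(seed)),
    class = "SimulationConfig"
  )
}

#' Simulate an expression + survival cohort
#'
#' Expression is drawn i.i.d. standard normal per gene, so the matrix is
#' self-consistently on the z-score scale (per-gene mean ~ 0, sd ~ 1).
#' Each sample's recurrence hazard is
#' `baselineHazard * prod(hr^(expr > cutoffZ))` over the planted effects
#' (times `exp(beta * scaled covariate)` for any `covariateBetas`); the
#' event time is exponential at that hazard, the censoring time is
#' exponential at `censoringRate` truncated at `maxFollowup`, observed
#' time is the minimum and `event = (event time <= censoring time)`.
#' Covariates emulate a high-risk (Gleason >= 8) prostate cohort: age
#' ~ N(62, 7.5) clipped to 44-78, Gleason score in 8-10, ordinal T
#' category 2-4, log-normal initial PSA, therapy "RP".
#'
#' The same configuration (including seed) always reproduces the identical
#' cohort, and the global RNG state is left untouched.
#'
#' @param config a [simulationConfig()].
#' @return a [SurvCohort-class]; the truth (planted effects, config) is in
#'   `metadata()`.
#' @export
simulateCohort <- function(config) {
  if (!inherits(config, "SimulationConfig")) {
    stop("'config' must come from simulationConfig()", call. = FALSE)
  }
  withSeed(config$seed, {
    G <- config$nGenes
    N <- config$nSamples
    genes <- sprintf("G%04d", seq_len(G))
    samples <- sprintf("S%03d", seq_len(N))
    expr <- matrix(stats::rnorm(G * N), nrow = G,
                   dimnames = list(genes, samples))

    age <- pmin(pmax(stats::rnorm(N, 62.4, 7.5), 44), 78)
    gs <- sample(8:10, N, replace = TRUE, prob = c(0.30, 0.63, 0.07))
    t_category <- sample(2:4, N, replace = TRUE, prob = c(0.14, 0.82, 0.04))
    ipsa <- stats::rlnorm(N, meanlog = log(15), sdlog = 0.9)
    covs <- data.frame(age = age, gs = gs, t_category = t_category,
                       ipsa = ipsa, therapy = "RP",
                       row.names = samples)

    if (!is.null(config$confound)) {
      cf <- config$confound
      zc <- as.numeric(scale(covs[[cf$covariate]]))
      expr[cf$geneIndex, ] <- sqrt(1 - cf$rho^2) * expr[cf$geneIndex, ] +
        cf$rho * zc
    }

    hazard <- rep(config$baselineHazard, N)
    for (pe in config$planted) {
      hazard <- hazard * pe$hr^(expr[pe$geneIndex, ] > pe$cutoffZ)
    }
    if (!is.null(config$covariateBetas)) {
      for (nm in names(config$covariateBetas)) {
        hazard <- hazard *
          exp(config$covariateBetas[[nm]] * as.numeric(scale(covs[[nm]])))
      }
    }
    eventTime <- stats::rexp(N, rate = hazard)
    censTime <- pmin(stats::rexp(N, rate = config$censoringRate),
                     config$maxFollowup)
    covs$time <- pmin(eventTime, censTime)
    covs$event <- as.integer(eventTime <= censTime)

    cohort <- SurvCohort(expr, covs)
    S4Vectors::metadata(cohort)$config <- config
    S4Vectors::metadata(cohort)$planted <- config$planted
    cohort
  })
}

#' Simulate per-field IHC intensity-category counts
#'
#' Each high-power field is an independent multinomial draw of `nCells`
#' cells over the four staining categories (negative, low, positive,
#' high), emulating manual evaluation of > 200 cells in each of three
#' fields.
#'
#' @param nFields number of fields (default 3).
#' @param nCells cells per field (>= 1; default 200).
#' @param categoryProbs 4 probabilities summing to 1 (tolerance 1e-9) in
#'   category order negative, low, positive, high.
#' @param seed integer seed.
#' @return integer matrix, 4 categories x `nFields` (columns `field1`,
#'   ...); column sums equal `nCells` exactly.
#' @export
simulateIhcFields <- function(nFields = 3L, nCells = 200L,
                              categoryProbs = c(0.4, 0.3, 0.2, 0.1),
                              seed = 1L) {
  nFields <- checkScalarCount(nFields, "nFields")
  nCells <- checkScalarCount(nCells, "nCells")
  if (length(categoryProbs) != 4L || anyNA(categoryProbs) ||
      any(categoryProbs < 0)) {
    stop("'categoryProbs' must be 4 non-negative probabilities",
         call. = FALSE)
  }
  if (abs(sum(categoryProbs) - 1) > 1e-9) {
    stop("'categoryProbs' must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  withSeed(seed, {
    m <- stats::rmultinom(nFields, size = nCells, prob = categoryProbs)
    dimnames(m) <- list(.hscoreCategories,
                        paste0("field", seq_len(nFields)))
    m
  })
}

#' Biochemical recurrence from a PSA series
#'
#' Applies the therapy-specific PSA criteria for biochemical recurrence:
#' after radical prostatectomy (RP), the first PSA value > 0.2 ng/mL that
#' is also rising; after radiotherapy (RT), the first PSA value
#' > nadir + 2 ng/mL; after hormonal therapy (HT), the first rising PSA
#' value provided serum testosterone is < 50 ng/dL (castrate). "Rising"
#' means strictly greater than the immediately preceding measurement, so
#' a first measurement alone can never qualify. If no criterion is met the
#' subject is censored at the last measurement; a criterion met exactly at
#' the last measurement is an event.
#'
#' @param months strictly increasing measurement times (months).
#' @param psa PSA values (ng/mL), same length.
#' @param therapy one of `"RP"`, `"RT"`, `"HT"`.
#' @param nadir post-RT PSA nadir (ng/mL); required for RT.
#' @param testosterone serum testosterone (ng/dL); required for HT.
#' @return list with `time` (months) and `event` (0/1).
#' @examples
#' recurrenceFromPsa(c(3, 6, 9), c(0.10, 0.25, 0.30), "RP")
#' # event at month 6
#' @export
recurrenceFromPsa <- function(months, psa, therapy = c("RP", "RT", "HT"),
                              nadir = NULL, testosterone = NULL) {
  therapy <- match.arg(therapy)
  if (length(months) != length(psa) || length(months) < 1L) {
    stop("'months' and 'psa' must be non-empty and of equal length",
         call. = FALSE)
  }
  if (anyNA(months) || anyNA(psa)) {
    stop("PSA series must not contain NA", call. = FALSE)
  }
  if (is.unsorted(months, strictly = TRUE)) {
    stop("'months' must be strictly increasing", call. = FALSE)
  }
  rising <- c(FALSE, diff(psa) > 0)
  hit <- switch(therapy,
    RP = psa > 0.2 & rising,
    RT = {
      if (is.null(nadir)) stop("'nadir' is required for RT", call. = FALSE)
      psa > nadir + 2
    },
    HT = {
      if (is.null(testosterone)) {
        stop("'testosterone' is required for HT", call. = FALSE)
      }
      if (testosterone >= 50) rep(FALSE, length(psa)) else rising
    }
  )
  if (any(hit)) {
    list(time = months[which(hit)[1L]], event = 1L)
  } else {
    list(time = months[length(months)], event = 0L)
  }
}
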