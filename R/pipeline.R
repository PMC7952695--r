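## Pipeline orchestration: a single structured config drives simulate ->
## screen -> report -> hscore -> enrich, with manifests for
## reproducibility. A thin command-line wrapper over these functions ships
## in inst/scripts/cutscreen.R.

#' Read a pipeline configuration
#'
#' YAML with optional blocks `paths` (expression, clinical, outDir, ...),
#' `thresholds` (alpha, zHi, zLo, minGroup), `simulation` (arguments of
#' [simulationConfig()]; `planted` as a list of `{geneIndex, cutoffZ, hr}`
#' entries), `covariates` (for multivariate models) and a top-level `seed`.
#' Thresholds are validated immediately so a bad config fails before any
#' file is written.
#'
#' @param path YAML file path.
#' @return config list (class `PipelineConfig`).
#' @export
readPipelineConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files",
         call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg)
}

#' Validate a pipeline configuration list
#'
#' @param cfg a list as produced by [readPipelineConfig()] or built in R.
#' @return the config, with threshold defaults filled in.
#' @export
validatePipelineConfig <- function(cfg) {
  stopifnot(is.list(cfg))
  th <- cfg$thresholds
  if (is.null(th)) th <- list()
  th$alpha <- if (is.null(th$alpha)) 0.05 else th$alpha
  th$zHi <- if (is.null(th$zHi)) 1 else th$zHi
  th$zLo <- if (is.null(th$zLo)) -1 else th$zLo
  if (th$alpha < 0 || th$alpha > 1) {
    stop("config error: alpha must be in [0, 1]", call. = FALSE)
  }
  if (th$zLo >= th$zHi) {
    stop("config error: zLo must be below zHi", call. = FALSE)
  }
  if (!is.null(th$minGroup)) checkScalarCount(th$minGroup, "minGroup")
  cfg$thresholds <- th
  if (is.null(cfg$seed)) cfg$seed <- 1L
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

.simConfigFrom <- function(cfg) {
  sim <- cfg$simulation
  if (is.null(sim)) sim <- list()
  planted <- lapply(sim$planted, function(pe) {
    plantedEffect(pe$geneIndex,
                  cutoffZ = if (is.null(pe$cutoffZ)) 1 else pe$cutoffZ,
                  hr = if (is.null(pe$hr)) 3 else pe$hr)
  })
  args <- sim[setdiff(names(sim), "planted")]
  args$planted <- planted
  args$seed <- if (is.null(sim$seed)) cfg$seed else sim$seed
  do.call(simulationConfig, args)
}

.writeManifest <- function(outDir, step, cfg) {
  flat <- paste(deparse(cfg[setdiff(names(cfg), "paths")]), collapse = "")
  hash <- sprintf("%08x",
                  sum(utf8ToInt(flat) * seq_along(utf8ToInt(flat))) %%
                    .Machine$integer.max)
  writeLines(
    c(sprintf("step\t%s", step),
      sprintf("seed\t%s", cfg$seed),
      sprintf("param_hash\t%s", hash),
      sprintf("timestamp\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    file.path(outDir, paste0("manifest_", step, ".tsv"))
  )
}

#' Simulate a cohort and write it to disk
#'
#' Generates the configured synthetic cohort and writes the expression
#' matrix and clinical table in the same TSV dialects the readers consume,
#' plus a manifest recording seed and parameter hash.
#'
#' @param cfg validated pipeline config (see [readPipelineConfig()]).
#' @return invisibly, the written file paths.
#' @export
runSimulate <- function(cfg) {
  cfg <- validatePipelineConfig(cfg)
  outDir <- if (is.null(cfg$paths$outDir)) "." else cfg$paths$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulateCohort(.simConfigFrom(cfg))
  exprPath <- file.path(outDir, "expression.tsv")
  clinPath <- file.path(outDir, "clinical.tsv")
  writeExpressionMatrix(SummarizedExperiment::assay(cohort), exprPath)
  writeClinicalTable(clinicalData(cohort), clinPath)
  .writeManifest(outDir, "simulate", cfg)
  message("wrote ", exprPath, " and ", clinPath)
  invisible(list(expression = exprPath, clinical = clinPath))
}

.loadCohort <- function(cfg) {
  exprPath <- cfg$paths$expression
  clinPath <- cfg$paths$clinical
  if (is.null(exprPath) || is.null(clinPath)) {
    outDir <- if (is.null(cfg$paths$outDir)) "." else cfg$paths$outDir
    if (is.null(exprPath)) exprPath <- file.path(outDir, "expression.tsv")
    if (is.null(clinPath)) clinPath <- file.path(outDir, "clinical.tsv")
  }
  expr <- readExpressionMatrix(exprPath, dialect = "plain")
  clin <- readClinicalTable(clinPath)
  al <- alignSamples(expr, clin)
  SurvCohort(al$expr, al$clin)
}

#' Run the genome-wide screen from files
#'
#' Reads the configured expression and clinical TSVs, aligns samples, runs
#' [screenGenes()] at the configured thresholds, writes the per-gene table
#' and prints the screening cascade (analyzed, associated, banded,
#' shorter / longer) so runs can be compared at a glance.
#'
#' @param cfg validated pipeline config.
#' @return the [ScreenResult-class], invisibly.
#' @export
runScreen <- function(cfg) {
  cfg <- validatePipelineConfig(cfg)
  cohort <- .loadCohort(cfg)
  th <- cfg$thresholds
  screen <- screenGenes(cohort, alpha = th$alpha, zHi = th$zHi,
                        zLo = th$zLo, minGroup = th$minGroup)
  outDir <- if (is.null(cfg$paths$outDir)) "." else cfg$paths$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeScreenResult(screen, file.path(outDir, "screen.tsv"))
  .writeManifest(outDir, "screen", cfg)
  cc <- cascadeCounts(screen)
  message(sprintf(
    "cascade: %d analyzed -> %d associated -> %d banded -> %d shorter + %d longer",
    cc[["analyzed"]], cc[["associated"]], cc[["banded"]],
    cc[["shorter"]], cc[["longer"]]))
  invisible(screen)
}

#' Single-gene survival report from files
#'
#' Runs [geneReport()] for one gene and writes the KM curves of both
#' groups and the Cox tables (unadjusted and covariate-adjusted, with
#' Bonferroni columns) as TSVs.
#'
#' @param cfg validated pipeline config.
#' @param gene gene symbol.
#' @param cutoff optional fixed cutoff (default: optimal cutpoint).
#' @return the [geneReport()] list, invisibly.
#' @export
runReport <- function(cfg, gene, cutoff = NULL) {
  cfg <- validatePipelineConfig(cfg)
  cohort <- .loadCohort(cfg)
  rep <- geneReport(cohort, gene, cutoff = cutoff,
                    covariates = cfg$covariates,
                    minGroup = cfg$thresholds$minGroup)
  outDir <- if (is.null(cfg$paths$outDir)) "." else cfg$paths$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeKMCurve(rep$kmHigh, file.path(outDir, paste0(gene, "_km_high.tsv")))
  writeKMCurve(rep$kmLow, file.path(outDir, paste0(gene, "_km_low.tsv")))
  tabs <- coefTable(rep$coxUnivariate)
  tabs$model <- "unadjusted"
  if (!is.null(rep$coxMultivariate)) {
    adj <- coefTable(rep$coxMultivariate)
    adj$model <- "adjusted"
    tabs <- rbind(tabs, adj)
  }
  utils::write.table(tabs, file.path(outDir, paste0(gene, "_cox.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(outDir, "report", cfg)
  invisible(rep)
}

#' Patient-level H-score analysis from files
#'
#' Reads a per-field IHC count TSV (columns `patient_id`, `field_id`,
#' `n_negative`, `n_low`, `n_positive`, `n_high`), applies [computeHScore()]
#' per field and the highest-field rule per patient, writes
#' `patient_id, h_selected, selected_field`, and, when the clinical table
#' is configured, links the selected H-scores to survival via
#' [hscoreSurvival()].
#'
#' @param cfg validated pipeline config; `paths$ihc` names the count file.
#' @return list with `hscores` (data.frame) and `survival`
#'   ([hscoreSurvival()] output or `NULL`), invisibly.
#' @export
runHscore <- function(cfg) {
  cfg <- validatePipelineConfig(cfg)
  path <- cfg$paths$ihc
  if (is.null(path)) stop("config error: paths$ihc not set", call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", fileEncoding = "UTF-8")
  need <- c("patient_id", "field_id", "n_negative", "n_low", "n_positive",
            "n_high")
  if (!all(need %in% colnames(df))) {
    stop("IHC table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(df, df$patient_id), function(d) {
    h <- apply(d[, c("n_negative", "n_low", "n_positive", "n_high")], 1L,
               computeHScore)
    names(h) <- as.character(d$field_id)
    sel <- selectField(h)
    data.frame(patient_id = d$patient_id[1L], h_selected = hSelected(sel),
               selected_field = selectedField(sel))
  }))
  rownames(out) <- NULL
  outDir <- if (is.null(cfg$paths$outDir)) "." else cfg$paths$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(out, file.path(outDir, "hscores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  surv <- NULL
  if (!is.null(cfg$paths$clinical)) {
    clin <- readClinicalTable(cfg$paths$clinical)
    m <- merge(out, clin, by.x = "patient_id", by.y = "sample")
    surv <- hscoreSurvival(m$h_selected, m$time, m$event,
                           minGroup = cfg$thresholds$minGroup)
  }
  .writeManifest(outDir, "hscore", cfg)
  invisible(list(hscores = out, survival = surv))
}

#' Overrepresentation analysis from files
#'
#' Reads a direction-annotated gene list TSV (columns `gene`,
#' `direction` in +1/-1), a GMT file, and a universe (one gene per line;
#' defaults to the screened genes in `screen.tsv` if present), and writes
#' the [enrichTable()].
#'
#' @param cfg validated pipeline config; `paths$list`, `paths$gmt`,
#'   optional `paths$universe`.
#' @return the enrichment data.frame, invisibly.
#' @export
runEnrich <- function(cfg) {
  cfg <- validatePipelineConfig(cfg)
  if (is.null(cfg$paths$list) || is.null(cfg$paths$gmt)) {
    stop("config error: paths$list and paths$gmt are required",
         call. = FALSE)
  }
  lst <- utils::read.delim(cfg$paths$list, sep = "\t",
                           fileEncoding = "UTF-8")
  if (!all(c("gene", "direction") %in% colnames(lst))) {
    stop("gene list must have columns 'gene' and 'direction'",
         call. = FALSE)
  }
  sets <- readGmt(cfg$paths$gmt)
  outDir <- if (is.null(cfg$paths$outDir)) "." else cfg$paths$outDir
  universe <- if (!is.null(cfg$paths$universe)) {
    readLines(cfg$paths$universe)
  } else {
    screenPath <- file.path(outDir, "screen.tsv")
    if (!file.exists(screenPath)) {
      stop("no universe: set paths$universe or run the screen first",
           call. = FALSE)
    }
    utils::read.delim(screenPath)$gene
  }
  tab <- enrichTable(as.character(lst$gene), as.numeric(lst$direction),
                     sets, universe,
                     zMin = if (is.null(cfg$thresholds$zMin)) 1
                            else cfg$thresholds$zMin,
                     alpha = cfg$thresholds$alpha)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(tab, file.path(outDir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .writeManifest(outDir, "enrich", cfg)
  invisible(tab)
}
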