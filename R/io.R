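## TSV / GMT readers and writers: cBioPortal-style z-score matrices,
## clinical tables, gene sets, KM curve and screen-result exports.

#' Read a gene-by-sample expression matrix
#'
#' Tab-separated, UTF-8, header row required; `''` and `'NA'` (configurable)
#' mark missing values. The `cbioportal_zscore` dialect expects the first
#' column to hold gene symbols and drops an optional `Entrez_Gene_Id`
#' second column; the `plain` dialect is gene-symbol column plus sample
#' columns. Duplicate gene symbols are resolved by keeping the row with the
#' fewest missing values (ties to the first occurrence), with a warning.
#'
#' @param path file path.
#' @param dialect `"cbioportal_zscore"` (default) or `"plain"`.
#' @param naStrings strings treated as missing.
#' @return numeric matrix with gene symbols as rownames, sample IDs as
#'   colnames, in file order.
#' @export
readExpressionMatrix <- function(path,
                                 dialect = c("cbioportal_zscore", "plain"),
                                 naStrings = c("", "NA")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, na.strings = naStrings,
                          colClasses = "character", sep = "\t",
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0L) {
    stop("no data rows in ", path, call. = FALSE)
  }
  symbols <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  if (dialect == "cbioportal_zscore" && ncol(df) > 0L &&
      colnames(df)[1L] %in% c("Entrez_Gene_Id", "entrez_gene_id")) {
    df <- df[, -1L, drop = FALSE]
  }
  if (ncol(df) == 0L) stop("no sample columns in ", path, call. = FALSE)
  mat <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(symbols, colnames(df)))
  for (j in seq_len(ncol(df))) {
    raw <- df[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d (gene '%s'), column '%s'",
                   raw[bad[1L]], bad[1L], symbols[bad[1L]],
                   colnames(df)[j]), call. = FALSE)
    }
    mat[, j] <- num
  }
  if (anyDuplicated(symbols)) {
    dups <- unique(symbols[duplicated(symbols)])
    warning("duplicate gene symbol(s) resolved by fewest missing values: ",
            paste(dups, collapse = ", "), call. = FALSE)
    nMiss <- rowSums(is.na(mat))
    keep <- vapply(unique(symbols), function(s) {
      idx <- which(symbols == s)
      idx[which.min(nMiss[idx])]      # ties -> first occurrence
    }, integer(1))
    mat <- mat[sort(keep), , drop = FALSE]
  }
  mat
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpressionMatrix()] (`plain` dialect): gene-symbol
#' column `gene` followed by one column per sample; full precision.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat),
                   format(mat, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-sample clinical/survival table
#'
#' Tab-separated with required columns `sample`, `time` (months) and
#' `event` (0/1); optional covariates (`age`, `gs`, `t_category`, `ipsa`,
#' `therapy`, ...) are carried through. Rows missing `time` or `event` are
#' dropped with a message reporting the count (patients without survival
#' data are excluded from analysis).
#'
#' @param path file path.
#' @param naStrings strings treated as missing.
#' @return data.frame, one row per retained sample.
#' @export
readClinicalTable <- function(path, naStrings = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, na.strings = naStrings,
                          sep = "\t", fileEncoding = "UTF-8")
  need <- c("sample", "time", "event")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  drop <- is.na(df$time) | is.na(df$event)
  if (any(drop)) {
    message(sum(drop), " sample(s) without survival data excluded")
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no samples with survival data", call. = FALSE)
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample IDs in clinical table", call. = FALSE)
  }
  if (any(df$time < 0)) stop("'time' must be >= 0", call. = FALSE)
  if (!all(df$event %in% c(0, 1))) {
    stop("'event' must be 0 or 1", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write a clinical table as TSV
#' @param clin data.frame with a `sample` column (or rownames as IDs).
#' @param path output path.
#' @export
writeClinicalTable <- function(clin, path) {
  clin <- as.data.frame(clin)
  if (!"sample" %in% colnames(clin)) {
    clin <- cbind(sample = rownames(clin), clin)
  }
  utils::write.table(clin, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member genes.
#' Members are deduplicated within a set. Lines with fewer than three
#' fields (i.e. without at least one member) are a parse error reporting
#' the line number.
#'
#' @param path file path.
#' @return named list of character vectors; names are unique set names.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop("GMT line ", i, ": fewer than 3 fields (need name, ",
           "description, >= 1 member)", call. = FALSE)
    }
    sets[[fields[1L]]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names in ", path, call. = FALSE)
  }
  sets
}

#' Align an expression matrix and a clinical table
#'
#' Restricts both to the intersection of their sample IDs, in the
#' expression matrix's column order, and reports the intersection size.
#' Idempotent.
#'
#' @param expr numeric matrix with sample IDs as colnames.
#' @param clin data.frame with a `sample` column or sample IDs as
#'   rownames.
#' @return list with aligned `expr` and `clin`.
#' @export
alignSamples <- function(expr, clin) {
  clin <- as.data.frame(clin)
  ids <- if ("sample" %in% colnames(clin)) {
    as.character(clin$sample)
  } else {
    rownames(clin)
  }
  shared <- intersect(colnames(expr), ids)
  if (length(shared) == 0L) {
    stop("no shared sample IDs between expression and clinical data",
         call. = FALSE)
  }
  message("aligned on ", length(shared), " shared sample(s)")
  expr <- expr[, shared, drop = FALSE]
  clin <- clin[match(shared, ids), , drop = FALSE]
  if (!"sample" %in% colnames(clin)) {
    clin <- cbind(sample = shared, clin)
  }
  rownames(clin) <- NULL
  list(expr = expr, clin = clin)
}

#' Export a KM curve as TSV
#' @param km a [KMCurve-class].
#' @param path output path.
#' @export
writeKMCurve <- function(km, path) {
  utils::write.table(as.data.frame(km), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a screen result as TSV (one row per analyzed gene)
#' @param screen a [ScreenResult-class].
#' @param path output path.
#' @export
writeScreenResult <- function(screen, path) {
  utils::write.table(as.data.frame(screenTable(screen)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
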