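## Generic overrepresentation analysis + activation z-score: a transparent
## stand-in for proprietary pathway software, filtered at the same
## thresholds (activation z >= 1, p < 0.05).

#' One-sided hypergeometric overrepresentation p-value
#'
#' Probability of observing at least the actual overlap between a gene
#' list and a gene set when the list is drawn without replacement from the
#' universe: the upper tail \eqn{P(X \ge k)} of
#' Hypergeometric(|set|, |universe| - |set|, |list|).
#'
#' @param geneList character vector of query genes (must be a subset of
#'   `universe`).
#' @param geneSet character vector of set members; members outside the
#'   universe are ignored.
#' @param universe character vector of background genes.
#' @return the p-value.
#' @examples
#' fisherOra(letters[1:5], letters[c(1:4, 10)], letters[1:20]) # 76/15504
#' @export
fisherOra <- function(geneList, geneSet, universe) {
  universe <- unique(universe)
  if (length(universe) < 1L) stop("'universe' must be non-empty",
                                  call. = FALSE)
  geneList <- unique(geneList)
  if (!all(geneList %in% universe)) {
    stop("gene list is not a subset of the universe", call. = FALSE)
  }
  geneSet <- unique(intersect(geneSet, universe))
  k <- length(intersect(geneList, geneSet))
  stats::phyper(k - 1, length(geneSet), length(universe) - length(geneSet),
                length(geneList), lower.tail = FALSE)
}

#' Activation z-score of a direction-annotated overlap
#'
#' Direction-consistency score \eqn{z = (n_{up} - n_{down}) / \sqrt{n}}
#' for the genes of a set that overlap the query list, each annotated +1
#' (up) or -1 (down).
#'
#' @param directions vector of +1 / -1 per overlapping gene.
#' @return the z-score.
#' @export
activationZ <- function(directions) {
  if (length(directions) < 1L) {
    stop("'directions' must be non-empty", call. = FALSE)
  }
  if (anyNA(directions) || !all(directions %in% c(-1, 1))) {
    stop("'directions' must contain only +1 and -1", call. = FALSE)
  }
  sum(directions) / sqrt(length(directions))
}

#' Overrepresentation table across gene sets
#'
#' One row per gene set: overlap with the query list, one-sided
#' hypergeometric p-value, activation z-score over the overlap's
#' directions, and a pass flag at the joint thresholds (z >= `zMin` and
#' p < `alpha`). Rows are sorted by p-value.
#'
#' @param geneList character vector of query genes.
#' @param directions +1 / -1 per query gene (same order as `geneList`).
#' @param sets named list of character vectors (e.g. from [readGmt()]).
#' @param universe background genes; a sensible default is every gene the
#'   upstream screen analyzed.
#' @param zMin,alpha pass thresholds (defaults 1 and 0.05).
#' @return data.frame with columns set, setSize, overlap, overlapGenes
#'   (comma-separated), p, activationZ, passes.
#' @export
enrichTable <- function(geneList, directions, sets, universe,
                        zMin = 1, alpha = 0.05) {
  if (length(sets) < 1L || is.null(names(sets)) ||
      anyDuplicated(names(sets))) {
    stop("'sets' must be a non-empty uniquely named list", call. = FALSE)
  }
  if (length(unique(universe)) < 1L) {
    stop("'universe' must be non-empty", call. = FALSE)
  }
  if (length(directions) != length(geneList)) {
    stop("'directions' must match 'geneList'", call. = FALSE)
  }
  names(directions) <- geneList
  rows <- lapply(names(sets), function(nm) {
    members <- unique(intersect(sets[[nm]], universe))
    ov <- intersect(geneList, members)
    z <- if (length(ov)) activationZ(directions[ov]) else NA_real_
    p <- fisherOra(geneList, members, universe)
    data.frame(
      set = nm, setSize = length(members), overlap = length(ov),
      overlapGenes = paste(ov, collapse = ","), p = p, activationZ = z,
      passes = !is.na(z) && z >= zMin && p < alpha
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}
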