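#' @rdname SurvCohort-class
#' @param x a `SurvCohort`.
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @rdname SurvCohort-class
#' @export
setGeneric("survEvent", function(x) standardGeneric("survEvent"))

#' @rdname SurvCohort-class
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname CutpointResult-class
#' @param x a `CutpointResult`.
#' @export
setGeneric("bestCutoff", function(x) standardGeneric("bestCutoff"))

#' @rdname CutpointResult-class
#' @export
setGeneric("hazardRatio", function(x) standardGeneric("hazardRatio"))

#' @rdname ScreenResult-class
#' @param x a `ScreenResult`.
#' @export
setGeneric("screenTable", function(x) standardGeneric("screenTable"))

#' @rdname ScreenResult-class
#' @export
setGeneric("cascadeCounts", function(x) standardGeneric("cascadeCounts"))

#' @rdname ScreenResult-class
#' @export
setGeneric("survivalAssociated", function(x) {
  standardGeneric("survivalAssociated")
})

#' @rdname ScreenResult-class
#' @export
setGeneric("shorterSurvivalGenes", function(x) {
  standardGeneric("shorterSurvivalGenes")
})

#' @rdname ScreenResult-class
#' @export
setGeneric("longerSurvivalGenes", function(x) {
  standardGeneric("longerSurvivalGenes")
})

#' @rdname HScoreResult-class
#' @param x an `HScoreResult`.
#' @export
setGeneric("hSelected", function(x) standardGeneric("hSelected"))

#' @rdname HScoreResult-class
#' @export
setGeneric("selectedField", function(x) standardGeneric("selectedField"))
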