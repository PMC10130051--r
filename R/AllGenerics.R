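#' @import methods
#' @importFrom stats var rnorm setNames
#' @importFrom utils read.csv write.csv combn packageVersion
#' @importFrom tools md5sum
NULL

#' @rdname snValues
#' @export
setGeneric("snValues", function(x, ...) standardGeneric("snValues"))

#' @rdname mainEffects
#' @export
setGeneric("mainEffects", function(x, ...) standardGeneric("mainEffects"))

#' @rdname bestLevels
#' @export
setGeneric("bestLevels", function(x, ...) standardGeneric("bestLevels"))

#' @rdname TaguchiExperiment-class
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname TaguchiExperiment-class
#' @export
setGeneric("factorCatalog", function(x) standardGeneric("factorCatalog"))

#' @rdname TaguchiExperiment-class
#' @export
setGeneric("studySpecies", function(x) standardGeneric("studySpecies"))

#' @rdname interactionSummary
#' @export
setGeneric("interactionSummary", function(x, ...) standardGeneric("interactionSummary"))
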