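#' @include AllClasses.R
NULL

#' @export
setGeneric("smiles", function(x, ...) standardGeneric("smiles"))

#' @export
setGeneric("tokenTable", function(x, ...) standardGeneric("tokenTable"))

#' @export
setGeneric("nTokens", function(x, ...) standardGeneric("nTokens"))

#' @export
setGeneric("nAtoms", function(x, ...) standardGeneric("nAtoms"))

#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @export
setGeneric("scoreMode", function(x, ...) standardGeneric("scoreMode"))

#' @export
setGeneric("atomCoords", function(x, ...) standardGeneric("atomCoords"))

#' @export
setGeneric("atomBonds", function(x, ...) standardGeneric("atomBonds"))

#' @export
setGeneric("atomRings", function(x, ...) standardGeneric("atomRings"))

#' @export
setGeneric("tokenIndices", function(x, ...) standardGeneric("tokenIndices"))

#' @export
setGeneric("atomIndices", function(x, ...) standardGeneric("atomIndices"))

#' @export
setGeneric("highlightKind", function(x, ...) standardGeneric("highlightKind"))

#' @export
setGeneric("recordId", function(x, ...) standardGeneric("recordId"))

#' @export
setGeneric("recordAttributes", function(x, ...) standardGeneric("recordAttributes"))
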