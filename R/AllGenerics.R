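#' @export
setGeneric("boundaryPoints", function(x) standardGeneric("boundaryPoints"))

#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @export
setGeneric("signatureFrame", function(x) standardGeneric("signatureFrame"))

#' @export
setGeneric("nucleusCentroids", function(x) standardGeneric("nucleusCentroids"))

#' @export
setGeneric("nucleusLabels", function(x) standardGeneric("nucleusLabels"))

#' @export
setGeneric("isEpithelial", function(x) standardGeneric("isEpithelial"))

#' @export
setGeneric("lumenMask", function(x) standardGeneric("lumenMask"))

#' @export
setGeneric("expectedAtypiaLobes", function(x) standardGeneric("expectedAtypiaLobes"))
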