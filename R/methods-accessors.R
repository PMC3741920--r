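#' Accessors for ductmorph data classes
#'
#' `boundaryPoints()` returns the n x 2 vertex matrix of a [DuctBoundary];
#' `nPoints()` its vertex count. `signatureFrame()` turns an
#' [AtypiaSignature] into a data.frame with columns `t`, `L`, `A` (pixel
#' units). `nucleusCentroids()`, `nucleusLabels()`, `isEpithelial()` access a
#' [NucleusSet]; `lumenMask()` and `expectedAtypiaLobes()` a [PhantomTruth].
#'
#' @param x the object.
#' @name accessors
#' @aliases boundaryPoints nPoints signatureFrame nucleusCentroids
#'   nucleusLabels isEpithelial lumenMask expectedAtypiaLobes
NULL

#' @rdname accessors
#' @export
setMethod("boundaryPoints", "DuctBoundary", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("nPoints", "DuctBoundary", function(x) nrow(x@points))

#' @rdname accessors
#' @export
setMethod("signatureFrame", "AtypiaSignature", function(x)
  data.frame(t = seq_along(x@L) - 1L, L = x@L, A = x@A))

#' @rdname accessors
#' @export
setMethod("nucleusCentroids", "NucleusSet", function(x) x@centroids)

#' @rdname accessors
#' @export
setMethod("nucleusLabels", "NucleusSet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("isEpithelial", "NucleusSet", function(x) x@epithelial)

#' @rdname accessors
#' @export
setMethod("lumenMask", "PhantomTruth", function(x) x@lumenMask)

#' @rdname accessors
#' @export
setMethod("expectedAtypiaLobes", "PhantomTruth", function(x) x@expectedAtypiaLobes)

setMethod("show", "DuctBoundary", function(object) {
  cat(sprintf("DuctBoundary (%s): %d points, perimeter %.1f px, area %.1f px^2\n",
              object@kind, nrow(object@points),
              polygonPerimeter(object@points), polygonArea(object@points)))
})

setMethod("show", "AtypiaSignature", function(object) {
  cat(sprintf("AtypiaSignature: m = %d, L_max = %.1f px, RMS amplitude %.2f px (%.3f um/px)\n",
              length(object@A), if (length(object@L)) max(object@L) else 0,
              if (length(object@A)) sqrt(mean(object@A^2)) else 0,
              object@resolution))
})

setMethod("show", "NucleusSet", function(object) {
  ne <- sum(object@epithelial %in% TRUE)
  nn <- sum(object@epithelial %in% FALSE)
  cat(sprintf("NucleusSet: %d nuclei (%s)\n", length(object@areas),
              if (all(is.na(object@epithelial))) "unpartitioned"
              else sprintf("%d epithelial, %d non-epithelial", ne, nn)))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %dx%d lumen mask (%d px), %d nuclei, %d expected atypia lobes\n",
              nrow(object@lumenMask), ncol(object@lumenMask),
              sum(object@lumenMask), nrow(object@nuclei),
              object@expectedAtypiaLobes))
})

#' Number of nuclei in a NucleusSet
#' @param x a [NucleusSet].
#' @export
setMethod("length", "NucleusSet", function(x) length(x@areas))
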