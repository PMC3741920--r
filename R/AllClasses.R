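# Raster convention throughout the package: masks and images are matrices (or
# EBImage Images) indexed [x, y], x horizontal, y vertical (y grows downward).
# Point coordinates are 1-based pixel centres (x, y). Closed boundaries are
# stored without repeating the first vertex; orientation is counter-clockwise
# in image coordinates and the start vertex is the topmost-then-leftmost one,
# so identical shapes always yield identical point sequences.

#' Ordered closed duct boundary
#'
#' An ordered, closed, simple polygon of image points describing a lumen
#' boundary: the traced original boundary, its convex hull, or the rescaled
#' ideal boundary. The closing edge (last vertex back to the first) is
#' implicit.
#'
#' @slot points numeric matrix with columns `x`, `y`; at least 3 vertices.
#' @slot kind character; one of `"original"`, `"convex"`, `"ideal"`.
#' @export
setClass("DuctBoundary",
  representation(points = "matrix", kind = "character"),
  prototype(kind = "original"),
  validity = function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 2) return("points must be an n x 2 numeric matrix")
    if (nrow(p) < 3) return("a boundary needs at least 3 points")
    if (any(!is.finite(p))) return("boundary points must be finite")
    if (!object@kind %in% c("original", "convex", "ideal"))
      return("kind must be 'original', 'convex' or 'ideal'")
    TRUE
  })

#' Atypia-amplitude signature
#'
#' The 1-D shape signature of a duct: for every point `p_t` of the ideal
#' lumen boundary, the arc-length position `L(t)` from the start point and
#' the signed orthogonal distance `A(t)` to the original boundary (positive
#' where the original boundary lies outside the ideal one, negative inside).
#' Both are stored in pixel units; `resolution` (micrometres per pixel)
#' converts them to physical units.
#'
#' @slot L numeric; non-decreasing arc length, `L[1] == 0`.
#' @slot A numeric; signed amplitudes, same length as `L`.
#' @slot resolution numeric scalar, micrometres per pixel.
#' @export
setClass("AtypiaSignature",
  representation(L = "numeric", A = "numeric", resolution = "numeric"),
  prototype(resolution = 1),
  validity = function(object) {
    if (length(object@L) != length(object@A))
      return("L and A must have the same length")
    if (length(object@L) > 0) {
      if (abs(object@L[1]) > 1e-9) return("L must start at 0")
      if (any(diff(object@L) < -1e-9)) return("L must be non-decreasing")
    }
    if (length(object@resolution) != 1 || object@resolution <= 0)
      return("resolution must be a positive scalar")
    TRUE
  })

#' Segmented nucleus set
#'
#' Labelled nuclei of a tissue image: an integer label raster (0 =
#' background, 1..n = nuclei), per-nucleus centroids and pixel areas, and an
#' epithelial flag once the epithelial / non-epithelial partition has been
#' computed (`NA` before).
#'
#' @slot labels integer matrix `[x, y]` of nucleus labels.
#' @slot centroids numeric matrix with columns `x`, `y`, one row per nucleus.
#' @slot areas numeric vector of pixel areas.
#' @slot epithelial logical vector (`NA` until [splitEpithelial()] is run).
#' @export
setClass("NucleusSet",
  representation(labels = "matrix", centroids = "matrix",
                 areas = "numeric", epithelial = "logical"),
  validity = function(object) {
    n <- nrow(object@centroids)
    if (length(object@areas) != n) return("areas and centroids disagree")
    if (length(object@epithelial) != n) return("epithelial flags and centroids disagree")
    if (n > 0 && max(object@labels) != n) return("label raster does not match nucleus count")
    TRUE
  })

#' Ground truth of a synthetic duct phantom
#'
#' @slot lumenMask integer matrix `[x, y]`, 1 inside the true lumen.
#' @slot nuclei data.frame with columns `x`, `y`, `is_epithelial`,
#'   `offset_um` (intended centroid-to-lumen distance, `NA` for stromal).
#' @slot expectedAtypiaLobes integer; analytic number of supra-threshold
#'   atypia regions built into the boundary.
#' @slot config list; the generating [phantomConfig()].
#' @export
setClass("PhantomTruth",
  representation(lumenMask = "matrix", nuclei = "data.frame",
                 expectedAtypiaLobes = "integer", config = "list"))

#' Construct a DuctBoundary from an n x 2 point matrix
#' @param points numeric matrix with columns x, y.
#' @param kind boundary kind: "original", "convex" or "ideal".
#' @export
DuctBoundary <- function(points, kind = "original") {
  colnames(points) <- c("x", "y")
  new("DuctBoundary", points = points, kind = kind)
}

#' Construct an AtypiaSignature from arc lengths and amplitudes
#' @param L,A numeric vectors (arc length, signed amplitude), same length.
#' @param resolution micrometres per pixel.
#' @export
AtypiaSignature <- function(L, A, resolution = 1) {
  new("AtypiaSignature", L = as.numeric(L), A = as.numeric(A),
      resolution = resolution)
}

#' Construct a NucleusSet from a label raster and centroids
#' @param labels integer matrix of nucleus labels.
#' @param centroids n x 2 matrix of centroids.
#' @param areas numeric vector of pixel areas.
#' @param epithelial logical epithelial flags (default all NA).
#' @export
NucleusSet <- function(labels, centroids, areas,
                       epithelial = rep(NA, length(areas))) {
  if (!is.matrix(centroids)) centroids <- matrix(centroids, ncol = 2)
  colnames(centroids) <- c("x", "y")
  new("NucleusSet", labels = labels, centroids = centroids,
      areas = as.numeric(areas), epithelial = as.logical(epithelial))
}
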