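# Polygon and raster geometry shared by the segmentation and atypia modules.
# Polygons are n x 2 (x, y) matrices, closed implicitly.

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param poly n x 2 matrix of vertices, closed implicitly.
#' @param signed if `TRUE` return the signed area (positive for
#'   counter-clockwise orientation in image coordinates, y down).
#' @return area in squared vertex units.
#' @export
polygonArea <- function(poly, signed = FALSE) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly); j <- c(2:n, 1)
  a <- sum(x * y[j] - x[j] * y) / 2
  if (signed) a else abs(a)
}

#' Polygon perimeter
#' @param poly n x 2 vertex matrix, closed implicitly.
#' @export
polygonPerimeter <- function(poly) {
  d <- diff(rbind(poly, poly[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# area-weighted centroid of a simple polygon
polygonCentroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly); j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Rasterize a polygon into a binary [x, y] matrix by even-odd scanline fill.
# A pixel is set when its centre lies inside the polygon.
polygonToMask <- function(poly, width, height) {
  mask <- matrix(0L, width, height)
  x <- poly[, 1]; y <- poly[, 2]; n <- length(x)
  j <- c(n, seq_len(n - 1))
  for (yr in seq_len(height)) {
    cross <- which((y > yr) != (y[j] > yr))
    if (!length(cross)) next
    xs <- sort(x[cross] + (yr - y[cross]) / (y[j][cross] - y[cross]) *
                 (x[j][cross] - x[cross]))
    for (i in seq(1, length(xs) - 1, by = 2)) {
      c1 <- ceiling(xs[i]); c2 <- floor(xs[i + 1])
      if (c2 >= c1 && c2 >= 1 && c1 <= width)
        mask[max(1, c1):min(width, c2), yr] <- 1L
    }
  }
  mask
}

# Normalize a closed boundary: counter-clockwise orientation (positive signed
# area in image coordinates) and start at the topmost-then-leftmost vertex.
normalizeBoundary <- function(pts) {
  if (polygonArea(pts, signed = TRUE) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  start <- which(pts[, 2] == min(pts[, 2]))
  start <- start[which.min(pts[start, 1])]
  if (start > 1) pts <- pts[c(start:nrow(pts), 1:(start - 1)), , drop = FALSE]
  pts
}

#' Trace the outer boundary of the largest object in a binary mask
#'
#' Contour tracing of the largest 4-connected foreground component,
#' normalized to counter-clockwise order with the topmost-then-leftmost
#' pixel first. Consecutive points are at most sqrt(2) px apart.
#'
#' @param mask binary `[x, y]` matrix or EBImage `Image`.
#' @return a [DuctBoundary] of kind `"original"`.
#' @export
traceBoundary <- function(mask) {
  m <- asMaskMatrix(mask)
  lab <- EBImage::bwlabel(EBImage::Image(m))
  if (max(lab) == 0) stop("cannot trace boundary of an empty mask")
  if (max(lab) > 1) {
    counts <- tabulate(as.integer(lab[lab > 0]))
    m <- matrix(as.integer(imageData(lab) == which.max(counts)), nrow(m), ncol(m))
  }
  oc <- EBImage::ocontour(EBImage::Image(m))[[1]] + 1  # ocontour is 0-based
  if (nrow(oc) < 3) stop("boundary degenerate: fewer than 3 contour points")
  DuctBoundary(normalizeBoundary(oc), kind = "original")
}

# Resample a closed polygon to (approximately) uniform arc-length spacing.
# Returns ceiling(perimeter / spacing) points, spacing <= requested.
resampleClosed <- function(poly, spacing = 1) {
  p <- rbind(poly, poly[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(seg))
  per <- cum[length(cum)]
  m <- max(8L, as.integer(ceiling(per / spacing)))
  s <- seq(0, per, length.out = m + 1)[1:m]
  xi <- stats::approx(cum, p[, 1], xout = s, ties = "ordered")$y
  yi <- stats::approx(cum, p[, 2], xout = s, ties = "ordered")$y
  cbind(x = xi, y = yi)
}

# Circular moving average of a closed polygon's vertices (window w, odd).
smoothClosed <- function(poly, w = 5) {
  n <- nrow(poly)
  if (n <= w) return(poly)
  half <- (w - 1) %/% 2
  idx <- outer(seq_len(n), -half:half, "+")
  idx <- ((idx - 1) %% n) + 1
  cbind(rowMeans(matrix(poly[idx, 1], n)), rowMeans(matrix(poly[idx, 2], n)))
}

# Even-odd point-in-polygon (mgcv's compiled routine).
pointsInPolygon <- function(pts, poly) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), pts)
}

# Minimum distance from points to a closed polyline; returns per-point
# distances. pts m x 2, poly n x 2.
distToPolygon <- function(pts, poly) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  a <- poly
  b <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), 1e-12)
  vapply(seq_len(nrow(pts)), function(i) {
    ap <- cbind(pts[i, 1] - a[, 1], pts[i, 2] - a[, 2])
    t <- pmin(pmax((ap[, 1] * ab[, 1] + ap[, 2] * ab[, 2]) / len2, 0), 1)
    dx <- ap[, 1] - t * ab[, 1]; dy <- ap[, 2] - t * ab[, 2]
    sqrt(min(dx * dx + dy * dy))
  }, numeric(1))
}

# Nearest point on a closed polyline to p: distance and foot coordinates.
closestOnPolygon <- function(p, poly) {
  a <- poly
  b <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), 1e-12)
  apx <- p[1] - a[, 1]; apy <- p[2] - a[, 2]
  t <- pmin(pmax((apx * ab[, 1] + apy * ab[, 2]) / len2, 0), 1)
  fx <- a[, 1] + t * ab[, 1]; fy <- a[, 2] + t * ab[, 2]
  d2 <- (p[1] - fx)^2 + (p[2] - fy)^2
  i <- which.min(d2)
  list(dist = sqrt(d2[i]), foot = c(fx[i], fy[i]))
}

# Intersect the line p + t*d (t in R, both directions) with the edges of a
# closed polygon; returns the signed t of the intersection nearest to p, or
# NA when the line misses every edge.
linePolygonNearestT <- function(p, d, poly) {
  a <- poly
  b <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  # Solve p + t d = a + u (b - a) for each edge:
  #   det = e_x d_y - e_y d_x;  t = (e_x w_y - e_y w_x)/det;
  #   u = (d_x w_y - d_y w_x)/det;  w = a - p
  det <- ex * d[2] - ey * d[1]
  ok <- abs(det) > 1e-12
  if (!any(ok)) return(NA_real_)
  wx <- a[, 1] - p[1]; wy <- a[, 2] - p[2]
  t <- (ex * wy - ey * wx) / det
  u <- (d[1] * wy - d[2] * wx) / det
  hit <- ok & u >= 0 & u < 1
  if (!any(hit)) return(NA_real_)
  th <- t[hit]
  th[which.min(abs(th))]
}

asMaskMatrix <- function(mask) {
  if (is(mask, "Image")) mask <- imageData(mask)
  if (length(dim(mask)) > 2) mask <- mask[, , 1]
  matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
}

# luminance (Rec. 601) of an [x, y, 3] array or color Image, values in [0, 1]
luminanceOf <- function(image) {
  d <- if (is(image, "Image")) imageData(image) else image
  if (length(dim(d)) == 2) return(d)
  0.299 * d[, , 1] + 0.587 * d[, , 2] + 0.114 * d[, , 3]
}

# run under a fixed seed without disturbing the caller's RNG
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
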