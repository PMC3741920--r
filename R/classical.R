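# The twelve classical morphometric features, computed for any region
# (lumen or nucleus) from its binary mask, in physical units.

classicalFeatureNames <- c("Area", "Perimeter", "Width", "Height",
                           "MajorAxis", "MinorAxis", "Circularity",
                           "FeretDiameter", "AspectRatio", "Skewness",
                           "Roundness", "Solidity")

#' Classical morphometric features of a region
#'
#' Computes, for one region given as a binary mask: Area (pixel count x
#' resolution^2), Perimeter (traced contour polygon length), Width/Height
#' (axis-aligned bounding box), Major/MinorAxis (best-fit ellipse from the
#' second central moments), Circularity `4*pi*A/P^2`, Feret diameter
#' (largest pairwise distance between boundary points), AspectRatio
#' (Major/Minor), Skewness (third standardized moment of the pixel
#' intensities inside the region; 0 without an intensity image), Roundness
#' `4*A/(pi*Major^2)` and Solidity (area over filled convex hull area).
#'
#' @param mask binary `[x, y]` matrix (or EBImage Image); one region.
#' @param intensity optional grayscale matrix of the same shape (luminance)
#'   for the Skewness feature.
#' @param resolution micrometres per pixel.
#' @return named numeric vector with the 12 features; lengths in um, areas
#'   in um^2, ratios unitless.
#' @export
regionFeatures <- function(mask, intensity = NULL, resolution = 0.492) {
  m <- asMaskMatrix(mask)
  idx <- which(m > 0)
  if (length(idx) < 3) stop("region has fewer than 3 pixels; ellipse undefined")
  nx <- nrow(m)
  xs <- ((idx - 1) %% nx) + 1
  ys <- ((idx - 1) %/% nx) + 1
  A_px <- length(idx)
  area <- A_px * resolution^2
  bnd <- boundaryPoints(traceBoundary(m))
  # the raw 4-connected trace is a staircase whose length overestimates a
  # smooth perimeter by up to 4/pi; a short circular moving average removes
  # the staircase before measuring length
  per <- polygonPerimeter(smoothClosed(bnd, 5)) * resolution
  wid <- (diff(range(xs)) + 1) * resolution
  hei <- (diff(range(ys)) + 1) * resolution
  # second central moments with the 1/12 pixel-variance term, as for a
  # square pixel footprint; axes = 4 sqrt(eigenvalue), the standard
  # image-moments best-fit ellipse
  mu_xx <- stats::var(xs) * (A_px - 1) / A_px + 1 / 12
  mu_yy <- stats::var(ys) * (A_px - 1) / A_px + 1 / 12
  mu_xy <- stats::cov(xs, ys) * (A_px - 1) / A_px
  tr <- mu_xx + mu_yy
  dt <- sqrt(pmax((mu_xx - mu_yy)^2 + 4 * mu_xy^2, 0))
  l1 <- (tr + dt) / 2; l2 <- pmax((tr - dt) / 2, 1e-12)
  major <- 4 * sqrt(l1) * resolution
  minor <- 4 * sqrt(l2) * resolution
  # Feret over pixel corners so that a w x h rectangle measures its full
  # diagonal rather than the centre-to-centre one
  corners <- rbind(cbind(bnd[, 1] - 0.5, bnd[, 2] - 0.5),
                   cbind(bnd[, 1] + 0.5, bnd[, 2] - 0.5),
                   cbind(bnd[, 1] - 0.5, bnd[, 2] + 0.5),
                   cbind(bnd[, 1] + 0.5, bnd[, 2] + 0.5))
  cornhull <- corners[grDevices::chull(corners), , drop = FALSE]
  feret <- maxPairwiseDistance(cornhull) * resolution
  hull <- bnd[grDevices::chull(bnd), , drop = FALSE]
  hullmask <- polygonToMask(hull, nrow(m), ncol(m))
  convex_px <- sum(hullmask | m)  # hull of pixel centres, padded by the region
  skew <- 0
  if (!is.null(intensity)) {
    v <- as.numeric(intensity)[idx]
    sdv <- sqrt(mean((v - mean(v))^2))
    if (sdv > 1e-12) skew <- mean((v - mean(v))^3) / sdv^3
  }
  c(Area = area, Perimeter = per, Width = wid, Height = hei,
    MajorAxis = major, MinorAxis = minor,
    Circularity = 4 * pi * area / per^2,
    FeretDiameter = feret,
    AspectRatio = major / minor,
    Skewness = skew,
    Roundness = 4 * area / (pi * major^2),
    Solidity = A_px / convex_px)
}

# exact max pairwise distance; callers pass convex hull vertices so the
# quadratic loop stays tiny
maxPairwiseDistance <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2))
}
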