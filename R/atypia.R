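# Duct-atypia features: ideal lumen boundary, atypia-amplitude signature,
# RMSAA, PIP detection, TSAV, atypia regions and cytoplasm lengths.

#' Ideal lumen boundary
#'
#' The atypia-free reference shape of a duct: the convex hull of the
#' original lumen boundary, rescaled about the hull centroid by
#' `s = sqrt(Area(R^O) / Area(R^C))` so that the enclosed area equals the
#' original lumen area, then resampled to uniform arc-length spacing.
#'
#' @param boundary a [DuctBoundary] (original lumen boundary, `B^O`).
#' @param spacing resample spacing of the ideal boundary, px.
#' @return list with `convex` and `ideal` ([DuctBoundary] objects) and the
#'   scaling factor `s`.
#' @export
idealBoundary <- function(boundary, spacing = 1) {
  bp <- boundaryPoints(boundary)
  h <- grDevices::chull(bp)
  hull <- bp[h, , drop = FALSE]
  if (nrow(hull) < 3 || polygonArea(hull) < 1e-9)
    stop("degenerate boundary: convex hull has no area")
  hull <- normalizeBoundary(hull)
  aO <- polygonArea(bp)
  aC <- polygonArea(hull)
  s <- sqrt(aO / aC)
  ctr <- polygonCentroid(hull)
  ideal <- sweep(sweep(hull, 2, ctr), 1, rep(s, nrow(hull)), "*")
  ideal <- sweep(ideal, 2, ctr, "+")
  ideal <- normalizeBoundary(resampleClosed(ideal, spacing))
  list(convex = DuctBoundary(hull, kind = "convex"),
       ideal = DuctBoundary(ideal, kind = "ideal"),
       s = s)
}

#' Atypia-amplitude signature of a duct
#'
#' For every point `p_t` of the ideal boundary, casts the line through
#' `p_t` along the local outward normal (tangent by central differences)
#' and takes the nearest intersection `q` with the original boundary
#' polygon. `A(t)` is the distance `|p_t q|`, signed positive when `q` lies
#' outside the region enclosed by the ideal boundary and negative inside;
#' `L(t)` is the arc length from the start point. If the normal line misses
#' the polygon entirely, the nearest original-boundary point is used with a
#' point-in-region sign.
#'
#' @param ideal,original [DuctBoundary] objects (`B^I` resampled uniformly,
#'   and `B^O`).
#' @param resolution micrometres per pixel, recorded in the signature.
#' @return an [AtypiaSignature]; `L` and `A` are in pixels.
#' @export
atypiaSignature <- function(ideal, original, resolution = 1) {
  pI <- boundaryPoints(ideal)
  pO <- boundaryPoints(original)
  m <- nrow(pI)
  if (m < 3 || nrow(pO) < 3) stop("both boundaries must have at least 3 points")
  # limit intersection work on very dense original boundaries
  pOi <- if (nrow(pO) > 4000) resampleClosed(pO, polygonPerimeter(pO) / 4000) else pO
  nxt <- c(2:m, 1); prv <- c(m, 1:(m - 1))
  tang <- pI[nxt, , drop = FALSE] - pI[prv, , drop = FALSE]
  tlen <- pmax(sqrt(rowSums(tang^2)), 1e-12)
  # candidate normal: tangent rotated by  -90 deg; orient outward globally
  nrm <- cbind(tang[, 2], -tang[, 1]) / tlen
  ctr <- polygonCentroid(pI)
  outwardness <- rowSums(nrm * sweep(pI, 2, ctr))
  if (mean(outwardness > 0) < 0.5) nrm <- -nrm
  A <- numeric(m)
  need_fallback <- logical(m)
  for (t in seq_len(m)) {
    tt <- linePolygonNearestT(pI[t, ], nrm[t, ], pOi)
    if (is.na(tt)) { need_fallback[t] <- TRUE; next }
    q <- pI[t, ] + tt * nrm[t, ]
    sgn <- if (pointsInPolygon(matrix(q, 1, 2), pI)) -1 else 1
    A[t] <- sgn * abs(tt)
  }
  if (any(need_fallback)) {
    for (t in which(need_fallback)) {
      cp <- closestOnPolygon(pI[t, ], pOi)
      sgn <- if (pointsInPolygon(matrix(cp$foot, 1, 2), pI)) -1 else 1
      A[t] <- sgn * cp$dist
    }
  }
  seg <- sqrt(rowSums((pI[nxt, , drop = FALSE] - pI)^2))
  L <- c(0, cumsum(seg[-m]))
  AtypiaSignature(L, A, resolution = resolution)
}

#' Root-mean-squared atypia amplitude
#'
#' `RMSAA = sqrt(mean(A(t)^2))` over the signature, in signature (pixel)
#' units; multiply by the resolution for micrometres.
#'
#' @param sig an [AtypiaSignature].
#' @export
rmsaa <- function(sig) {
  if (length(sig@A) == 0) stop("empty signature")
  sqrt(mean(sig@A^2))
}

#' Perceptually important points of an atypia signature
#'
#' Recursive bisection in the `(L, A)` plane: between the current PIP pair,
#' the point with the maximum vertical distance (VD) from the chord is added
#' as a PIP when that distance exceeds `T`, and both sub-intervals are
#' processed in turn; this finds every critical point with significance
#' above `T` rather than a fixed number of PIPs. A post-processing pass
#' prunes interior PIPs whose turning angle is below `theta_min`
#' (near-collinear), iterating until all remaining interior angles pass.
#'
#' @param sig an [AtypiaSignature] with at least 2 points.
#' @param T vertical-distance threshold in signature units; `>= 0`.
#' @param theta_min pruning angle in radians (default 5 degrees).
#' @return integer vector of PIP indices into the signature (1-based,
#'   always including the first and last point).
#' @export
detectPips <- function(sig, T = 1, theta_min = 5 * pi / 180) {
  if (T < 0) stop("T must be non-negative")
  L <- sig@L; A <- sig@A
  m <- length(L)
  if (m < 2) stop("signature must have at least 2 points")
  pips <- c(1L, m)
  stack <- list(c(1L, m))
  while (length(stack)) {
    se <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    s <- se[1]; e <- se[2]
    if (e - s < 2) next
    idx <- (s + 1):(e - 1)
    # vertical distance from the chord (s, e)
    chordA <- A[s] + (L[idx] - L[s]) / max(L[e] - L[s], 1e-12) * (A[e] - A[s])
    vd <- abs(A[idx] - chordA)
    k <- idx[which.max(vd)]
    if (max(vd) > T) {
      pips <- c(pips, k)
      stack[[length(stack) + 1]] <- c(s, k)
      stack[[length(stack) + 1]] <- c(k, e)
    }
  }
  pips <- sort(unique(pips))
  prunePips(L, A, pips, theta_min)
}

# iteratively drop the interior PIP with the smallest turning angle while
# any angle is below theta_min
prunePips <- function(L, A, pips, theta_min) {
  repeat {
    if (length(pips) <= 2) break
    P <- cbind(L[pips], A[pips])
    k <- length(pips)
    a <- P[2:(k - 1), , drop = FALSE] - P[1:(k - 2), , drop = FALSE]
    b <- P[3:k, , drop = FALSE] - P[2:(k - 1), , drop = FALSE]
    na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
    cosv <- rowSums(a * b) / pmax(na * nb, 1e-12)
    ang <- acos(pmin(pmax(cosv, -1), 1))
    if (all(ang >= theta_min)) break
    pips <- pips[-(which.min(ang) + 1)]
  }
  pips
}

#' Total sum of atypia volatilities at PIPs
#'
#' Sums, over the interior PIPs, the angle between the incoming and
#' outgoing chord vectors in the `(L, A)` plane:
#' `TSAV = sum arccos(a_i . b_i / (|a_i| |b_i|))`.
#'
#' @param sig an [AtypiaSignature].
#' @param pips integer PIP indices from [detectPips()]; at least 2.
#' @return TSAV in radians (0 when there are no interior PIPs).
#' @export
tsav <- function(sig, pips) {
  if (length(pips) < 2) stop("need at least 2 PIPs")
  if (length(pips) == 2) return(0)
  P <- cbind(sig@L[pips], sig@A[pips])
  k <- nrow(P)
  a <- P[2:(k - 1), , drop = FALSE] - P[1:(k - 2), , drop = FALSE]
  b <- P[3:k, , drop = FALSE] - P[2:(k - 1), , drop = FALSE]
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na < 1e-12) || any(nb < 1e-12)) stop("duplicate PIPs give zero-length vectors")
  cosv <- pmin(pmax(rowSums(a * b) / (na * nb), -1), 1)
  sum(acos(cosv))
}

#' Atypia regions between the original and ideal lumen regions
#'
#' The symmetric difference of `R^O` and `R^I` is separated by the ideal
#' boundary into protrusions (`R^O` outside `R^I`) and intrusions (`R^I`
#' outside `R^O`); each side is labelled into 4-connected components.
#' `AtypiaRatio` is the total atypia area over the original lumen area
#' (all components); `NumAtypiaRegions` counts the components whose area
#' exceeds `threshold_um2`.
#'
#' @param maskO,maskI binary `[x, y]` masks of `R^O` and `R^I` (same shape).
#' @param threshold_um2 area threshold for counting, in square micrometres.
#' @param resolution micrometres per pixel.
#' @return list with `regions` (data.frame: `area_px`, `area_um2`, `side`),
#'   `atypiaRatio` and `numAtypiaRegions`.
#' @export
atypiaRegions <- function(maskO, maskI, threshold_um2 = 300, resolution = 0.492) {
  stopifnot(threshold_um2 >= 0)
  O <- asMaskMatrix(maskO); I <- asMaskMatrix(maskI)
  stopifnot(identical(dim(O), dim(I)))
  areaO <- sum(O)
  if (areaO == 0) stop("original lumen region has zero area")
  sides <- list(outside = O & !I, inside = I & !O)
  regs <- do.call(rbind, lapply(names(sides), function(sd) {
    lab <- EBImage::bwlabel(EBImage::Image(matrix(as.integer(sides[[sd]]), nrow(O), ncol(O))))
    if (max(lab) == 0) return(NULL)
    a <- tabulate(as.integer(imageData(lab)[imageData(lab) > 0]))
    data.frame(area_px = a, area_um2 = a * resolution^2, side = sd)
  }))
  if (is.null(regs))
    regs <- data.frame(area_px = numeric(0), area_um2 = numeric(0), side = character(0))
  list(regions = regs,
       atypiaRatio = sum(regs$area_px) / areaO,
       numAtypiaRegions = sum(regs$area_um2 > threshold_um2))
}

#' Cytoplasm length of the epithelial nuclei
#'
#' The orthogonal distance from each epithelial nucleus centroid to the
#' original lumen boundary polyline (the minimizing segment meets the
#' boundary perpendicularly at its foot). Returns per-nucleus lengths with
#' their mean and population standard deviation (divisor `m`), which
#' quantifies loss of nuclear polarity.
#'
#' @param nuclei a [NucleusSet] with epithelial flags, or a numeric matrix
#'   of epithelial centroids.
#' @param boundary a [DuctBoundary] (`B^O`).
#' @param resolution micrometres per pixel.
#' @return list with `lengths_um`, `mean_um`, `sd_um`.
#' @export
cytoplasmFeatures <- function(nuclei, boundary, resolution = 0.492) {
  cen <- if (is.matrix(nuclei)) nuclei
         else nucleusCentroids(nuclei)[isEpithelial(nuclei) %in% TRUE, , drop = FALSE]
  if (nrow(cen) == 0) {
    warning("no epithelial nuclei: cytoplasm features set to 0")
    return(list(lengths_um = numeric(0), mean_um = 0, sd_um = 0))
  }
  d <- distToPolygon(cen, boundaryPoints(boundary)) * resolution
  list(lengths_um = d, mean_um = mean(d),
       sd_um = sqrt(mean((d - mean(d))^2)))
}
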