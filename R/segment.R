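# Lumen and nuclei segmentation for single-duct H&E images.

#' Kapur maximum-entropy threshold of a grayscale image
#'
#' Exhaustive search over the 256-bin histogram for the threshold that
#' maximizes the sum of foreground and background Shannon entropies.
#'
#' @param gray numeric matrix/vector with values in `[0, 1]`.
#' @return threshold on the `[0, 1]` scale; `NA` for a constant input.
#' @export
kapurThreshold <- function(gray) {
  v <- as.numeric(gray)
  v <- v[is.finite(v)]
  bins <- pmin(pmax(floor(v * 256), 0), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  p <- h / sum(h)
  if (sum(p > 0) < 2) return(NA_real_)
  P <- cumsum(p)
  # entropy accumulators; empty classes contribute -Inf and are skipped
  plogp <- ifelse(p > 0, p * log(p), 0)
  cumPlogp <- cumsum(plogp)
  best <- -Inf; bestT <- NA_real_
  for (t in 1:255) {
    w0 <- P[t]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    h0 <- log(w0) - cumPlogp[t] / w0
    h1 <- log(w1) - (cumPlogp[256] - cumPlogp[t]) / w1
    if (h0 + h1 > best) { best <- h0 + h1; bestT <- t }
  }
  bestT / 256
}

#' Binarize a tissue image for lumen detection
#'
#' Median filtering, illumination correction (morphological rolling-ball
#' background subtraction on the luminance channel), then Kapur
#' maximum-entropy thresholding. Bright, lumen-like pixels become
#' foreground.
#'
#' @param image RGB array/Image (values in `[0, 1]`) or grayscale matrix.
#' @param median_radius median filter radius in px.
#' @param background_radius rolling-ball (disc opening) radius in px; `0`
#'   (the default) skips illumination correction, which is only meaningful
#'   when the ball is larger than every structure of interest - rarely true
#'   for a single-duct crop.
#' @return list with `mask` (binary `[x, y]` matrix), `threshold`, and the
#'   preprocessed `gray` image used for thresholding and region growing.
#' @export
preprocessBinarize <- function(image, median_radius = 2, background_radius = 0) {
  gray <- luminanceOf(image)
  if (median_radius > 0)
    gray <- imageData(EBImage::medianFilter(EBImage::Image(gray), median_radius))
  if (background_radius > 0) {
    # background = gray opened with a disc; dividing out flattens shading
    brush <- EBImage::makeBrush(2 * background_radius + 1, shape = "disc")
    bg <- imageData(EBImage::opening(EBImage::Image(gray), brush))
    floorv <- stats::quantile(bg, 0.05)
    gray <- gray - pmax(bg - floorv, 0)
    gray <- pmin(pmax(gray, 0), 1)
  }
  thr <- kapurThreshold(gray)
  if (is.na(thr)) {
    warning("constant image: maximum-entropy threshold undefined, returning empty mask")
    return(list(mask = matrix(0L, nrow(gray), ncol(gray)), threshold = NA_real_,
                gray = gray))
  }
  list(mask = matrix(as.integer(gray > thr), nrow(gray), ncol(gray)),
       threshold = thr, gray = gray)
}

#' Direction cumulative map of a binary mask
#'
#' For every white pixel, the sum over the four axis directions of the
#' square root of the run length of contiguous white pixels strictly in that
#' direction (the pixel itself excluded, stopping at the first black pixel
#' or the border). Black pixels score 0, as do isolated white pixels, which
#' suppresses narrow structures while peaking near the centre of wide ones.
#'
#' @param mask binary `[x, y]` matrix.
#' @return numeric matrix of the same shape.
#' @export
directionCumulativeMap <- function(mask) {
  A <- asMaskMatrix(mask)
  nx <- nrow(A); ny <- ncol(A)
  run <- function(M) { # run length strictly before each x, scanning x upward
    L <- matrix(0, nrow(M), ncol(M))
    if (nrow(M) > 1) for (i in 2:nrow(M))
      L[i, ] <- M[i - 1, ] * (L[i - 1, ] + 1)
    L
  }
  Lx <- run(A)
  Rx <- run(A[nx:1, , drop = FALSE])[nx:1, , drop = FALSE]
  Uy <- t(run(t(A)))
  Dy <- t(run(t(A)[ny:1, , drop = FALSE]))[, ny:1, drop = FALSE]
  (sqrt(Lx) + sqrt(Rx) + sqrt(Uy) + sqrt(Dy)) * A
}

#' Seed points from a direction cumulative map
#'
#' Thresholds the map with Otsu's method computed on its nonzero values,
#' then returns the local maxima of the thresholded map; a connected
#' plateau yields a single seed at its centroid (rounded to the nearest
#' pixel).
#'
#' @param H direction cumulative map from [directionCumulativeMap()].
#' @return integer matrix with columns `x`, `y` (possibly 0 rows).
#' @export
detectSeedPoints <- function(H) {
  nz <- H[H > 0]
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  if (!length(nz)) return(empty)
  rng <- range(nz)
  if (diff(rng) < 1e-12) {
    HT <- H
  } else {
    sc <- (nz - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(matrix(sc, ncol = 1)), range = c(0, 1))
    HT <- H * (H >= rng[1] + thr * diff(rng))
  }
  if (!any(HT > 0)) return(empty)
  # local maxima incl. plateaus: pixel equals the max of its 3x3 neighbourhood
  nx <- nrow(HT); ny <- ncol(HT)
  pad <- matrix(-Inf, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- HT
  nbmax <- matrix(-Inf, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nbmax <- pmax(nbmax, pad[(2 + dx):(nx + 1 + dx), (2 + dy):(ny + 1 + dy)])
  }
  peaks <- (HT > 0) & (HT >= nbmax)
  if (!any(peaks)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(matrix(as.integer(peaks), nx, ny)))
  labv <- as.integer(imageData(lab))
  idx <- which(labv > 0)
  xs <- ((idx - 1) %% nx) + 1
  ys <- ((idx - 1) %/% nx) + 1
  cx <- round(tapply(xs, labv[idx], mean))
  cy <- round(tapply(ys, labv[idx], mean))
  cbind(x = as.integer(cx), y = as.integer(cy))
}

# Seeded region growing with a region-mean homogeneity criterion: pixels
# join while |I - mean(region)| <= tol; regions sharing a boundary merge
# (they are grown as connected components of the homogeneity mask, so the
# result is independent of seed order).
srgGrow <- function(gray, seeds, tol = 0.15, max_iter = 12) {
  nx <- nrow(gray); ny <- ncol(gray)
  sidx <- (seeds[, 2] - 1) * nx + seeds[, 1]
  region <- matrix(FALSE, nx, ny)
  region[sidx] <- TRUE
  for (i in seq_len(max_iter)) {
    mu <- mean(gray[region])
    M <- abs(gray - mu) <= tol
    M[sidx] <- TRUE
    lab <- EBImage::bwlabel(EBImage::Image(matrix(as.integer(M), nx, ny)))
    labm <- imageData(lab)
    keep <- unique(labm[sidx])
    keep <- keep[keep > 0]
    newregion <- matrix(labm %in% keep, nx, ny)
    if (identical(newregion, region)) break
    region <- newregion
  }
  region
}

#' Segment the duct lumen by seeded region growing
#'
#' Grows from all seed points on the preprocessed intensity image with a
#' region-mean similarity criterion; touching regions merge, and the largest
#' resulting region is taken as the lumen. Its traced outer boundary is
#' returned.
#'
#' @param image RGB image, or the `gray` component of [preprocessBinarize()].
#' @param seeds integer matrix of seed points (columns `x`, `y`).
#' @param tol homogeneity tolerance on the `[0, 1]` intensity scale.
#' @param median_radius,background_radius preprocessing parameters, used when
#'   `image` is an unpreprocessed RGB image.
#' @return list with `boundary` (a [DuctBoundary]), `mask` (binary matrix)
#'   and `leaked` (TRUE when the region touches more than half of the image
#'   border, indicating a background leak).
#' @export
segmentLumen <- function(image, seeds, tol = 0.15, median_radius = 2,
                         background_radius = 0) {
  if (is.null(seeds) || nrow(seeds) == 0) stop("segmentLumen requires at least one seed")
  gray <- if (is.matrix(image) && length(dim(image)) == 2) image
          else preprocessBinarize(image, median_radius, background_radius)$gray
  nx <- nrow(gray); ny <- ncol(gray)
  # seeds of very different intensity cannot share a region mean: grow each
  # intensity-coherent seed cluster separately, then let the grown regions
  # merge wherever they meet
  sval <- gray[cbind(seeds[, 1], seeds[, 2])]
  o <- order(sval)
  cl <- cumsum(c(1, diff(sval[o]) > tol / 2))
  # candidate regions: per cluster, the connected components of its grown
  # mask (components within one cluster have merged already inside srgGrow)
  cands <- list()
  for (g in unique(cl)) {
    reg <- srgGrow(gray, seeds[o[cl == g], , drop = FALSE], tol = tol)
    lab <- EBImage::bwlabel(EBImage::Image(matrix(as.integer(reg), nx, ny)))
    labm <- imageData(lab)
    for (i in seq_len(max(lab))) cands[[length(cands) + 1]] <- labm == i
  }
  areas <- vapply(cands, sum, numeric(1))
  # background regions hug the image border; a cropped duct does not
  bfrac <- vapply(cands, function(m)
    mean(c(m[1, ], m[nx, ], m[, 1], m[, ny])), numeric(1))
  interior <- which(bfrac < 0.2)
  leaked <- FALSE
  if (length(interior)) {
    pick <- interior[which.max(areas[interior])]
  } else {
    pick <- which.max(areas)
    leaked <- TRUE
    warning("grown region touches most of the image border; likely background leak")
  }
  mask <- matrix(as.integer(cands[[pick]]), nx, ny)
  list(boundary = traceBoundary(mask), mask = mask, leaked = leaked)
}

# deterministic k-means colour clustering. Centres are initialized at the
# extremes and evenly spaced quantiles of the luminance distribution (not
# its mass terciles): tissue classes differ in brightness but not in mass,
# and anchoring one centre on the darkest pixels keeps the sparse nuclear
# class from being absorbed into the stroma.
kmeansColor <- function(rgb_px, k = 3, max_px = 50000) {
  lum <- rgb_px %*% c(0.299, 0.587, 0.114)
  n <- nrow(rgb_px)
  sub <- if (n > max_px) seq(1, n, length.out = max_px) else seq_len(n)
  qs <- stats::quantile(lum[sub], probs = seq(0, 1, length.out = k))
  centers <- t(vapply(seq_len(k), function(i) {
    band <- abs(lum[sub] - qs[i])
    colMeans(rgb_px[sub[order(band)[seq_len(max(10, length(sub) %/% 50))]], , drop = FALSE])
  }, numeric(3)))
  centers <- unique(round(centers, 6))
  k_eff <- nrow(centers)
  if (k_eff > 1) {
    km <- suppressWarnings(stats::kmeans(rgb_px[sub, , drop = FALSE],
                                         centers = centers, iter.max = 50,
                                         algorithm = "Lloyd"))
    centers <- km$centers[stats::complete.cases(km$centers), , drop = FALSE]
  }
  # assign every pixel to the nearest fitted centre
  d2 <- vapply(seq_len(nrow(centers)), function(i)
    rowSums(sweep(rgb_px, 2, centers[i, ])^2), numeric(n))
  cl <- max.col(-matrix(d2, n), ties.method = "first")
  list(cluster = cl, centers = centers)
}

#' Segment all nuclei of a tissue image
#'
#' Median filtering, k-means colour clustering (the darkest-luminance
#' cluster is kept as nuclear), hole filling, then a watershed split of
#' touching nuclei on the distance transform. Components smaller than
#' `min_area` px are discarded.
#'
#' @param image RGB array or EBImage colour `Image`, values in `[0, 1]`.
#' @param k number of colour clusters (tissue classes); at least 2.
#' @param median_radius median filter radius in px.
#' @param min_area minimum nucleus area in px.
#' @param watershed_ext neighbourhood radius used when splitting touching
#'   nuclei; about the expected nucleus minor semi-axis.
#' @param watershed_tol minimum distance-transform depth separating two
#'   nuclei before they are split.
#' @param min_contrast minimum luminance separation between the darkest
#'   colour cluster and the next one for the dark cluster to count as
#'   nuclear at all; below it the image is treated as nucleus-free.
#' @return a [NucleusSet] (0 nuclei when no dark cluster pixels exist).
#' @export
segmentNuclei <- function(image, k = 3, median_radius = 2, min_area = 10,
                          watershed_ext = 3, watershed_tol = 1,
                          min_contrast = 0.08) {
  stopifnot(k >= 2)
  img <- if (is(image, "Image")) imageData(image) else image
  if (length(dim(img)) != 3) stop("segmentNuclei expects an RGB image")
  if (median_radius > 0)
    for (ch in 1:3) img[, , ch] <- imageData(
      EBImage::medianFilter(EBImage::Image(img[, , ch]), median_radius))
  nx <- dim(img)[1]; ny <- dim(img)[2]
  px <- cbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]), as.numeric(img[, , 3]))
  km <- kmeansColor(px, k = k)
  lum_centers <- sort(km$centers %*% c(0.299, 0.587, 0.114))
  dark <- which.min(km$centers %*% c(0.299, 0.587, 0.114))
  sep <- if (length(lum_centers) > 1) lum_centers[2] - lum_centers[1] else 0
  mask <- matrix(as.integer(km$cluster == dark), nx, ny)
  if (!any(mask > 0) || sep < min_contrast) {
    warning("no distinctly dark colour cluster; returning an empty nucleus set")
    return(NucleusSet(matrix(0L, nx, ny), matrix(numeric(0), 0, 2), numeric(0)))
  }
  maskI <- EBImage::fillHull(EBImage::Image(mask))
  dm <- EBImage::distmap(maskI)
  ws <- EBImage::watershed(dm, tolerance = watershed_tol, ext = watershed_ext)
  wsm <- imageData(ws)
  areas <- tabulate(as.integer(wsm[wsm > 0]))
  keep <- which(areas >= min_area)
  if (!length(keep)) {
    warning("all nuclei below the minimum area; returning an empty nucleus set")
    return(NucleusSet(matrix(0L, nx, ny), matrix(numeric(0), 0, 2), numeric(0)))
  }
  relab <- integer(length(areas)); relab[keep] <- seq_along(keep)
  labels <- matrix(0L, nx, ny)
  pos <- which(wsm > 0)
  labels[pos] <- relab[as.integer(wsm[pos])]
  idx <- which(labels > 0)
  lv <- labels[idx]
  xs <- ((idx - 1) %% nx) + 1; ys <- ((idx - 1) %/% nx) + 1
  cx <- tapply(xs, lv, mean); cy <- tapply(ys, lv, mean)
  NucleusSet(labels, cbind(as.numeric(cx), as.numeric(cy)),
             areas[keep])
}

#' Partition nuclei into epithelial and non-epithelial sets
#'
#' For every point of the lumen boundary, the nucleus whose centroid is
#' nearest (ties broken by the smallest nucleus index) is marked
#' epithelial; the rest are non-epithelial. This is the union over boundary
#' points of the per-point nearest nucleus.
#'
#' @param nuclei a [NucleusSet].
#' @param boundary a [DuctBoundary] (the original lumen boundary).
#' @return the [NucleusSet] with its `epithelial` flags filled in.
#' @export
splitEpithelial <- function(nuclei, boundary) {
  n <- length(nuclei)
  if (n == 0) {
    warning("empty nucleus set: nothing to partition")
    return(nuclei)
  }
  bp <- boundaryPoints(boundary)
  cen <- nucleusCentroids(nuclei)
  epith <- rep(FALSE, n)
  # distance matrix in blocks to bound memory
  block <- 2048L
  for (s in seq(1, nrow(bp), by = block)) {
    e <- min(s + block - 1L, nrow(bp))
    d2 <- outer(bp[s:e, 1], cen[, 1], "-")^2 + outer(bp[s:e, 2], cen[, 2], "-")^2
    # which.min on each row takes the first (smallest index) on ties
    epith[unique(apply(d2, 1, which.min))] <- TRUE
  }
  nuclei@epithelial <- epith
  nuclei
}
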