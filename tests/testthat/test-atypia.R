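mkCircle <- function(r = 100, c0 = c(0, 0), m = 360) {
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  DuctBoundary(cbind(c0[1] + r * cos(th), c0[2] + r * sin(th)))
}

test_that("the ideal boundary of a convex shape is the shape itself", {
  circ <- mkCircle(100, c(150, 150))
  ib <- idealBoundary(circ)
  expect_lt(abs(ib$s - 1), 0.01)
  d <- ductmorph:::distToPolygon(boundaryPoints(ib$ideal), boundaryPoints(circ))
  expect_lt(max(d), 1)
})

test_that("a notched square yields the closed-form scaling factor", {
  # 100 x 100 square with a 20 x 20 corner bite: the region area is 9600 and
  # the convex hull of its vertices closes the bite with a chord, giving
  # 10000 - 20*20/2 = 9800 (shoelace on both polygons)
  poly <- cbind(c(0, 100, 100, 80, 80, 0), c(0, 0, 80, 80, 100, 100))
  ib <- idealBoundary(DuctBoundary(poly))
  expect_equal(polygonArea(poly), 9600)
  expect_equal(polygonArea(boundaryPoints(ib$convex)), 9800, tolerance = 1e-6)
  expect_equal(ib$s, sqrt(9600 / 9800), tolerance = 1e-6)
})

test_that("ideal-boundary area is preserved on random star polygons", {
  set.seed(202)
  for (i in 1:25) {
    poly <- randomStarPolygon()
    ib <- idealBoundary(DuctBoundary(ductmorph:::normalizeBoundary(poly)))
    aO <- polygonArea(poly)
    aI <- polygonArea(boundaryPoints(ib$ideal))
    expect_lt(abs(aI - aO) / aO, 0.01)
  }
})

test_that("collinear boundaries are rejected", {
  line <- cbind(1:5, 1:5)
  expect_error(idealBoundary(DuctBoundary(line)), "degenerate")
})

test_that("the atypia signature is zero for identical boundaries and tracks a bulge", {
  circ <- mkCircle(100, c(150, 150), 720)
  sig0 <- atypiaSignature(circ, circ)
  expect_lt(max(abs(sig0@A)), 0.5)
  # bulge: radius 110 over a 30-degree arc
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  r <- ifelse(abs(th - pi / 2) < pi / 12, 110, 100)
  bo <- DuctBoundary(ductmorph:::normalizeBoundary(
    cbind(150 + r * cos(th), 150 + r * sin(th))))
  sig <- atypiaSignature(circ, bo)
  on_arc <- abs(sig@A) > 5
  expect_gt(sum(on_arc), 10)
  expect_true(all(sig@A[on_arc] > 0))          # bulge is outside: positive
  expect_lt(abs(max(sig@A) - 10), 0.6)
  off_arc <- sig@A[abs(sig@A) <= 5]
  expect_lt(stats::median(abs(off_arc)), 0.5)
})

test_that("arc length telescopes to the ideal-boundary perimeter", {
  circ <- mkCircle(80, c(100, 100), 500)
  sig <- atypiaSignature(circ, circ)
  p <- boundaryPoints(circ)
  m <- nrow(p)
  closing <- sqrt(sum((p[m, ] - p[1, ])^2))
  expect_equal(sig@L[m] + closing, polygonPerimeter(p), tolerance = 1e-9)
})

test_that("RMSAA follows its closed form", {
  expect_equal(rmsaa(AtypiaSignature(c(0, 1, 2), c(0, 0, 0))), 0)
  expect_equal(rmsaa(AtypiaSignature(0:4, rep(-3, 5))), 3)
  expect_equal(rmsaa(AtypiaSignature(c(0, 1), c(3, -4))), sqrt(12.5))
  expect_error(rmsaa(AtypiaSignature(numeric(0), numeric(0))), "empty")
})

test_that("PIP detection keeps endpoints, finds apexes, prunes collinear points", {
  flat <- AtypiaSignature(0:20, 0.5 * (0:20))
  expect_equal(detectPips(flat, T = 1), c(1L, 21L))
  tri <- AtypiaSignature(0:20, c(seq(0, 10, by = 1), seq(9, 0, by = -1)))
  expect_equal(detectPips(tri, T = 1), c(1L, 11L, 21L))
  expect_error(detectPips(tri, T = -1), "non-negative")
})

test_that("PIP detection matches the independent recursive oracle", {
  set.seed(77)
  for (i in 1:200) {
    m <- 50
    L <- cumsum(runif(m, 0.5, 1.5)); L <- L - L[1]
    A <- cumsum(rnorm(m))
    T <- runif(1, 0.2, 3)
    sig <- AtypiaSignature(L, A)
    expect_identical(detectPips(sig, T), brutePips(L, A, T))
  }
})

test_that("TSAV sums interior turning angles", {
  sig3 <- AtypiaSignature(c(0, 1, 2), c(0, 1, 0))
  expect_equal(tsav(sig3, 1:3), pi / 2, tolerance = 1e-9)
  lin <- AtypiaSignature(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_lt(tsav(lin, 1:4), 1e-6)
  expect_equal(tsav(sig3, c(1L, 3L)), 0)
  dup <- AtypiaSignature(c(0, 0, 2), c(0, 0, 1))
  expect_error(tsav(dup, 1:3), "zero-length")
})

test_that("atypia regions count supra-threshold components per side", {
  O <- diskMask(60, pad = 30)
  expect_equal(atypiaRegions(O, O, 300, 1)$numAtypiaRegions, 0)
  expect_equal(atypiaRegions(O, O, 300, 1)$atypiaRatio, 0)
  # add one bump (outside) and carve one notch (inside)
  n <- nrow(O); c0 <- (n + 1) / 2
  xy <- expand.grid(x = 1:n, y = 1:n)
  bump <- matrix((xy$x - (c0 + 60))^2 + (xy$y - c0)^2 <= 18^2, n, n)
  notch <- matrix((xy$x - (c0 - 60))^2 + (xy$y - c0)^2 <= 16^2, n, n)
  O2 <- (O | bump) & !notch
  ar <- atypiaRegions(O2, O, 300, 1)
  expect_equal(ar$numAtypiaRegions, 2)
  expect_setequal(ar$regions$side, c("outside", "inside"))
  want_ratio <- sum(xor(O2, O)) / sum(O2)
  expect_equal(ar$atypiaRatio, want_ratio)
  # sub-threshold pieces keep the ratio positive but the count at zero
  ar2 <- atypiaRegions(O2, O, 4000, 1)
  expect_equal(ar2$numAtypiaRegions, 0)
  expect_gt(ar2$atypiaRatio, 0)
  expect_error(atypiaRegions(matrix(0L, 5, 5), matrix(0L, 5, 5), 300, 1),
               "zero area")
})

test_that("cytoplasm length is the orthogonal centroid-boundary distance", {
  circ <- mkCircle(100, c(150, 150), 720)
  on_b <- boundaryPoints(circ)[1, , drop = FALSE]
  out <- cytoplasmFeatures(on_b, circ, resolution = 1)
  expect_lt(out$mean_um, 0.05)
  ring <- cbind(150 + 110 * cos(seq(0, 2 * pi, length.out = 9)[-9]),
                150 + 110 * sin(seq(0, 2 * pi, length.out = 9)[-9]))
  out2 <- cytoplasmFeatures(ring, circ, resolution = 1)
  expect_lt(max(abs(out2$lengths_um - 10)), 0.5)
  expect_lt(out2$sd_um, 0.1)
  # population standard deviation: equal lengths give exactly zero
  expect_equal(cytoplasmFeatures(ring[c(1, 1, 1), ], circ, 1)$sd_um, 0)
  expect_warning(res <- cytoplasmFeatures(matrix(numeric(0), 0, 2), circ, 1),
                 "no epithelial")
  expect_equal(res$mean_um, 0)
})

test_that("duct features are invariant under rigid motion of the image", {
  cfg <- quickPhantomConfig(rng_seed = 21)
  ph <- generateDuctPhantom(cfg)
  img <- EBImage::imageData(ph$image)
  rot <- aperm(img, c(2, 1, 3))[, dim(img)[1]:1, ]  # 90-degree rotation
  pc <- pipelineConfig()
  f1 <- suppressWarnings(runPipeline(img, pc, resolution = cfg$resolution))
  f2 <- suppressWarnings(runPipeline(rot, pc, resolution = cfg$resolution))
  for (nm in c("RMSAA", "AtypiaRatio", "CytoplasmLength", "CytoplasmLength_SD"))
    expect_lt(abs(f1[[nm]] - f2[[nm]]) / max(abs(f1[[nm]]), 0.5), 0.01)
  expect_equal(f1$NumAtypiaRegions, f2$NumAtypiaRegions)
})
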