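test_that("maximum-entropy binarization separates a two-level image", {
  img <- matrix(50 / 255, 60, 60)
  img[31:60, ] <- 200 / 255
  out <- preprocessBinarize(img, median_radius = 0)
  expect_gt(out$threshold, 50 / 255)
  expect_lt(out$threshold, 200 / 255)
  expect_equal(unname(out$mask[31:60, ]), matrix(1L, 30, 60))
  expect_equal(unname(out$mask[1:30, ]), matrix(0L, 30, 60))
})

test_that("constant images yield an empty mask with a warning", {
  img <- matrix(0.5, 40, 40)
  expect_warning(out <- preprocessBinarize(img, median_radius = 0),
                 "threshold undefined")
  expect_equal(sum(out$mask), 0)
})

test_that("direction cumulative map matches hand counts and the brute force", {
  expect_equal(directionCumulativeMap(matrix(0L, 7, 7)), matrix(0, 7, 7))
  w5 <- matrix(1L, 5, 5)
  expect_equal(directionCumulativeMap(w5)[3, 3], 4 * sqrt(2))
  iso <- matrix(0L, 5, 5); iso[3, 3] <- 1L
  expect_equal(directionCumulativeMap(iso)[3, 3], 0)
  set.seed(42)
  for (i in 1:10) {
    A <- matrix(rbinom(32 * 32, 1, 0.6), 32, 32)
    expect_equal(directionCumulativeMap(A), bruteDirectionMap(A))
  }
})

test_that("seed detection finds bump maxima and handles degenerate maps", {
  expect_equal(nrow(detectSeedPoints(matrix(0, 10, 10))), 0)
  xy <- expand.grid(x = 1:41, y = 1:41)
  H1 <- matrix(pmax(0, 20 - sqrt((xy$x - 21)^2 + (xy$y - 21)^2)), 41, 41)
  s1 <- detectSeedPoints(H1)
  expect_equal(nrow(s1), 1)
  expect_equal(unname(s1[1, ]), c(21, 21))
  H2 <- matrix(pmax(0, 8 - sqrt((xy$x - 10)^2 + (xy$y - 10)^2)), 41, 41) +
        matrix(pmax(0, 8 - sqrt((xy$x - 32)^2 + (xy$y - 30)^2)), 41, 41)
  expect_equal(nrow(detectSeedPoints(H2)), 2)
})

test_that("seeded region growing recovers a bright ellipse and merges seeds", {
  xy <- expand.grid(x = 1:80, y = 1:80)
  ell <- matrix(as.integer(((xy$x - 40) / 25)^2 + ((xy$y - 40) / 15)^2 <= 1), 80, 80)
  gray <- 0.2 + 0.7 * ell
  one <- segmentLumen(gray, cbind(x = 40, y = 40))
  expect_false(one$leaked)
  # boundary within 1 px (Hausdorff) of the true ellipse contour
  truth <- boundaryPoints(traceBoundary(ell))
  d1 <- ductmorph:::distToPolygon(boundaryPoints(one$boundary), truth)
  expect_lt(max(d1), 1.5)
  # a second seed in the same region changes nothing, nor does seed order
  two <- segmentLumen(gray, cbind(x = c(40, 45), y = c(40, 38)))
  rev2 <- segmentLumen(gray, cbind(x = c(45, 40), y = c(38, 40)))
  expect_identical(one$mask, two$mask)
  expect_identical(two$mask, rev2$mask)
})

test_that("homogeneous images grow to the frame with a leak warning", {
  gray <- matrix(0.5, 50, 50)
  expect_warning(out <- segmentLumen(gray, cbind(x = 25, y = 25)),
                 "background leak")
  expect_true(out$leaked)
  expect_equal(sum(out$mask), 2500)
})

test_that("nuclei segmentation counts disjoint and touching nuclei", {
  img <- array(0, dim = c(120, 120, 3))
  for (ch in 1:3) img[, , ch] <- c(0.85, 0.75, 0.8)[ch]
  centers <- expand.grid(x = c(20, 60, 100), y = c(20, 60, 100))
  centers <- centers[1:9, ][-5, ]  # 8 nuclei
  xy <- expand.grid(x = 1:120, y = 1:120)
  for (i in seq_len(nrow(centers))) {
    sel <- ((xy$x - centers$x[i]) / 6)^2 + ((xy$y - centers$y[i]) / 4)^2 <= 1
    for (ch in 1:3) img[, , ch][matrix(sel, 120, 120)] <- c(0.2, 0.15, 0.45)[ch]
  }
  ns <- segmentNuclei(img, median_radius = 0)
  expect_equal(length(ns), 8)
  cen <- nucleusCentroids(ns)
  ord <- order(cen[, 2], cen[, 1])
  got <- cen[ord, , drop = FALSE]
  want <- as.matrix(centers[order(centers$y, centers$x), ])
  expect_lt(max(abs(got - want)), 1)
})

test_that("overlapping nuclei are split by the watershed", {
  img <- array(0.8, dim = c(60, 60, 3))
  xy <- expand.grid(x = 1:60, y = 1:60)
  a <- ((xy$x - 25) / 7)^2 + ((xy$y - 30) / 5)^2 <= 1
  b <- ((xy$x - 36) / 7)^2 + ((xy$y - 30) / 5)^2 <= 1
  for (ch in 1:3) img[, , ch][matrix(a | b, 60, 60)] <- 0.2
  ns <- segmentNuclei(img, median_radius = 0, watershed_ext = 5, watershed_tol = 0.5)
  expect_equal(length(ns), 2)
})

test_that("a nucleus-free image yields an empty set with a warning", {
  img <- array(0, dim = c(40, 40, 3))
  img[, , 1] <- 0.9; img[, , 2] <- 0.7; img[, , 3] <- 0.78
  img <- img + array(rnorm(40 * 40 * 3, 0, 0.005), dim = dim(img))
  ns <- suppressWarnings(segmentNuclei(img, median_radius = 0, min_area = 60))
  expect_equal(length(ns), 0)
})

test_that("epithelial split matches the brute-force nearest-nucleus union", {
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  bo <- DuctBoundary(cbind(100 + 50 * cos(th), 100 + 50 * sin(th)))
  set.seed(11)
  for (rep in 1:5) {
    n <- 15
    cen <- cbind(runif(n, 10, 190), runif(n, 10, 190))
    labels <- matrix(0L, 200, 200)
    labels[cbind(round(cen[, 1]), round(cen[, 2]))] <- seq_len(n)
    ns <- ductmorph:::NucleusSet(labels, cen, rep(1, n))
    got <- isEpithelial(splitEpithelial(ns, bo))
    # brute force: double loop over boundary points and nuclei
    bp <- boundaryPoints(bo)
    want <- rep(FALSE, n)
    for (i in seq_len(nrow(bp))) {
      d <- sqrt((cen[, 1] - bp[i, 1])^2 + (cen[, 2] - bp[i, 2])^2)
      want[which.min(d)] <- TRUE  # which.min takes the lowest index on ties
    }
    expect_identical(got, want)
    expect_equal(sum(got) + sum(!got), n)
  }
})

test_that("a single nucleus is always epithelial and a far group is not", {
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  bo <- DuctBoundary(cbind(150 + 40 * cos(th), 150 + 40 * sin(th)))
  ring_th <- seq(0, 2 * pi, length.out = 13)[-13]
  cen <- rbind(cbind(150 + 45 * cos(ring_th), 150 + 45 * sin(ring_th)),
               cbind(seq(260, 280, length.out = 5), rep(280, 5)))
  labels <- matrix(0L, 300, 300)
  labels[cbind(round(cen[, 1]), round(cen[, 2]))] <- seq_len(nrow(cen))
  ns <- splitEpithelial(ductmorph:::NucleusSet(labels, cen, rep(1, 17)), bo)
  expect_equal(sum(isEpithelial(ns)), 12)
  expect_equal(which(!isEpithelial(ns)), 13:17)
  one <- ductmorph:::NucleusSet(matrix(c(0L, 1L, 0L, 0L), 2, 2),
                                matrix(c(2, 1), 1, 2), 1)
  expect_true(isEpithelial(splitEpithelial(one, bo)))
})
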