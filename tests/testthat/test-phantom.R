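test_that("identical seeds give bit-identical phantoms", {
  a <- generateDuctPhantom(quickPhantomConfig(rng_seed = 5))
  b <- generateDuctPhantom(quickPhantomConfig(rng_seed = 5))
  expect_identical(EBImage::imageData(a$image), EBImage::imageData(b$image))
  expect_identical(lumenMask(a$truth), lumenMask(b$truth))
  expect_identical(a$truth@nuclei, b$truth@nuclei)
  c_ <- generateDuctPhantom(quickPhantomConfig(rng_seed = 6))
  expect_false(identical(EBImage::imageData(a$image), EBImage::imageData(c_$image)))
})

test_that("phantom truth is internally consistent", {
  ph <- generateDuctPhantom(quickPhantomConfig(rng_seed = 9))
  lum <- lumenMask(ph$truth)
  lab <- EBImage::bwlabel(EBImage::Image(lum))
  expect_equal(max(lab), 1)  # one 4-connected component
  nuc <- ph$truth@nuclei
  ep <- nuc[nuc$is_epithelial, ]
  # epithelial centroids lie outside the lumen
  inside <- lum[cbind(round(ep$x), round(ep$y))]
  expect_equal(sum(inside), 0)
  # intended offsets were realized by construction
  expect_lt(max(abs(ep$offset_um - 10)), 0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(generateDuctPhantom(
    phantomConfig(image_size = c(100, 100), lumen_radius = 90)), "does not fit")
  expect_error(generateDuctPhantom(
    quickPhantomConfig(n_epithelial = 500)), "cannot place")
  expect_error(phantomConfig(lumen_radius = -5))
})

test_that("papillary lobes are rendered with analytic region margins", {
  cfg <- phantomConfig(lumen_radius = 180, n_lobes = 3, lobe_area_um2 = 2000,
                       n_epithelial = 40, n_stromal = 60,
                       cytoplasm_offset_mean = 12, rng_seed = 4)
  ph <- generateDuctPhantom(cfg)
  expect_equal(expectedAtypiaLobes(ph$truth), 3L)
  # the truth lumen alone reproduces the expected count through the
  # ideal-boundary construction (no segmentation in the loop)
  bo <- traceBoundary(lumenMask(ph$truth))
  ib <- idealBoundary(bo)
  maskI <- ductmorph:::polygonToMask(boundaryPoints(ib$ideal),
                                     nrow(lumenMask(ph$truth)),
                                     ncol(lumenMask(ph$truth)))
  ar <- atypiaRegions(lumenMask(ph$truth), maskI, 300, cfg$resolution)
  expect_equal(ar$numAtypiaRegions, 3)
})

test_that("cohorts are reproducible and sized n_per_class x classes", {
  cfgs <- list(A = quickPhantomConfig(),
               B = quickPhantomConfig(n_lobes = 2, lobe_area_um2 = 600,
                                      lumen_radius = 110))
  m1 <- generateCohort(1, cfgs, seed = 3, materialize = TRUE)
  expect_equal(nrow(m1), 2)
  expect_equal(length(attr(m1, "images")), 2)
  expect_equal(vapply(attr(m1, "images"), `[[`, character(1), "label"),
               c("A", "B"))
  m2 <- generateCohort(4, cfgs, seed = 3)
  m3 <- generateCohort(4, cfgs, seed = 3)
  expect_identical(m2$seed, m3$seed)
  expect_equal(nrow(m2), 8)
  m4 <- generateCohort(4, cfgs, seed = 4)
  expect_false(identical(m2$seed, m4$seed))
})

test_that("re-segmenting a noise-free phantom recovers the truth lumen", {
  cfg <- quickPhantomConfig(rng_seed = 31, color_noise_sd = 0)
  ph <- generateDuctPhantom(cfg)
  out <- suppressWarnings(
    runPipeline(ph$image, pipelineConfig(), resolution = cfg$resolution,
                keep_objects = TRUE))
  m <- out$objects$lumen$mask; tr <- lumenMask(ph$truth)
  dice <- 2 * sum(m & tr) / (sum(m) + sum(tr))
  expect_gte(dice, 0.98)
  # nucleus count exact, epithelial flags at least 95% correct
  ns <- out$objects$nuclei
  truth_n <- ph$truth@nuclei
  expect_equal(length(ns), nrow(truth_n))
  cen <- nucleusCentroids(ns)
  match_idx <- vapply(seq_len(nrow(truth_n)), function(i)
    which.min((cen[, 1] - truth_n$x[i])^2 + (cen[, 2] - truth_n$y[i])^2),
    integer(1))
  agree <- isEpithelial(ns)[match_idx] == truth_n$is_epithelial
  expect_gte(mean(agree), 0.95)
})
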