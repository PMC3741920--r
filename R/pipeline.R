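# Image/table IO, pipeline configuration and the end-to-end feature
# extraction for one duct image.

#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline, with physical units.
#'
#' @param resolution micrometres per pixel (used unless TIFF metadata or a
#'   caller overrides it).
#' @param median_radius median filter radius, px.
#' @param background_radius rolling-ball illumination-correction radius, px.
#' @param srg_tol region-growing homogeneity tolerance on `[0, 1]`.
#' @param k colour clusters for nuclei segmentation.
#' @param min_nucleus_area minimum nucleus area, px.
#' @param watershed_ext watershed neighbourhood radius, px.
#' @param pip_T PIP vertical-distance threshold, signature (pixel) units.
#' @param theta_min PIP pruning angle, radians.
#' @param atypia_threshold_um2 atypia-region counting threshold, um^2.
#' @param seed master seed recorded with every output row.
#' @return a config list of class `pipeline_config`.
#' @export
pipelineConfig <- function(resolution = 0.492, median_radius = 2,
                           background_radius = 0, srg_tol = 0.15, k = 3,
                           min_nucleus_area = 10, watershed_ext = 3,
                           pip_T = 1.0, theta_min = 5 * pi / 180,
                           atypia_threshold_um2 = 300, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(resolution > 0, median_radius >= 0, background_radius >= 0,
            srg_tol > 0, k >= 2, min_nucleus_area >= 0, pip_T >= 0,
            theta_min >= 0, atypia_threshold_um2 >= 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read/write a pipeline configuration
#'
#' Serialized as JSON; a written config re-parses to an identical object.
#'
#' @param cfg a [pipelineConfig()]; `path` a file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Load a duct image
#'
#' Reads a 24-bit RGB PNG or TIFF into the package's `[x, y, 3]`
#' convention. The physical resolution comes from `resolution` when given,
#' else from the TIFF resolution metadata (converted to micrometres per
#' pixel), else from the `default_resolution`.
#'
#' @param path image file.
#' @param resolution micrometres per pixel; overrides any metadata.
#' @param default_resolution fallback when neither is available.
#' @return list with `image` (EBImage colour `Image`) and `resolution`.
#' @export
loadDuctImage <- function(path, resolution = NULL, default_resolution = 0.492) {
  if (!file.exists(path)) stop("no such image file: ", path)
  lower <- tolower(path)
  meta_res <- NULL
  if (grepl("\\.png$", lower)) {
    arr <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    arr <- tiff::readTIFF(path, info = TRUE)
    xres <- attr(arr, "x.resolution"); unit <- attr(arr, "resolution.unit")
    if (!is.null(xres) && is.numeric(xres) && xres > 0) {
      per_px <- 1 / xres
      meta_res <- switch(ifelse(is.null(unit), "inch", as.character(unit)),
                         cm = per_px * 1e4, inch = per_px * 25400, NULL)
    }
  } else stop("unsupported image format (need PNG or TIFF): ", path)
  if (length(dim(arr)) == 3 && dim(arr)[3] == 4) arr <- arr[, , 1:3]
  if (length(dim(arr)) != 3 || dim(arr)[3] != 3)
    stop("expected 3 channels in ", path)
  img <- aperm(arr, c(2, 1, 3))  # readers return [row, col, ch]
  list(image = EBImage::Image(img, colormode = "Color"),
       resolution = if (!is.null(resolution)) resolution
                    else if (!is.null(meta_res)) meta_res else default_resolution)
}

#' Write a phantom image as PNG
#' @param image EBImage colour `Image` (`[x, y, 3]`).
#' @param path output file.
#' @export
writeDuctImage <- function(image, path) {
  arr <- aperm(imageData(image), c(2, 1, 3))
  png::writePNG(arr, path)
  invisible(path)
}

#' Export / import a boundary as JSON
#' @param boundary a [DuctBoundary]; `path` a file path.
#' @export
writeBoundaryJson <- function(boundary, path) {
  jsonlite::write_json(list(kind = boundary@kind,
                            x = boundaryPoints(boundary)[, 1],
                            y = boundaryPoints(boundary)[, 2]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBoundaryJson
#' @export
readBoundaryJson <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  DuctBoundary(cbind(d$x, d$y), kind = d$kind)
}

ductFeatureNames <- function() {
  c(paste0("Lumen_", classicalFeatureNames),
    paste0("EN_", classicalFeatureNames),
    paste0("NEN_", classicalFeatureNames),
    proposedLumenFeatures, proposedEpithelialFeatures)
}

#' Run the full feature-extraction pipeline on one image
#'
#' Lumen segmentation (binarize, direction cumulative map, seed detection,
#' seeded region growing), nuclei segmentation and the epithelial split,
#' classical features for the lumen and per-image nucleus averages, and the
#' duct-atypia features. Nucleus classical features are averaged over the
#' nuclei of each class to give one row per image.
#'
#' @param image an EBImage colour `Image`, an `[x, y, 3]` array, or a file
#'   path.
#' @param cfg a [pipelineConfig()].
#' @param resolution micrometres per pixel; overrides `cfg$resolution`.
#' @param keep_objects also return the intermediate objects (masks,
#'   boundaries, nucleus set, signature).
#' @return one-row data.frame: 36 classical columns (`Lumen_*`, `EN_*`,
#'   `NEN_*`), `RMSAA` (um), `TSAV` (rad), `AtypiaRatio`,
#'   `NumAtypiaRegions`, `CytoplasmLength` (um), `CytoplasmLength_SD` (um),
#'   plus `status` (`"ok"` or `"lumen_not_found"`) and `seed`. With
#'   `keep_objects = TRUE`, a list `(features, objects)`.
#' @export
runPipeline <- function(image, cfg = pipelineConfig(), resolution = NULL,
                        keep_objects = FALSE) {
  if (is.character(image)) {
    loaded <- loadDuctImage(image, resolution)
    image <- loaded$image
    if (is.null(resolution)) resolution <- loaded$resolution
  }
  res <- if (!is.null(resolution)) resolution else cfg$resolution
  img <- if (is(image, "Image")) imageData(image) else image
  gray <- luminanceOf(img)

  row <- as.data.frame(setNames(as.list(rep(NA_real_, length(ductFeatureNames()))),
                                ductFeatureNames()))
  row$status <- "ok"; row$seed <- cfg$seed

  pre <- preprocessBinarize(img, cfg$median_radius, cfg$background_radius)
  seeds <- detectSeedPoints(directionCumulativeMap(pre$mask))
  if (nrow(seeds) == 0) {
    row$status <- "lumen_not_found"
    return(if (keep_objects) list(features = row, objects = NULL) else row)
  }
  lum <- segmentLumen(pre$gray, seeds, tol = cfg$srg_tol)
  BO <- lum$boundary

  nuclei <- segmentNuclei(img, k = cfg$k, median_radius = cfg$median_radius,
                          min_area = cfg$min_nucleus_area,
                          watershed_ext = cfg$watershed_ext)
  if (length(nuclei) > 0) nuclei <- splitEpithelial(nuclei, BO)

  # classical features: lumen region, then per-image nucleus means
  lf <- regionFeatures(lum$mask, gray, res)
  row[paste0("Lumen_", classicalFeatureNames)] <- as.list(lf)
  labs <- nucleusLabels(nuclei)
  nxm <- nrow(labs)
  pixByNuc <- split(which(labs > 0), labs[labs > 0])
  nucFeat <- function(idx) {
    xs <- ((idx - 1) %% nxm) + 1
    ys <- ((idx - 1) %/% nxm) + 1
    xr <- (min(xs) - 1):(max(xs) + 1); yr <- (min(ys) - 1):(max(ys) + 1)
    xr <- xr[xr >= 1 & xr <= nxm]; yr <- yr[yr >= 1 & yr <= ncol(labs)]
    sub <- matrix(0L, length(xr), length(yr))
    sub[cbind(match(xs, xr), match(ys, yr))] <- 1L
    regionFeatures(sub, gray[xr, yr, drop = FALSE], res)
  }
  for (grp in c("EN", "NEN")) {
    want <- if (grp == "EN") isEpithelial(nuclei) %in% TRUE else isEpithelial(nuclei) %in% FALSE
    ids <- which(want)
    if (length(ids)) {
      fm <- vapply(pixByNuc[as.character(ids)], nucFeat, numeric(12))
      row[paste0(grp, "_", classicalFeatureNames)] <- as.list(rowMeans(fm))
    } else {
      row[paste0(grp, "_", classicalFeatureNames)] <- as.list(rep(0, 12))
    }
  }

  ib <- idealBoundary(BO)
  sig <- atypiaSignature(ib$ideal, BO, resolution = res)
  pips <- detectPips(sig, T = cfg$pip_T, theta_min = cfg$theta_min)
  maskI <- polygonToMask(boundaryPoints(ib$ideal), nrow(lum$mask), ncol(lum$mask))
  ar <- atypiaRegions(lum$mask, maskI, cfg$atypia_threshold_um2, res)
  cyto <- cytoplasmFeatures(nuclei, BO, res)
  row$RMSAA <- rmsaa(sig) * res
  row$TSAV <- tsav(sig, pips)
  row$AtypiaRatio <- ar$atypiaRatio
  row$NumAtypiaRegions <- ar$numAtypiaRegions
  row$CytoplasmLength <- cyto$mean_um
  row$CytoplasmLength_SD <- cyto$sd_um

  if (keep_objects)
    list(features = row,
         objects = list(binarized = pre, seeds = seeds, lumen = lum,
                        nuclei = nuclei, ideal = ib, signature = sig,
                        pips = pips, atypia_regions = ar, cytoplasm = cyto))
  else row
}

#' Extract the feature table of a phantom cohort
#'
#' Runs [runPipeline()] over every image of a [generateCohort()] manifest,
#' rendering phantoms one at a time.
#'
#' @param manifest cohort manifest from [generateCohort()].
#' @param cfg a [pipelineConfig()]; its resolution is overridden by each
#'   phantom's own.
#' @param verbose print progress.
#' @return data.frame of per-image features with a `label` column.
#' @export
cohortFeatureTable <- function(manifest, cfg = pipelineConfig(), verbose = FALSE) {
  cfgs <- attr(manifest, "configs")
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    ph <- generateDuctPhantom(cfgs[[i]])
    r <- runPipeline(ph$image, cfg, resolution = cfgs[[i]]$resolution)
    if (verbose && i %% 20 == 0) message("  image ", i, "/", nrow(manifest))
    r$label <- manifest$class[i]
    r
  })
  do.call(rbind, rows)
}

# CSV export with the conventional printed feature names
tableFeatureNames <- c(NumAtypiaRegions = "#AtypiaRegions")

#' Write / read a feature table as CSV
#'
#' Columns use the conventional feature names (`#AtypiaRegions` for the
#' atypia-region count); reading restores the package's internal names.
#'
#' @param features data.frame from [runPipeline()] rows; `path` file path.
#' @export
writeFeatureTable <- function(features, path) {
  out <- features
  for (i in seq_along(tableFeatureNames))
    names(out)[names(out) == names(tableFeatureNames)[i]] <- tableFeatureNames[i]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  for (i in seq_along(tableFeatureNames))
    names(d)[names(d) == tableFeatureNames[i]] <- names(tableFeatureNames)[i]
  d
}
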