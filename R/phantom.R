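# Synthetic duct phantoms with analytic ground truth.
#
# A phantom is a bright lumen on pink stroma ringed by dark, radially
# oriented (columnar) epithelial nuclei, with scattered stromal nuclei.
# Papillary atypia is rendered as n_lobes elliptical papillae projecting
# into the lumen from the rim. Because the ideal-boundary construction is
# area preserving, the symmetric difference between the lumen and its ideal
# shape always balances papilla area with an equal area on the other side
# of the ideal boundary; to keep the atypia-region count analytic, the rim
# is crenellated (square-wave, period `cren_period`) so that the balancing
# area is spent in slivers of closed-form size lambda/2 * delta, well below
# the counting threshold, while each papilla core stays well above it.

#' Phantom generator configuration
#'
#' @param image_size `c(width, height)` in px, or `NULL` to fit the duct.
#' @param lumen_radius lumen crest radius in px.
#' @param n_lobes number of papillary lobes (0 = convex duct).
#' @param lobe_area_um2 area of each papilla in square micrometres.
#' @param boundary_noise_amp RMS radial boundary perturbation in px
#'   (smooth, low-order harmonics).
#' @param n_epithelial,n_stromal nucleus counts.
#' @param cytoplasm_offset_mean,cytoplasm_offset_sd nucleus-to-lumen
#'   offset in micrometres (the sd models loss of nuclear polarity).
#' @param nucleus_axes `c(major, minor)` full ellipse axes in px.
#' @param resolution micrometres per pixel of the rendered image.
#' @param lumen_radius_sd,n_lobes_sd,offset_between_sd between-image
#'   spreads: the realized radius, lobe count and mean cytoplasm offset of
#'   one phantom are drawn around their nominal values with these standard
#'   deviations (0 = deterministic), emulating the large duct-to-duct
#'   variability of real cohorts.
#' @param rng_seed integer seed; identical seeds give identical phantoms.
#' @param cren_period,cren_sliver crenellation period and inner sliver
#'   depth in px (papillary phantoms only).
#' @param color_noise_sd additive Gaussian RGB noise.
#' @param atypia_threshold_um2 counting threshold the analytic margins are
#'   validated against.
#' @return a validated config list of class `phantom_config`.
#' @export
phantomConfig <- function(image_size = NULL, lumen_radius = 220, n_lobes = 0,
                          lobe_area_um2 = 2000, boundary_noise_amp = 0,
                          n_epithelial = 36, n_stromal = 80,
                          cytoplasm_offset_mean = 12, cytoplasm_offset_sd = 0,
                          nucleus_axes = c(9.4, 6.2), resolution = 0.984,
                          lumen_radius_sd = 0, n_lobes_sd = 0,
                          offset_between_sd = 0,
                          rng_seed = 1, cren_period = 24, cren_sliver = 4,
                          color_noise_sd = 0.01, stroma_noise_sd = 0.035,
                          atypia_threshold_um2 = 300) {
  cfg <- list(image_size = image_size, lumen_radius = lumen_radius,
              n_lobes = as.integer(n_lobes), lobe_area_um2 = lobe_area_um2,
              boundary_noise_amp = boundary_noise_amp,
              n_epithelial = as.integer(n_epithelial),
              n_stromal = as.integer(n_stromal),
              cytoplasm_offset_mean = cytoplasm_offset_mean,
              cytoplasm_offset_sd = cytoplasm_offset_sd,
              nucleus_axes = nucleus_axes, resolution = resolution,
              lumen_radius_sd = lumen_radius_sd, n_lobes_sd = n_lobes_sd,
              offset_between_sd = offset_between_sd,
              rng_seed = as.integer(rng_seed), cren_period = cren_period,
              cren_sliver = cren_sliver, color_noise_sd = color_noise_sd,
              stroma_noise_sd = stroma_noise_sd,
              atypia_threshold_um2 = atypia_threshold_um2)
  with(cfg, {
    stopifnot(lumen_radius > 0, n_lobes >= 0, lobe_area_um2 > 0,
              boundary_noise_amp >= 0, n_epithelial >= 0, n_stromal >= 0,
              cytoplasm_offset_mean > 0, cytoplasm_offset_sd >= 0,
              all(nucleus_axes > 0), resolution > 0)
  })
  class(cfg) <- "phantom_config"
  cfg
}

# radius(theta) of the phantom lumen plus lobe/crenellation bookkeeping
phantomBoundaryProfile <- function(cfg, theta, noise_coef = NULL) {
  r <- cfg$lumen_radius
  A_px <- cfg$lobe_area_um2 / cfg$resolution^2
  depth <- numeric(length(theta))
  k <- cfg$n_lobes
  if (k > 0) {
    ncren <- max(8L, round(2 * pi * r / cfg$cren_period))
    dout <- cfg$cren_sliver + k * A_px / (pi * r)
    depth <- (cfg$cren_sliver + dout) * (cos(ncren * theta) < 0)
    b <- sqrt(A_px / pi)          # papilla along-rim semi-axis
    cdep <- 2.6 * b               # papilla depth semi-axis
    if (cdep + cfg$cren_sliver + dout > 0.6 * r)
      stop("papillae too deep for this lumen radius; enlarge lumen_radius or shrink lobe_area_um2")
    centers <- 2 * pi * (seq_len(k) - 1) / k + pi / (2 * k)
    for (c0 in centers) {
      dth <- atan2(sin(theta - c0), cos(theta - c0))
      u <- dth * r / b
      sel <- abs(u) < 1
      depth[sel] <- depth[sel] + cdep * sqrt(pmax(0, 1 - u[sel]^2))
    }
  }
  rad <- r - depth
  if (cfg$boundary_noise_amp > 0 && !is.null(noise_coef)) {
    modes <- 3:7
    f <- numeric(length(theta))
    for (i in seq_along(modes))
      f <- f + noise_coef$c[i] * cos(modes[i] * theta + noise_coef$phi[i])
    rad <- rad + cfg$boundary_noise_amp * f / noise_coef$rms
  }
  rad
}

#' Generate one synthetic duct phantom
#'
#' Renders the image (bright lumen, dark nuclei, pink stroma, additive
#' Gaussian noise) and its ground truth. Identical configurations produce
#' bit-identical output.
#'
#' @param cfg a [phantomConfig()].
#' @return list with `image` (EBImage colour `Image`) and `truth`
#'   (a [PhantomTruth]).
#' @export
generateDuctPhantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  withSeed(cfg$rng_seed, {
    res <- cfg$resolution
    # between-image variability: realize this phantom's radius, lobe count
    # and offset around the nominal study conditions
    if (cfg$lumen_radius_sd > 0) {
      r0 <- cfg$lumen_radius
      draw <- stats::rnorm(1, r0, cfg$lumen_radius_sd)
      draw <- min(max(draw, r0 - 2 * cfg$lumen_radius_sd),
                  r0 + 2 * cfg$lumen_radius_sd)   # truncate at 2 sd
      cfg$lumen_radius <- max(40, round(draw))
      # cell counts track duct size so the epithelial lining stays contiguous
      sc <- cfg$lumen_radius / r0
      cfg$n_epithelial <- max(8L, as.integer(round(cfg$n_epithelial * sc)))
      cfg$n_stromal <- max(8L, as.integer(round(cfg$n_stromal * sc)))
    }
    if (cfg$n_lobes_sd > 0)
      cfg$n_lobes <- max(0L, as.integer(round(stats::rnorm(1, cfg$n_lobes,
                                                           cfg$n_lobes_sd))))
    if (cfg$offset_between_sd > 0)
      cfg$cytoplasm_offset_mean <- max((cfg$nucleus_axes[2] / 2 + 2.5) * res,
                                       stats::rnorm(1, cfg$cytoplasm_offset_mean,
                                                    cfg$offset_between_sd))
    # shed lobes that cannot fit the realized radius
    A_px <- cfg$lobe_area_um2 / res^2
    while (cfg$n_lobes > 0 &&
           2.6 * sqrt(A_px / pi) + 2 * cfg$cren_sliver +
             cfg$n_lobes * A_px / (pi * cfg$lumen_radius) > 0.6 * cfg$lumen_radius)
      cfg$n_lobes <- cfg$n_lobes - 1L
    off_px_max <- (cfg$cytoplasm_offset_mean + 3 * cfg$cytoplasm_offset_sd) / res
    margin <- ceiling(off_px_max + cfg$nucleus_axes[1] + 3 * cfg$boundary_noise_amp + 14)
    need <- 2 * (cfg$lumen_radius + margin)
    size <- if (is.null(cfg$image_size)) c(need, need) else cfg$image_size
    if (size[1] < need || size[2] < need)
      stop(sprintf("lumen (radius %g px plus margins) does not fit a %d x %d image",
                   cfg$lumen_radius, size[1], size[2]))
    W <- as.integer(size[1]); H <- as.integer(size[2])
    cx <- (W + 1) / 2; cy <- (H + 1) / 2

    noise_coef <- NULL
    if (cfg$boundary_noise_amp > 0) {
      cc <- stats::rnorm(5); phi <- stats::runif(5, 0, 2 * pi)
      noise_coef <- list(c = cc, phi = phi, rms = sqrt(sum(cc^2) / 2))
    }
    m <- max(1440L, as.integer(ceiling(14 * cfg$lumen_radius)))
    theta <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
    rad <- phantomBoundaryProfile(cfg, theta, noise_coef)
    if (any(rad <= 2)) stop("boundary perturbation collapses the lumen")
    poly <- cbind(cx + rad * cos(theta), cy + rad * sin(theta))
    lumen <- polygonToMask(poly, W, H)
    lab <- EBImage::bwlabel(EBImage::Image(lumen))
    if (max(lab) > 1) {
      # rasterizing the crenellated rim can strand a few pixels where a wall
      # runs along a scan row; keep the dominant component
      counts <- tabulate(as.integer(lab[lab > 0]))
      if (max(counts) < 0.999 * sum(counts))
        stop("lumen mask is not a single connected component")
      lumen <- matrix(as.integer(imageData(lab) == which.max(counts)), W, H)
    }

    # --- epithelial nuclei: candidate slots are sampled along the whole
    # boundary polygon (papillae included, as real epithelium lines them),
    # each offset along the local outward normal; a slot is kept only when
    # the achieved nearest-boundary distance equals the intended offset
    # (within 0.3 px), which automatically rejects high-curvature papilla
    # tips and crenellation walls where the offset cannot be realized ----
    aMaj <- cfg$nucleus_axes[1] / 2; aMin <- cfg$nucleus_axes[2] / 2
    offs_um <- rep(cfg$cytoplasm_offset_mean, cfg$n_epithelial) +
      if (cfg$cytoplasm_offset_sd > 0) stats::rnorm(cfg$n_epithelial, 0, cfg$cytoplasm_offset_sd) else 0
    offs_um <- pmax(offs_um, (aMin + 2) * res)
    cand <- resampleClosed(poly, 4)
    nc <- nrow(cand)
    nxt <- c(2:nc, 1); prv <- c(nc, 1:(nc - 1))
    tang <- cand[nxt, , drop = FALSE] - cand[prv, , drop = FALSE]
    tlen <- pmax(sqrt(rowSums(tang^2)), 1e-9)
    nrm <- cbind(tang[, 2], -tang[, 1]) / tlen
    probe <- cand + 3 * nrm
    inside <- pointsInPolygon(probe, poly)
    nrm[inside, ] <- -nrm[inside, , drop = FALSE]
    off_probe_px <- max(cfg$cytoplasm_offset_mean / res, (aMin + 2))
    pts <- cand + off_probe_px * nrm
    ok <- abs(distToPolygon(pts, poly) - off_probe_px) < 0.3 &
      pts[, 1] > aMaj + 2 & pts[, 1] < W - aMaj - 2 &
      pts[, 2] > aMaj + 2 & pts[, 2] < H - aMaj - 2
    slots <- which(ok)
    nuc <- list(); canvas <- matrix(0L, W, H)
    placed <- 0; tries_ep <- 0
    if (cfg$n_epithelial > 0) {
      # evenly spread primary slots, then fill collisions from the rest
      prim <- unique(round(seq(1, length(slots), length.out = min(length(slots), cfg$n_epithelial))))
      order_idx <- slots[c(prim, setdiff(seq_along(slots), prim))]
      i <- 0
      for (j in order_idx) {
        if (i >= cfg$n_epithelial) break
        pos <- cand[j, ] + (offs_um[i + 1] / res) * nrm[j, ]
        ang <- atan2(nrm[j, 2], nrm[j, 1])   # long axis along the normal: columnar
        px <- ellipsePixels(pos, aMaj, aMin, ang, W, H)
        px_pad <- ellipsePixels(pos, aMaj + 1.5, aMin + 1.5, ang, W, H)
        if (any(lumen[px] > 0) || any(canvas[px_pad] > 0)) next
        canvas[px] <- length(nuc) + 1L
        achieved <- distToPolygon(matrix(pos, 1, 2), poly) * res
        nuc[[length(nuc) + 1]] <- data.frame(x = pos[1], y = pos[2],
                                             is_epithelial = TRUE, offset_um = achieved)
        i <- i + 1
      }
      if (i < cfg$n_epithelial)
        stop(sprintf("cannot place %d epithelial nuclei without overlap (placed %d)",
                     cfg$n_epithelial, i))
    }

    # --- stromal nuclei: rejection-sampled well clear of the duct; the
    # clearance exceeds the worst epithelial-to-boundary distance (offset
    # plus crenellation depth) so no boundary point is nearer to a stromal
    # nucleus than to an epithelial one --------------------------------
    cren_depth <- if (cfg$n_lobes > 0)
      2 * cfg$cren_sliver + cfg$n_lobes * (cfg$lobe_area_um2 / res^2) / (pi * cfg$lumen_radius)
      else 0
    clear_px <- off_px_max + cfg$nucleus_axes[1] + 6 + 1.5 * cren_depth
    tries <- 0
    while (sum(vapply(nuc, function(d) !d$is_epithelial, logical(1))) < cfg$n_stromal) {
      tries <- tries + 1
      if (tries > 400 * max(cfg$n_stromal, 1))
        stop("cannot place the requested stromal nuclei without overlap")
      pos <- c(stats::runif(1, aMaj + 2, W - aMaj - 2),
               stats::runif(1, aMaj + 2, H - aMaj - 2))
      if (distToPolygon(matrix(pos, 1, 2), poly) < clear_px) next
      if (sqrt(sum((pos - c(cx, cy))^2)) < cfg$lumen_radius) next
      ang <- stats::runif(1, 0, pi)
      px <- ellipsePixels(pos, aMaj, aMin, ang, W, H)
      # test an inflated footprint so rendered nuclei keep a gap that the
      # watershed split can always resolve
      px_pad <- ellipsePixels(pos, aMaj + 3, aMin + 3, ang, W, H)
      if (any(lumen[px] > 0) || any(canvas[px_pad] > 0)) next
      canvas[px] <- length(nuc) + 1L
      nuc[[length(nuc) + 1]] <- data.frame(x = pos[1], y = pos[2],
                                           is_epithelial = FALSE, offset_um = NA_real_)
    }
    nuclei <- if (length(nuc)) do.call(rbind, nuc)
              else data.frame(x = numeric(0), y = numeric(0),
                              is_epithelial = logical(0), offset_um = numeric(0))

    # --- render ----------------------------------------------------------
    # eosin-like textured stroma, glass-bright lumen, hematoxylin nuclei;
    # stroma carries extra texture so the luminance histogram has the broad
    # tissue mode the entropy thresholder expects of real H&E
    img <- array(0, dim = c(W, H, 3))
    stroma <- c(200, 140, 170) / 255
    lum_col <- c(245, 245, 245) / 255
    nuc_col <- c(60, 40, 120) / 255
    texture <- if (cfg$stroma_noise_sd > 0)
      matrix(stats::rnorm(W * H, 0, cfg$stroma_noise_sd), W, H) else matrix(0, W, H)
    for (ch in 1:3) {
      plane <- matrix(stroma[ch], W, H) + texture
      plane[lumen > 0] <- lum_col[ch]
      plane[canvas > 0] <- nuc_col[ch]
      if (cfg$color_noise_sd > 0)
        plane <- plane + stats::rnorm(W * H, 0, cfg$color_noise_sd)
      img[, , ch] <- pmin(pmax(plane, 0), 1)
    }
    truth <- new("PhantomTruth", lumenMask = lumen, nuclei = nuclei,
                 expectedAtypiaLobes = cfg$n_lobes, config = unclass(cfg))
    list(image = EBImage::Image(img, colormode = "Color"), truth = truth)
  })
}

# pixel indices of a filled rotated ellipse, clipped to the image
ellipsePixels <- function(center, a, b, angle, W, H) {
  x0 <- center[1]; y0 <- center[2]
  xr <- max(1, floor(x0 - a)):min(W, ceiling(x0 + a))
  yr <- max(1, floor(y0 - a)):min(H, ceiling(y0 + a))
  gx <- rep(xr, times = length(yr)) - x0
  gy <- rep(yr, each = length(xr)) - y0
  u <- gx * cos(angle) + gy * sin(angle)
  v <- -gx * sin(angle) + gy * cos(angle)
  sel <- (u / a)^2 + (v / b)^2 <= 1
  (rep(yr, each = length(xr))[sel] - 1L) * W + rep(xr, times = length(yr))[sel]
}

#' Per-grade phantom configurations
#'
#' Study conditions for a three-class cohort (normal ducts,
#' well-differentiated and moderately differentiated carcinoma), with lumen
#' sizes, papilla counts, cytoplasm offsets and polarity jitter set from
#' the per-grade group means of the reported feature statistics.
#'
#' @param resolution micrometres per pixel of the rendered phantoms.
#' @return named list of [phantomConfig()] templates
#'   (`Normal`, `Grade1`, `Grade2`).
#' @export
gradePhantomConfigs <- function(resolution = 0.984) {
  list(
    Normal = phantomConfig(lumen_radius = round(110 / resolution), n_lobes = 0,
                           boundary_noise_amp = 0.6, n_epithelial = 42,
                           n_stromal = 60, cytoplasm_offset_mean = 6.2,
                           cytoplasm_offset_sd = 2.1, lumen_radius_sd = 18,
                           n_lobes_sd = 0.25, offset_between_sd = 1.8,
                           nucleus_axes = c(9.0, 6.0) / resolution * 0.984,
                           resolution = resolution),
    Grade1 = phantomConfig(lumen_radius = round(147 / resolution), n_lobes = 2,
                           lobe_area_um2 = 1500, boundary_noise_amp = 2.5,
                           n_epithelial = 46, n_stromal = 80,
                           cytoplasm_offset_mean = 12.9, cytoplasm_offset_sd = 5.75,
                           lumen_radius_sd = 28, n_lobes_sd = 1.4,
                           offset_between_sd = 2.6,
                           nucleus_axes = c(10.2, 6.6) / resolution * 0.984,
                           resolution = resolution),
    Grade2 = phantomConfig(lumen_radius = round(195 / resolution), n_lobes = 5,
                           lobe_area_um2 = 1500, boundary_noise_amp = 4.5,
                           n_epithelial = 56, n_stromal = 110,
                           cytoplasm_offset_mean = 15.9, cytoplasm_offset_sd = 8.47,
                           lumen_radius_sd = 42, n_lobes_sd = 1.6,
                           offset_between_sd = 2.3,
                           nucleus_axes = c(9.8, 6.2) / resolution * 0.984,
                           resolution = resolution))
}

#' Generate a labelled phantom cohort
#'
#' Derives one reproducible seed per image from the master seed and returns
#' a manifest; images are rendered lazily (or eagerly with
#' `materialize = TRUE`) so that large cohorts need not be held in memory.
#'
#' @param n_per_class images per class; `>= 1`.
#' @param class_cfgs named list of [phantomConfig()] templates, one per
#'   class (e.g. [gradePhantomConfigs()]).
#' @param seed master seed.
#' @param materialize render all images now.
#' @return a data.frame manifest (`class`, `seed`) with the per-image
#'   configs in `attr(, "configs")`; with `materialize = TRUE`, also an
#'   `images` attribute holding `list(image, truth, label)` per row.
#' @export
generateCohort <- function(n_per_class, class_cfgs, seed = 1, materialize = FALSE) {
  stopifnot(n_per_class >= 1, length(class_cfgs) >= 1, !is.null(names(class_cfgs)))
  n <- n_per_class * length(class_cfgs)
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
  manifest <- data.frame(class = rep(names(class_cfgs), each = n_per_class),
                         seed = seeds, stringsAsFactors = FALSE)
  cfgs <- lapply(seq_len(n), function(i) {
    cfg <- class_cfgs[[manifest$class[i]]]
    cfg$rng_seed <- manifest$seed[i]
    cfg
  })
  attr(manifest, "configs") <- cfgs
  if (materialize)
    attr(manifest, "images") <- lapply(seq_len(n), function(i) {
      ph <- generateDuctPhantom(cfgs[[i]])
      list(image = ph$image, truth = ph$truth, label = manifest$class[i])
    })
  manifest
}
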