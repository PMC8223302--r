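#' Model leaf reflectance spectrum
#'
#' Smooth vegetation-like reflectance over the 250-band grid (roughly
#' 400-1000 nm): a green peak near 550 nm, a chlorophyll-driven red valley
#' near 670 nm, a red-edge rise over 680-760 nm onto the NIR plateau, and a
#' water-absorption dip on the 930-1000 nm shoulder whose depth scales with
#' the `water` parameter. Increasing `water` makes the first derivative of
#' reflectance around 959 nm more negative (the dip is centered beyond the
#' band so 959 nm sits on its descending flank); increasing `chlorophyll`
#' deepens the red valley.
#'
#' @param water water-content parameter in `[0, 1]`.
#' @param chlorophyll chlorophyll parameter in `[0, 1]`.
#' @param n_bands number of spectral bands (default 250).
#' @return numeric reflectance vector in `[0, 1]`, length `n_bands`.
#' @export
leaf_spectrum <- function(water = 0.5, chlorophyll = 0.5, n_bands = 250) {
  wl <- band_wavelength(seq_len(n_bands), n_bands = n_bands)
  r <- 0.08 + 0.42 * stats::plogis((wl - 715) / 18) +       # red edge -> NIR
    0.08 * exp(-((wl - 550) / 30)^2) -                      # green peak
    0.06 * chlorophyll * exp(-((wl - 670) / 30)^2) -        # red valley
    0.30 * water * exp(-((wl - 980) / 40)^2)                # water dip
  pmin(pmax(r, 0), 1)
}

#' Phantom specification for a synthetic plant scan triplet
#'
#' Collects the ground-truth geometry and optics of one synthetic plant:
#' silhouette area/height/width for the RGB stack, foreground/background
#' reflectance for the hyperspectral cube, and culm annulus radii and
#' intensities for the CT slice. All downstream extractors can be checked
#' against these values.
#'
#' @param plant_area_px target foreground pixel count per side view.
#' @param plant_height_px,plant_width_px silhouette extents in px.
#' @param leaf_reflectance,background_reflectance length-`n_bands` vectors in
#'   `[0, 1]`.
#' @param culm_outer_radius_px,culm_inner_radius_px annulus radii
#'   (outer > inner > 0).
#' @param material_intensity,background_intensity reconstructed-intensity
#'   values of culm wall and background.
#' @param n_views number of side views (default 20).
#' @param n_bands number of spectral bands (default 250).
#' @param n_projections number of CT projections at 1 degree steps
#'   (default 360).
#' @param hsi_noise_sd reflectance noise sd added per pixel/band.
#' @param seed integer seed.
#' @return an object of class `phantom_spec` (validated list).
#' @export
phantom_spec <- function(plant_area_px = 12000, plant_height_px = 150,
                         plant_width_px = 120,
                         leaf_reflectance = leaf_spectrum(),
                         background_reflectance = rep(0.05, 250),
                         culm_outer_radius_px = 40, culm_inner_radius_px = 25,
                         material_intensity = 1000, background_intensity = 0,
                         n_views = 20, n_bands = 250, n_projections = 360,
                         hsi_noise_sd = 0.005, seed = 1) {
  if (culm_inner_radius_px <= 0 || culm_outer_radius_px <= culm_inner_radius_px)
    stopf("culm radii must satisfy 0 < inner < outer")
  if (n_views < 1) stopf("'n_views' must be >= 1")
  if (length(leaf_reflectance) != n_bands ||
      length(background_reflectance) != n_bands)
    stopf("reflectance vectors must have length n_bands = %d", n_bands)
  if (any(leaf_reflectance < 0 | leaf_reflectance > 1) ||
      any(background_reflectance < 0 | background_reflectance > 1))
    stopf("reflectance values must lie in [0, 1]")
  if (material_intensity < 0 || background_intensity < 0)
    stopf("intensities must be nonnegative")
  structure(as.list(environment()), class = "phantom_spec")
}

## Deterministic plant silhouette: stem rectangle + 6 thick leaf polylines
## (quadratic arcs), rasterized on an integer grid. Leaf thickness is solved
## from the area budget, with one corrective pass so the realized pixel count
## lands within the contracted 2% of plant_area_px.
rasterize_silhouette <- function(area_px, height_px, width_px) {
  nr <- ceiling(height_px * 1.12)
  nc <- ceiling(width_px * 1.2)
  cx <- nc / 2
  base <- nr - 2
  stem_w <- max(3, round(0.35 * area_px / height_px))
  leaf_area <- max(area_px - stem_w * height_px, 0.2 * area_px)
  n_leaves <- 6
  # leaf k: starts at stem, height fraction, alternating sides, arc length
  lengths <- (width_px / 2 - stem_w / 2) * c(1, 1, 0.85, 0.85, 0.65, 0.5)
  per_leaf <- leaf_area * lengths / sum(lengths)
  draw <- function(thick_scale) {
    m <- matrix(FALSE, nr, nc)
    # stem
    r0 <- base - height_px + 1
    c0 <- round(cx - stem_w / 2); c1 <- c0 + stem_w - 1
    m[r0:base, c0:c1] <- TRUE
    yy <- matrix(seq_len(nr), nr, nc)
    xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (k in seq_len(n_leaves)) {
      L <- lengths[k]
      # thickness from area budget: L*t + pi*(t/2)^2 = per_leaf
      t <- (-L + sqrt(L^2 + pi * per_leaf[k])) / (pi / 2) * thick_scale
      side <- if (k %% 2 == 1) 1 else -1
      y_attach <- base - height_px * (0.25 + 0.12 * (k - 1))
      # quadratic arc control points (droop outwards)
      s <- seq(0, 1, length.out = 24)
      px <- cx + side * (L * s)
      py <- y_attach - 18 * s + 30 * s^2
      # distance to polyline <= t/2
      box_r <- range(pmax(1, floor(py - t)), pmin(nr, ceiling(py + t)))
      box_c <- range(pmax(1, floor(px - t)), pmin(nc, ceiling(px + t)))
      rr <- box_r[1]:box_r[2]; cc <- box_c[1]:box_c[2]
      d2 <- matrix(Inf, length(rr), length(cc))
      Y <- matrix(rr, length(rr), length(cc))
      X <- matrix(cc, length(rr), length(cc), byrow = TRUE)
      for (i in seq_len(length(s) - 1)) {
        ax <- px[i]; ay <- py[i]; bx <- px[i + 1]; by <- py[i + 1]
        vx <- bx - ax; vy <- by - ay
        vv <- vx^2 + vy^2
        tt <- pmin(pmax(((X - ax) * vx + (Y - ay) * vy) / vv, 0), 1)
        d2 <- pmin(d2, (X - ax - tt * vx)^2 + (Y - ay - tt * vy)^2)
      }
      m[rr, cc] <- m[rr, cc] | (d2 <= (t / 2)^2)
    }
    m
  }
  m <- draw(1)
  got <- sum(m)
  if (abs(got - area_px) / area_px > 0.005) {
    # one corrective pass on leaf thickness
    stem_a <- stem_w * height_px
    scale <- (area_px - stem_a) / max(got - stem_a, 1)
    m <- draw(max(0.2, min(3, scale)))
  }
  m
}

#' Generate a synthetic scan triplet (RGB stack, HSI cube, CT sinogram)
#'
#' Rasterizes a deterministic plant silhouette (stem rectangle plus
#' parameterized leaf arcs, so area/height/width have analytic ground truth),
#' paints it into `n_views` side-view RGB images and one hyperspectral cube,
#' and forward-projects an annulus culm slice into a sinogram via the
#' discrete Radon transform. The ground-truth slice and masks are returned
#' alongside so round-trip accuracy can be measured.
#'
#' @param spec a [phantom_spec()].
#' @return class `scan_set`: list with `rgb` (list of H x W x 3 arrays),
#'   `hsi` (bands x H x W array), `mask` (ground-truth silhouette),
#'   `sinogram` (class `sinogram`), `slice_truth` (ground-truth CT slice),
#'   and `truth` (named list of ground-truth numbers, e.g. `hollow_area`
#'   = pi * inner_radius^2).
#' @export
make_image_phantoms <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- rasterize_silhouette(spec$plant_area_px, spec$plant_height_px,
                               spec$plant_width_px)
  nr <- nrow(mask); nc <- ncol(mask)
  with_seed(spec$seed, {
    # RGB stack: identical silhouette per view (odd views mirrored, which
    # preserves area and width exactly)
    green <- c(0.25, 0.62, 0.22); white <- c(1, 1, 1)
    mk_view <- function(m) {
      img <- array(0, c(nr, nc, 3))
      for (ch in 1:3)
        img[, , ch] <- ifelse(m, green[ch], white[ch]) +
          stats::rnorm(nr * nc, sd = 0.01)
      pmin(pmax(img, 0), 1)
    }
    views <- lapply(seq_len(spec$n_views), function(v)
      mk_view(if (v %% 2 == 0) mask[, rev(seq_len(nc))] else mask))

    # HSI cube on the same silhouette
    cube <- array(0, c(spec$n_bands, nr, nc))
    fg <- which(mask); bg <- which(!mask)
    for (b in seq_len(spec$n_bands)) {
      plane <- matrix(spec$background_reflectance[b], nr, nc)
      plane[fg] <- spec$leaf_reflectance[b]
      cube[b, , ] <- pmax(plane + stats::rnorm(nr * nc, sd = spec$hsi_noise_sd), 0)
    }

    # CT: annulus slice + forward Radon projection
    side <- max(101L, 2L * ceiling(1.35 * spec$culm_outer_radius_px) + 1L)
    if (spec$culm_outer_radius_px >= side / 2 - 1)
      stopf("invalid geometry: culm radius exceeds slice extent")
    ctr <- (side + 1) / 2
    gx <- matrix(seq_len(side) - ctr, side, side)
    gy <- t(gx)
    rad <- sqrt(gx^2 + gy^2)
    slice <- matrix(spec$background_intensity, side, side)
    slice[rad <= spec$culm_outer_radius_px &
            rad >= spec$culm_inner_radius_px] <- spec$material_intensity
    sino <- radon_transform(slice, n_projections = spec$n_projections)

    structure(
      list(rgb = views, hsi = cube, mask = mask, sinogram = sino,
           slice_truth = slice,
           truth = list(
             area_px = sum(mask),
             plant_area_px = spec$plant_area_px,
             height_px = diff(range(which(rowSums(mask) > 0))) + 1,
             width_px = diff(range(which(colSums(mask) > 0))) + 1,
             hollow_area = pi * spec$culm_inner_radius_px^2,
             culm_diameter = 2 * spec$culm_outer_radius_px,
             wall_thickness = spec$culm_outer_radius_px -
               spec$culm_inner_radius_px,
             leaf_reflectance = spec$leaf_reflectance),
           spec = spec),
      class = "scan_set")
  })
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf(paste0("scan_set: %d RGB views (%dx%d), HSI cube %d bands, ",
                     "sinogram %d x %d\n"),
              length(x$rgb), nrow(x$mask), ncol(x$mask), dim(x$hsi)[1],
              nrow(x$sinogram$data), ncol(x$sinogram$data)))
  cat(sprintf("  truth: area %d px, height %d, width %d, hollow area %.0f px^2\n",
              x$truth$area_px, x$truth$height_px, x$truth$width_px,
              x$truth$hollow_area))
  invisible(x)
}

#' Write a scan set to disk (PNG views, TIFF cube and sinogram, manifest)
#'
#' RGB views go out as PNG, the hyperspectral cube as a multi-page TIFF (one
#' page per band), the sinogram and ground-truth slice as 32-bit TIFF, and a
#' plain-text key-value manifest records the seed and ground truth.
#'
#' @param scans a `scan_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scan_set <- function(scans, dir) {
  stopifnot(inherits(scans, "scan_set"))
  if (!requireNamespace("png", quietly = TRUE) ||
      !requireNamespace("tiff", quietly = TRUE))
    stopf("writing scan sets requires the 'png' and 'tiff' packages")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in seq_along(scans$rgb))
    png::writePNG(scans$rgb[[v]], file.path(dir, sprintf("view_%02d.png", v)))
  pages <- lapply(seq_len(dim(scans$hsi)[1]), function(b) scans$hsi[b, , ])
  tiff::writeTIFF(pages, file.path(dir, "cube.tif"), bits.per.sample = 32)
  sino <- scans$sinogram$data
  tiff::writeTIFF(sino / max(max(sino), 1), file.path(dir, "sinogram.tif"),
                  bits.per.sample = 32)
  tru <- scans$truth
  keep <- vapply(tru, function(z) is.numeric(z) && length(z) == 1, logical(1))
  writeLines(c(sprintf("seed=%d", scans$spec$seed),
               sprintf("%s=%s", names(tru)[keep], unlist(tru[keep]))),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
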