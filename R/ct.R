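#' Discrete Radon transform (forward projection)
#'
#' Parallel-beam line integrals of a square image at `n_projections` angles
#' with a fixed angular step (default 1 degree over a full turn, the
#' canonical acquisition here). Each projection is obtained by bilinear
#' resampling of the image on a grid rotated about the image center and
#' summing along the beam direction.
#'
#' @param image square numeric matrix.
#' @param n_projections number of projections (>= 2).
#' @param step angular step in degrees (default 1).
#' @return class `sinogram`: list with `data` (projections x detector bins),
#'   `angles` (degrees), `step`.
#' @export
radon_transform <- function(image, n_projections = 360, step = 1) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  if (n_projections < 2) stopf("need at least 2 projections")
  s <- nrow(image)
  ctr <- (s + 1) / 2
  angles <- (seq_len(n_projections) - 1) * step
  grid <- seq_len(s) - ctr
  X <- matrix(grid, s, s, byrow = TRUE)   # detector coordinate t
  Y <- matrix(grid, s, s)                 # beam coordinate
  sino <- matrix(0, n_projections, s)
  for (a in seq_len(n_projections)) {
    th <- angles[a] * pi / 180
    xs <- X * cos(th) - Y * sin(th) + ctr
    ys <- X * sin(th) + Y * cos(th) + ctr
    sino[a, ] <- colSums(bilinear_sample(image, ys, xs))
  }
  structure(list(data = sino, angles = angles, step = step),
            class = "sinogram")
}

## vectorized bilinear interpolation; out-of-range samples are 0
bilinear_sample <- function(image, r, c) {
  nr <- nrow(image); nc <- ncol(image)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out <- numeric(length(ri))
    out[ok] <- image[cbind(ri[ok], ci[ok])]
    out
  }
  d <- dim(r)
  v <- val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
  dim(v) <- d
  v
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram: %d projections x %d detector bins, step %g deg\n",
              nrow(x$data), ncol(x$data), x$step))
  invisible(x)
}

#' Filtered back-projection reconstruction of a sinogram
#'
#' Classical FBP: each projection is convolved with a ramp (Ram-Lak) filter
#' in the frequency domain (optionally apodized with a Hann window), then
#' back-projected with linear interpolation onto a square grid whose side is
#' the detector-bin count. Angular coverage below 180 degrees triggers a
#' limited-angle warning.
#'
#' @param sinogram a `sinogram` (or bare projections x bins matrix at 1
#'   degree steps).
#' @param filter `"ramp"` (default) or `"hann"`.
#' @return class `ct_slice`: list with `image` (square matrix) and the
#'   reconstruction settings.
#' @export
reconstruct_slice <- function(sinogram, filter = c("ramp", "hann")) {
  filter <- match.arg(filter)
  if (is.matrix(sinogram))
    sinogram <- structure(list(data = sinogram,
                               angles = seq_len(nrow(sinogram)) - 1, step = 1),
                          class = "sinogram")
  p <- sinogram$data
  n_proj <- nrow(p); s <- ncol(p)
  coverage <- diff(range(sinogram$angles)) + sinogram$step
  if (coverage < 180)
    warnf("angular coverage %.0f deg < 180 deg: limited-angle artifacts expected",
          coverage)
  # ramp filter in frequency domain, zero-padded
  L <- 2^ceiling(log2(2 * s))
  freq <- c(seq(0, L / 2), seq(-L / 2 + 1, -1)) / L
  H <- abs(freq)
  if (filter == "hann") H <- H * (0.5 + 0.5 * cos(2 * pi * freq))
  filt <- t(apply(p, 1, function(row) {
    Re(stats::fft(stats::fft(c(row, rep(0, L - s))) * H, inverse = TRUE))[seq_len(s)] / L
  }))
  ctr <- (s + 1) / 2
  grid <- seq_len(s) - ctr
  Xg <- matrix(grid, s, s, byrow = TRUE)
  Yg <- matrix(grid, s, s)
  recon <- matrix(0, s, s)
  for (a in seq_len(n_proj)) {
    th <- sinogram$angles[a] * pi / 180
    tpos <- Xg * cos(th) - Yg * sin(th) + ctr
    i0 <- floor(tpos)
    frac <- tpos - i0
    q <- filt[a, ]
    ok0 <- i0 >= 1 & i0 <= s
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= s
    v <- matrix(0, s, s)
    v[ok0] <- q[i0[ok0]] * (1 - frac[ok0])
    v[ok1] <- v[ok1] + q[i0[ok1] + 1] * frac[ok1]
    recon <- recon + v
  }
  # angular quadrature weight; a full turn covers each line twice
  dup <- if (coverage >= 360 - sinogram$step / 2) 2 else 1
  recon <- recon * (sinogram$step * pi / 180) / dup
  structure(list(image = recon, filter = filter, n_projections = n_proj),
            class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("ct_slice: %d x %d reconstruction (%s filter, %d projections)\n",
              nrow(x$image), ncol(x$image), x$filter, x$n_projections))
  invisible(x)
}

#' Segment the culm cross-section at an intensity threshold
#'
#' Material mask = largest connected component of pixels at or above `tau`;
#' hollow mask = the enclosed sub-threshold region inside that ring (holes
#' of the material component). A threshold above every pixel yields empty
#' masks with a warning.
#'
#' @param slice a `ct_slice` or bare intensity matrix.
#' @param tau intensity threshold.
#' @return list with logical matrices `material` and `hollow`.
#' @export
segment_culm_at_threshold <- function(slice, tau) {
  img <- if (inherits(slice, "ct_slice")) slice$image else slice
  stopifnot(is.matrix(img), is.finite(tau))
  bin <- img >= tau
  if (!any(bin)) {
    warnf("no pixel reaches threshold %g: empty masks", tau)
    return(list(material = bin, hollow = bin))
  }
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  tab <- tabulate(as.integer(lab))
  material <- matrix(as.integer(lab) == which.max(tab), nrow(img), ncol(img))
  filled <- EBImage::fillHull(EBImage::Image(material * 1)) > 0.5
  list(material = material, hollow = matrix(filled, nrow(img)) & !material)
}

#' Names of the 100-trait CT registry
#'
#' Ten culm measures at each of the ten intensity thresholds 100..1000.
#' @param thresholds threshold ladder (default `seq(100, 1000, 100)`).
#' @return character vector (length 100 for the default ladder).
#' @export
ct_trait_names <- function(thresholds = seq(100, 1000, by = 100)) {
  measures <- c("culm_diameter", "hollow_area", "material_area", "total_area",
                "wall_thickness", "outer_perimeter", "hollow_fraction",
                "eccentricity", "mean_material_intensity",
                "hollow_centroid_offset")
  as.vector(vapply(thresholds, function(tau) paste0(measures, "_", tau),
                   character(length(measures))))
}

#' Culm morphometrics at a ladder of intensity thresholds
#'
#' For every threshold tau in the ladder the reconstructed slice is
#' segmented with [segment_culm_at_threshold()] and ten measures are taken:
#' maximal Feret diameter of the material+hollow union (`culm_diameter`),
#' hollow/material/total areas, mean wall thickness over 360 rays from the
#' union centroid, outer perimeter, hollow fraction, eccentricity of the
#' union, mean material intensity, and the offset of the hollow centroid
#' from the union centroid. Thresholds with empty segmentation are
#' missing-coded.
#'
#' @param slice a `ct_slice` (or intensity matrix).
#' @param thresholds intensity ladder (default 100..1000 step 100, giving
#'   the 100-trait registry).
#' @return named numeric vector, `10 * length(thresholds)` entries.
#' @export
extract_ct_traits <- function(slice, thresholds = seq(100, 1000, by = 100)) {
  img <- if (inherits(slice, "ct_slice")) slice$image else slice
  out <- stats::setNames(rep(NA_real_, 10 * length(thresholds)),
                         ct_trait_names(thresholds))
  for (tau in thresholds) {
    seg <- withCallingHandlers(
      segment_culm_at_threshold(img, tau),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!any(seg$material)) next
    union <- seg$material | seg$hollow
    ij <- which(union, arr.ind = TRUE)
    ctr <- colMeans(ij)
    # maximal Feret diameter over hull points (+1 px for pixel extent)
    hull <- ij[grDevices::chull(ij), , drop = FALSE]
    feret <- if (nrow(hull) > 1)
      sqrt(max(as.vector(stats::dist(hull))^2)) + 1 else 1
    # wall thickness over 360 rays from the centroid
    rmax <- max(sqrt((ij[, 1] - ctr[1])^2 + (ij[, 2] - ctr[2])^2)) + 1
    th <- seq(0, 2 * pi, length.out = 361)[-361]
    rs <- seq(0, rmax, by = 0.5)
    rr <- outer(rs, sin(th)) + ctr[1]
    cc <- outer(rs, cos(th)) + ctr[2]
    mat_s <- bilinear_sample(seg$material * 1, rr, cc) > 0.5
    wall <- vapply(seq_along(th), function(k) {
      hit <- which(mat_s[, k])
      if (length(hit) == 0) NA_real_
      else (max(hit) - min(hit)) * 0.5 + 0.5
    }, numeric(1))
    ecc <- if (nrow(ij) >= 3) {
      ev <- eigen(stats::cov(ij), symmetric = TRUE, only.values = TRUE)$values
      if (is.finite(ev[1]) && ev[1] > 0) sqrt(max(0, 1 - ev[2] / ev[1])) else 0
    } else 0
    hollow_off <- if (any(seg$hollow)) {
      hij <- which(seg$hollow, arr.ind = TRUE)
      sqrt(sum((colMeans(hij) - ctr)^2))
    } else 0
    m_area <- sum(seg$material); h_area <- sum(seg$hollow)
    vals <- c(feret, h_area, m_area, m_area + h_area,
              mean(wall, na.rm = TRUE), mask_perimeter(union),
              h_area / (m_area + h_area), ecc, mean(img[seg$material]),
              hollow_off)
    out[paste0(c("culm_diameter", "hollow_area", "material_area",
                 "total_area", "wall_thickness", "outer_perimeter",
                 "hollow_fraction", "eccentricity",
                 "mean_material_intensity", "hollow_centroid_offset"),
               "_", tau)] <- vals
  }
  out
}
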