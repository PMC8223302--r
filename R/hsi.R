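#' Band index to wavelength mapping for the 250-band cube
#'
#' Linear calibration through the two anchor bands of the hyperspectral
#' registry: band 15 at 434 nm and band 233 at 959 nm, i.e.
#' `lambda(b) = 434 + (b - 15) * (959 - 434) / (233 - 15)`. With this map
#' band 136 rounds to 725 nm and band 200 to 880 nm.
#'
#' @param band band index (vectorized), within `1..n_bands`.
#' @param n_bands number of bands on the grid (default 250).
#' @return wavelength(s) in nm.
#' @seealso [wavelength_band()] for the inverse lookup.
#' @export
band_wavelength <- function(band, n_bands = 250) {
  if (any(band < 1 | band > n_bands) || any(band != floor(band)))
    stopf("band index out of range 1..%d", n_bands)
  434 + (band - 15) * (959 - 434) / (233 - 15)
}

#' Nearest band for a wavelength
#' @param nm wavelength(s) in nm; must fall on the grid spanned by bands
#'   `1..n_bands`.
#' @inheritParams band_wavelength
#' @return integer band index (nearest band).
#' @export
wavelength_band <- function(nm, n_bands = 250) {
  b <- round(15 + (nm - 434) * (233 - 15) / (959 - 434))
  if (any(b < 1 | b > n_bands))
    stopf("wavelength outside the %d-band grid (%.0f-%.0f nm)",
          n_bands, band_wavelength(1, n_bands), band_wavelength(n_bands, n_bands))
  as.integer(b)
}

#' Per-band reflectance statistics over plant pixels
#'
#' Computes, for every band `b`, the total reflectance `T_b` (sum over plant
#' pixels) and average reflectance `A_b` (mean over plant pixels) of a
#' hyperspectral cube. If no mask is supplied the plant is segmented on an
#' NDVI-like band contrast (near-infrared vs red band).
#'
#' @param cube bands x height x width reflectance array.
#' @param mask optional logical matrix (or `plant_mask`) of plant pixels with
#'   the cube's spatial dimensions.
#' @param ndvi_threshold segmentation threshold on the NDVI-like index.
#' @return class `spectral_profile`: list with `T`, `A` (length `n_bands`),
#'   `n_pixels`, and `wavelength`.
#' @export
extract_spectral_profile <- function(cube, mask = NULL, ndvi_threshold = 0.2) {
  stopifnot(length(dim(cube)) == 3)
  nb <- dim(cube)[1]
  if (is.null(mask)) {
    nir <- cube[wavelength_band(800, nb), , ]
    red <- cube[wavelength_band(670, nb), , ]
    ndvi <- (nir - red) / (nir + red + 1e-12)
    if (diff(range(ndvi)) < 1e-6)
      warnf("degenerate contrast: NDVI-like index is constant, segmentation failed")
    mask <- ndvi > ndvi_threshold
  }
  if (inherits(mask, "plant_mask")) mask <- mask$mask
  if (!all(dim(mask) == dim(cube)[2:3]))
    stopf("mask dimensions do not match the cube's spatial dimensions")
  fg <- which(mask)
  if (length(fg) == 0) stopf("no plant pixels")
  flat <- matrix(cube, nb, prod(dim(cube)[2:3]))
  Tb <- rowSums(flat[, fg, drop = FALSE])
  structure(list(T = Tb, A = Tb / length(fg), n_pixels = length(fg),
                 wavelength = band_wavelength(seq_len(nb), nb)),
            class = "spectral_profile")
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf("spectral_profile: %d bands over %d plant pixels (A range %.3f-%.3f)\n",
              length(x$A), x$n_pixels, min(x$A), max(x$A)))
  invisible(x)
}

#' The 2000-trait hyperspectral registry of one scan
#'
#' Eight families over the 250 bands: total reflectance `T`, average
#' reflectance `A`, their base-10 logarithms `lgT`/`lgA` (missing-coded where
#' the argument is nonpositive), first derivatives `dT`/`dA` (central finite
#' differences over band index, one-sided at the ends), and second
#' derivatives `ddT`/`ddA`. Derivatives are taken with respect to band index
#' with unit step; since the wavelength grid is equally spaced this is
#' proportional to the per-nm derivative. Names follow the `dT233` / `lgA15`
#' convention (family then band index).
#'
#' @param profile a [extract_spectral_profile()] result.
#' @return named numeric vector of length `8 * n_bands` (2000 for the
#'   default grid).
#' @export
extract_hsi_traits <- function(profile) {
  stopifnot(inherits(profile, "spectral_profile"))
  d1 <- function(x) {
    n <- length(x)
    c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
  }
  d2 <- function(x) {
    n <- length(x)
    c(x[1] - 2 * x[2] + x[3], x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)],
      x[n - 2] - 2 * x[n - 1] + x[n])
  }
  lg <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & x > 0
    out[ok] <- log10(x[ok])
    out
  }
  fam <- list(T = profile$T, A = profile$A,
              lgT = lg(profile$T), lgA = lg(profile$A),
              dT = d1(profile$T), dA = d1(profile$A),
              ddT = d2(profile$T), ddA = d2(profile$A))
  nb <- length(profile$T)
  out <- unlist(fam, use.names = FALSE)
  names(out) <- unlist(lapply(names(fam), function(f) paste0(f, seq_len(nb))))
  out
}

#' Names of the hyperspectral trait registry
#' @param n_bands number of bands (default 250).
#' @return character vector of length `8 * n_bands`.
#' @export
hsi_trait_names <- function(n_bands = 250)
  unlist(lapply(c("T", "A", "lgT", "lgA", "dT", "dA", "ddT", "ddA"),
                function(f) paste0(f, seq_len(n_bands))))
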