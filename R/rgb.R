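#' Segment the plant silhouette in a side-view color image
#'
#' Excess-green thresholding (`2G - R - B`) with an Otsu-selected cut,
#' followed by a 3x3 morphological opening and largest-connected-component
#' selection. Degenerate contrast (no green/background separation) yields an
#' empty mask with a warning, never an error.
#'
#' @param view H x W x 3 numeric array with values in `[0, 1]`.
#' @param min_exg minimum excess-green separation required between the two
#'   Otsu classes before the image is declared degenerate.
#' @param clean apply the morphological opening (default `TRUE`).
#' @return class `plant_mask`: list with `mask` (logical matrix), `area_px`,
#'   and `view` (index, filled by callers that know it).
#' @export
segment_plant <- function(view, min_exg = 0.05, clean = TRUE) {
  stopifnot(length(dim(view)) == 3, dim(view)[3] >= 3)
  exg <- 2 * view[, , 2] - view[, , 1] - view[, , 3]
  rng <- range(exg)
  empty <- function(msg) {
    warnf(msg)
    structure(list(mask = matrix(FALSE, nrow(exg), ncol(exg)),
                   area_px = 0L, view = NA_integer_), class = "plant_mask")
  }
  if (diff(rng) < 1e-6)
    return(empty("degenerate contrast: excess-green index is constant; empty mask returned"))
  scaled <- (exg - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mask <- scaled > thr
  if (mean(exg[mask]) - mean(exg[!mask]) < min_exg || !any(mask))
    return(empty("degenerate contrast: foreground indistinguishable by greenness; empty mask returned"))
  if (clean) {
    kern <- EBImage::makeBrush(3, shape = "box")
    mask <- EBImage::opening(EBImage::Image(mask * 1), kern) > 0.5
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(as.integer(lab))
  if (length(tab) == 0 || max(tab) == 0)
    return(empty("no plant pixels survive morphological cleanup; empty mask returned"))
  mask <- matrix(as.integer(lab) == which.max(tab), nrow(exg), ncol(exg))
  structure(list(mask = mask, area_px = sum(mask), view = NA_integer_),
            class = "plant_mask")
}

#' @export
print.plant_mask <- function(x, ...) {
  cat(sprintf("plant_mask: %d px foreground in %d x %d image\n",
              x$area_px, nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

mask_width <- function(mask) {
  cols <- which(colSums(mask) > 0)
  if (length(cols) == 0) 0L else diff(range(cols)) + 1L
}
mask_height <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  if (length(rows) == 0) 0L else diff(range(rows)) + 1L
}

#' Select the maximum-width side view of an RGB scan
#'
#' Each view is segmented and the view whose silhouette has the largest
#' horizontal extent is returned; ties break to the lowest index. The
#' geometric traits of the scan are computed on this view.
#'
#' @param scan a `scan_set`, or a plain list of H x W x 3 view arrays.
#' @return integer view index.
#' @export
select_max_width_view <- function(scan) {
  views <- if (inherits(scan, "scan_set")) scan$rgb else scan
  if (length(views) < 1) stopf("scan has no views")
  widths <- vapply(views, function(v)
    mask_width(suppressWarnings(segment_plant(v))$mask), numeric(1))
  if (all(widths == 0)) stopf("no plant detected in any view")
  which.max(widths)  # which.max breaks ties at the lowest index
}

#' Names of the 67-trait RGB registry
#'
#' 15 geometry/architecture traits, 12 color summaries, and 40 hue-histogram
#' bin fractions.
#' @return character vector of length 67.
#' @export
rgb_trait_names <- function() {
  c("TPA", "plant_height", "plant_width", "height_width_ratio", "hull_area",
    "solidity", "perimeter", "bbox_fill", "centroid_height_frac",
    "top_area_frac", "compactness", "extent_left", "extent_right",
    "skeleton_length", "stem_width",
    paste0(rep(c("mean_", "sd_"), 6),
           rep(c("R", "G", "B", "hue", "sat", "val"), each = 2)),
    sprintf("hue_bin_%02d", 1:40))
}

## boundary edge count: number of foreground pixel edges facing background
mask_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  sum(core & !pad[1:nr, 2:(nc + 1)]) + sum(core & !pad[3:(nr + 2), 2:(nc + 1)]) +
    sum(core & !pad[2:(nr + 1), 1:nc]) + sum(core & !pad[2:(nr + 1), 3:(nc + 2)])
}

## convex hull area over pixel corners, so a filled rectangle has
## hull_area == area and solidity exactly 1
hull_area_px <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  pts <- rbind(cbind(idx[, 1] - 0.5, idx[, 2] - 0.5),
               cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
               cbind(idx[, 1] + 0.5, idx[, 2] - 0.5),
               cbind(idx[, 1] + 0.5, idx[, 2] + 0.5))
  h <- grDevices::chull(pts)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## Zhang-Suen thinning; returns skeleton pixel count as a length proxy
skeleton_length_px <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  if (sum(m) == 0) return(0)
  nb <- function(m) {
    p <- matrix(FALSE, nr + 2, nc + 2); p[2:(nr + 1), 2:(nc + 1)] <- m
    list(p2 = p[1:nr, 2:(nc + 1)],     p3 = p[1:nr, 3:(nc + 2)],
         p4 = p[2:(nr + 1), 3:(nc + 2)], p5 = p[3:(nr + 2), 3:(nc + 2)],
         p6 = p[3:(nr + 2), 2:(nc + 1)], p7 = p[3:(nr + 2), 1:nc],
         p8 = p[2:(nr + 1), 1:nc],      p9 = p[1:nr, 1:nc])
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      q <- nb(m)
      B <- q$p2 + q$p3 + q$p4 + q$p5 + q$p6 + q$p7 + q$p8 + q$p9
      seqs <- list(q$p2, q$p3, q$p4, q$p5, q$p6, q$p7, q$p8, q$p9, q$p2)
      A <- Reduce(`+`, lapply(1:8, function(i) (!seqs[[i]]) & seqs[[i + 1]]))
      cond <- m & B >= 2 & B <= 6 & A == 1
      cond <- cond & if (pass == 1) !(q$p2 & q$p4 & q$p6) & !(q$p4 & q$p6 & q$p8)
                     else            !(q$p2 & q$p4 & q$p8) & !(q$p2 & q$p6 & q$p8)
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  sum(m)
}

#' Extract the 67-trait RGB registry from a side-view scan
#'
#' Geometric traits are computed on the maximum-width view's silhouette;
#' color traits over its plant pixels. With an empty plant (nothing
#' segmentable in any view) all geometric traits are 0 and color traits are
#' missing-coded.
#'
#' @param scan a `scan_set` or list of H x W x 3 view arrays.
#' @param mm_per_px optional calibration; lengths scale by it and areas by
#'   its square (default 1 = pixel units).
#' @return named numeric vector of length 67 (see [rgb_trait_names()]).
#' @export
extract_rgb_traits <- function(scan, mm_per_px = 1) {
  views <- if (inherits(scan, "scan_set")) scan$rgb else scan
  nms <- rgb_trait_names()
  idx <- tryCatch(select_max_width_view(views), error = function(e) NA_integer_)
  if (is.na(idx)) {
    out <- c(rep(0, 15), rep(NA_real_, 52))
    names(out) <- nms
    return(out)
  }
  view <- views[[idx]]
  pm <- suppressWarnings(segment_plant(view))
  mask <- pm$mask
  area <- sum(mask)
  rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
  h <- diff(range(rows)) + 1; w <- diff(range(cols)) + 1
  ij <- which(mask, arr.ind = TRUE)
  centroid_r <- mean(ij[, 1]); centroid_c <- mean(ij[, 2])
  hull <- hull_area_px(mask)
  per <- mask_perimeter(mask)
  top_half <- sum(ij[, 1] <= min(rows) + h / 2 - 0.5)
  # stem column: median column of the bottom rows
  bottom <- ij[ij[, 1] >= max(rows) - max(1, round(0.1 * h)) + 1, , drop = FALSE]
  stem_c <- stats::median(bottom[, 2])
  widths_bottom <- tapply(bottom[, 2], bottom[, 1], function(z) diff(range(z)) + 1)
  geo <- c(
    TPA = area * mm_per_px^2,
    plant_height = h * mm_per_px,
    plant_width = w * mm_per_px,
    height_width_ratio = h / w,
    hull_area = hull * mm_per_px^2,
    solidity = if (hull > 0) min(area / hull, 1) else 0,
    perimeter = per * mm_per_px,
    bbox_fill = area / (h * w),
    centroid_height_frac = (max(rows) - centroid_r) / max(h - 1, 1),
    top_area_frac = top_half / area,
    compactness = 4 * pi * area / per^2,
    extent_left = (stem_c - min(cols)) * mm_per_px,
    extent_right = (max(cols) - stem_c) * mm_per_px,
    skeleton_length = skeleton_length_px(mask) * mm_per_px,
    stem_width = stats::median(widths_bottom) * mm_per_px)
  r <- view[, , 1][mask]; g <- view[, , 2][mask]; b <- view[, , 3][mask]
  hsv <- grDevices::rgb2hsv(rbind(r, g, b) * 255, maxColorValue = 255)
  col <- c(mean_R = mean(r), sd_R = stats::sd(r),
           mean_G = mean(g), sd_G = stats::sd(g),
           mean_B = mean(b), sd_B = stats::sd(b),
           mean_hue = mean(hsv[1, ]), sd_hue = stats::sd(hsv[1, ]),
           mean_sat = mean(hsv[2, ]), sd_sat = stats::sd(hsv[2, ]),
           mean_val = mean(hsv[3, ]), sd_val = stats::sd(hsv[3, ]))
  bins <- tabulate(pmin(floor(hsv[1, ] * 40) + 1, 40), nbins = 40) / area
  names(bins) <- sprintf("hue_bin_%02d", 1:40)
  out <- c(geo, col, bins)
  names(out) <- nms
  out
}
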