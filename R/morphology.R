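#' Posterior area and mean intensity in a single slice
#'
#' The posterior area is the number of pixels in the ROI and the intensity is
#' the arithmetic mean of the image over the ROI, both evaluated on a single
#' Z slice.
#'
#' @param image 2D numeric matrix.
#' @param posterior_roi 2D mask, same dimensions.
#' @return list with `area_px` and `mean_intensity`.
#' @export
posterior_area_intensity <- function(image, posterior_roi) {
  if (!all(dim(image) == dim(posterior_roi))) stop("image/roi dimensions differ")
  roi <- posterior_roi > 0
  if (!any(roi)) stop("posterior roi is empty")
  list(area_px = sum(roi), mean_intensity = mean(image[roi]))
}

## Boundary length of a binary mask: marching-squares contour at the 0.5
## iso-level of the (optionally Gaussian-smoothed) mask. Smoothing with
## sigma ~ 1 px removes the staircase bias of raw binary contours, which
## otherwise overestimates the perimeter of smooth shapes by ~8-10%.
mask_perimeter <- function(mask, sigma = 1) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  pad <- max(4, ceiling(3 * sigma))
  mp <- matrix(0, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  mp[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  if (sigma > 0) mp <- as.matrix(EBImage::gblur(mp, sigma = sigma))
  cl <- grDevices::contourLines(x = seq_len(nrow(mp)), y = seq_len(ncol(mp)),
                                z = mp, levels = 0.5)
  if (length(cl) == 0) stop("no 0.5 iso-contour found: mask too small")
  sum(vapply(cl, function(s) sum(sqrt(diff(s$x)^2 + diff(s$y)^2)), numeric(1)))
}

#' Circularity of a segmented region
#'
#' Circularity = 4 * pi * A / P^2, with A the pixel count of the region and
#' P its estimated boundary length. A perfect circle gives 1; elongated or
#' irregular shapes give smaller values. The boundary length is measured as
#' the marching-squares contour of the Gaussian-smoothed mask at the 0.5
#' iso-level (`sigma = 1` px by default; `sigma = 0` gives the raw binary
#' contour, which overestimates P for smooth shapes).
#'
#' @param mask 2D mask of a single connected region with at least 4 pixels.
#' @param sigma smoothing SD (pixels) for the perimeter estimate.
#' @return circularity (dimensionless).
#' @seealso [circularity_value()] for the bare formula.
#' @export
circularity <- function(mask, sigma = 1) {
  m <- mask > 0
  a <- sum(m)
  if (a < 4) stop("region smaller than 4 pixels: circularity unreliable")
  lab <- label_components(m)
  if (max(lab) != 1) stop("region must be a single connected component")
  circularity_value(a, mask_perimeter(m, sigma))
}

#' Circularity from area and perimeter
#'
#' The bare shape formula `4 * pi * A / P^2`, for analytic shapes or
#' externally measured area/perimeter pairs.
#'
#' @param area region area.
#' @param perimeter region boundary length (same length unit as `sqrt(area)`).
#' @return circularity (dimensionless).
#' @export
circularity_value <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0)) {
    stop("area and perimeter must be positive")
  }
  4 * pi * area / perimeter^2
}

#' Membrane-to-cytoplasm intensity ratio
#'
#' Mean intensity over the membrane compartment (erosion-subtracted rim)
#' divided by the mean over the cytoplasm compartment (eroded core) of the
#' same cell mask; used e.g. for junctional-adhesion localization readouts.
#'
#' @param image 2D or 3D intensity data.
#' @param cell_mask mask of the cell, same dimensions.
#' @param erosion_radius_px erosion passes defining the rim width.
#' @param element structuring element, `"2d"` (default) or `"3d"`.
#' @return fold ratio (dimensionless).
#' @export
membrane_to_cytoplasm_ratio <- function(image, cell_mask, erosion_radius_px = 2,
                                        element = c("2d", "3d")) {
  element <- match.arg(element)
  parts <- membrane_cytoplasm_split(cell_mask, erosion_radius_px, element)
  cyt <- mean(image[parts$cytoplasm])
  if (cyt == 0) stop("cytoplasm mean intensity is zero: ratio undefined")
  mean(image[parts$membrane]) / cyt
}

#' Normalize a time course to its first or maximum value
#'
#' @param series numeric vector.
#' @param mode `"first"` or `"max"`.
#' @return `series` divided elementwise by the reference value.
#' @export
normalize_timecourse <- function(series, mode = c("first", "max")) {
  mode <- match.arg(mode)
  if (length(series) == 0) stop("series is empty")
  ref <- switch(mode, first = series[1], max = max(series, na.rm = TRUE))
  if (!is.finite(ref) || ref == 0) {
    stop("reference value is zero or undefined: cannot normalize")
  }
  series / ref
}
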