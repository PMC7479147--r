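#' Refine a coarse ROI by automatic thresholding
#'
#' Refines a manually drawn region by thresholding the intensities inside it
#' at the level that minimizes intra-class variance (the Otsu criterion,
#' evaluated on a 256-bin histogram spanning the ROI's own intensity range)
#' and keeping the largest connected above-threshold component. The result
#' is always a subset of the input ROI. Works on 2D images (4-connected
#' components) and 3D volumes (6-connected).
#'
#' @param image numeric matrix (Y, X) or 3D array (Z, Y, X).
#' @param roi logical/0-1 mask of the same dimensions.
#' @param levels number of candidate thresholds (histogram bins).
#' @return integer mask (same dimensions, 1 = refined segmentation) with the
#'   chosen threshold in attribute `"threshold"`.
#' @export
refine_roi_threshold <- function(image, roi, levels = 256) {
  if (!all(dim(image) == dim(roi))) stop("image and roi dimensions differ")
  roi <- roi > 0
  vals <- image[roi]
  if (length(vals) == 0) stop("roi is empty")
  if (length(unique(vals)) < 2) {
    stop("degenerate histogram: roi holds fewer than 2 distinct intensities")
  }
  thr <- otsu_threshold(vals, levels = levels)
  cand <- image > thr & roi
  if (!any(cand)) stop("no voxels above the Otsu threshold inside the roi")
  lab <- label_components(cand)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  out <- array(0L, dim(image))
  out[lab == keep] <- 1L
  attr(out, "threshold") <- thr
  out
}

## Otsu's threshold over the 256 candidate cuts spanning range(vals): the
## returned threshold is the bin edge maximizing between-class variance
## (equivalently minimizing the total intra-class variance). Class statistics
## use the raw intensity values, not bin midpoints, so the optimum is exact
## with respect to the candidate grid.
otsu_threshold <- function(vals, levels = 256) {
  rng <- range(vals)
  edges <- seq(rng[1], rng[2], length.out = levels + 1)
  bin <- findInterval(vals, edges, rightmost.closed = TRUE, all.inside = TRUE)
  n <- tabulate(bin, nbins = levels)
  s <- numeric(levels)
  sums <- tapply(vals, bin, sum)
  s[as.integer(names(sums))] <- sums
  cn <- cumsum(n); cs <- cumsum(s)
  N <- cn[levels]; S <- cs[levels]
  k <- seq_len(levels - 1)
  w1 <- cn[k]; w2 <- N - w1
  sb2 <- ifelse(w1 > 0 & w2 > 0,
                (S * w1 - N * cs[k])^2 / (w1 * w2), -Inf)
  edges[which.max(sb2) + 1]
}

## Connected-component labelling: EBImage::bwlabel (4-connected) in 2D;
## 6-connected iterative label propagation in 3D (no installed package
## offers 3D labelling).
label_components <- function(mask) {
  mask <- mask > 0
  if (length(dim(mask)) == 2 || is.null(dim(mask))) {
    m <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
    return(matrix(as.integer(m), nrow(mask), ncol(mask)))
  }
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  shift_min <- function(a, ax, by) {
    out <- array(Inf, d)
    idx_src <- idx_dst <- lapply(d, seq_len)
    if (by > 0) { idx_dst[[ax]] <- (1 + by):d[ax]; idx_src[[ax]] <- 1:(d[ax] - by) }
    else        { idx_dst[[ax]] <- 1:(d[ax] + by); idx_src[[ax]] <- (1 - by):d[ax] }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  work <- lab
  work[!mask] <- Inf
  repeat {
    nb <- work
    for (ax in 1:3) for (by in c(-1, 1)) nb <- pmin(nb, shift_min(work, ax, by))
    nb[!mask] <- Inf
    if (all(nb[mask] == work[mask])) break
    work <- nb
  }
  out <- array(0L, d)
  out[mask] <- as.integer(match(work[mask], sort(unique(work[mask]))))
  out
}

#' Centroid of a label mask in physical coordinates
#'
#' The unweighted mean of all labeled voxel coordinates (0-based voxel-centre
#' convention), scaled by the voxel spacing.
#'
#' @param mask 2D or 3D mask (non-zero = segmented).
#' @param spacing voxel spacing in µm: `(z, y, x)` for volumes, `(y, x)` for
#'   2D masks.
#' @return centroid in µm, named `(z, y, x)` (or `(y, x)`).
#' @export
cluster_centroid <- function(mask, spacing = NULL) {
  nd <- length(dim(mask))
  if (is.null(spacing)) spacing <- rep(1, nd)
  if (length(spacing) != nd) stop("spacing length must match mask dimensions")
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty: centroid undefined")
  ctr <- colMeans(idx_to_um(idx, spacing))
  names(ctr) <- if (nd == 3) c("z", "y", "x") else c("y", "x")
  ctr
}

## Binary erosion with a 3x3 (2D) or 3x3x3 (3D) box, applied `radius` times.
## 2D uses EBImage; 3D uses a separable min-filter.
erode_mask <- function(mask, radius = 2, element = c("2d", "3d")) {
  element <- match.arg(element)
  if (radius < 0) stop("erosion radius must be >= 0")
  if (radius == 0) return(mask > 0)
  nd <- length(dim(mask))
  if (nd == 2) {
    m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
    brush <- EBImage::makeBrush(3, shape = "box")
    for (i in seq_len(radius)) m <- EBImage::erode(m, brush)
    return(m > 0)
  }
  m <- (mask > 0) * 1
  d <- dim(m)
  axes <- if (element == "3d") 1:3 else 2:3
  min3 <- function(a, ax) {
    lo <- hi <- a
    idx <- lapply(d, seq_len)
    il <- idx; il[[ax]] <- c(1, seq_len(d[ax] - 1))
    ih <- idx; ih[[ax]] <- c(seq_len(d[ax] - 1) + 1, d[ax])
    lo <- a[il[[1]], il[[2]], il[[3]], drop = FALSE]; dim(lo) <- d
    hi <- a[ih[[1]], ih[[2]], ih[[3]], drop = FALSE]; dim(hi) <- d
    ## border voxels erode away (outside counts as background)
    bl <- idx; bl[[ax]] <- 1; bh <- idx; bh[[ax]] <- d[ax]
    lo[bl[[1]], bl[[2]], bl[[3]]] <- 0
    hi[bh[[1]], bh[[2]], bh[[3]]] <- 0
    pmin(a, lo, hi)
  }
  if (element == "2d") {
    ## per-slice 2D erosion must not erode across z; handled by axes = 2:3
  }
  for (i in seq_len(radius)) for (ax in axes) m <- min3(m, ax)
  m > 0
}

#' Split a cell mask into membrane and cytoplasm compartments
#'
#' Erodes the cell segmentation and subtracts it from the original: the
#' eroded core is the cytoplasm compartment and the subtracted rim the
#' membrane compartment. The two regions partition the input mask.
#'
#' @param cell_mask 2D or 3D cell mask.
#' @param erosion_radius_px number of 1-pixel erosion passes (3x3 box).
#' @param element `"2d"` (per-slice, default) or `"3d"` (3x3x3 box) for
#'   volumetric masks.
#' @return list with logical masks `membrane` and `cytoplasm`.
#' @export
membrane_cytoplasm_split <- function(cell_mask, erosion_radius_px = 2,
                                     element = c("2d", "3d")) {
  element <- match.arg(element)
  cell <- cell_mask > 0
  if (!any(cell)) stop("cell mask is empty")
  cyto <- erode_mask(cell, erosion_radius_px, element)
  if (!any(cyto)) {
    stop(sprintf("object too thin: erosion radius %d annihilates the mask",
                 erosion_radius_px))
  }
  list(membrane = cell & !cyto, cytoplasm = cyto)
}

#' Peripheral (cortical) rim of a cell mask
#'
#' The membrane compartment of [membrane_cytoplasm_split()]: the pixels
#' removed by `erosion_radius_px` erosion passes.
#'
#' @inheritParams membrane_cytoplasm_split
#' @return logical mask of the periphery.
#' @export
periphery_mask <- function(cell_mask, erosion_radius_px = 2,
                           element = c("2d", "3d")) {
  membrane_cytoplasm_split(cell_mask, erosion_radius_px, element)$membrane
}
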