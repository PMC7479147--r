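#' Parameters for cortical-polarity quantification
#'
#' Houses the cut-offs used throughout the polarity workflow: a polarized
#' region must be at least `ratio_threshold`-fold brighter than cytoplasm,
#' automatic detection keeps connected periphery regions larger than
#' `min_region_px` pixels that exceed the cell mean by `sd_threshold`
#' standard deviations, a reorientation event is an angular shift greater
#' than `reorientation_deg`, and the posterior compartment is the lowest
#' `posterior_fraction` of segmented rows after rotation.
#'
#' @param ratio_threshold fold-intensity criterion for calling a region
#'   polarized (default 1.2).
#' @param sd_threshold SD multiple above the cell mean for candidate pixels
#'   (default 1.5).
#' @param min_region_px minimum connected-region size in pixels; regions must
#'   be strictly larger (default 10).
#' @param reorientation_deg angular-shift threshold in degrees (default 60).
#' @param posterior_fraction fraction of segmented rows defining the
#'   posterior (default 0.20).
#' @param erosion_radius_px erosion passes isolating the cell periphery.
#' @return list of class `polarity_params`.
#' @export
polarity_params <- function(ratio_threshold = 1.2, sd_threshold = 1.5,
                            min_region_px = 10, reorientation_deg = 60,
                            posterior_fraction = 0.20, erosion_radius_px = 2) {
  stopifnot_positive(ratio_threshold = ratio_threshold,
                     sd_threshold = sd_threshold,
                     min_region_px = min_region_px,
                     reorientation_deg = reorientation_deg,
                     posterior_fraction = posterior_fraction,
                     erosion_radius_px = erosion_radius_px)
  if (posterior_fraction >= 1) stop("posterior_fraction must lie in (0, 1)")
  structure(as.list(environment()), class = "polarity_params")
}

#' Polarized-to-cytoplasm intensity ratio
#'
#' Ratio of the mean intensity in a polarized-region ROI to the mean in a
#' cytoplasm ROI of the same cell, with the `>= ratio_threshold` criterion
#' evaluated alongside.
#'
#' @param image image or volume covering both ROIs.
#' @param polarized_roi,cytoplasm_roi masks with the same dimensions as
#'   `image`.
#' @param params a [polarity_params()].
#' @return list with `ratio` (fold) and `meets_threshold` (logical).
#' @export
polarity_ratio <- function(image, polarized_roi, cytoplasm_roi,
                           params = polarity_params()) {
  if (!any(polarized_roi > 0) || !any(cytoplasm_roi > 0)) {
    stop("both ROIs must be non-empty")
  }
  cyt <- mean(image[cytoplasm_roi > 0])
  if (cyt == 0) stop("cytoplasm mean intensity is zero: ratio undefined")
  r <- mean(image[polarized_roi > 0]) / cyt
  list(ratio = r, meets_threshold = r >= params$ratio_threshold)
}

#' Automatic detection of a polarized cortical region
#'
#' On a 2D image (single slice or maximum-intensity projection), isolates the
#' cell periphery by erosion-subtraction, flags periphery pixels brighter
#' than the whole-cell mean plus `sd_threshold` standard deviations, and
#' keeps 4-connected components larger than `min_region_px` pixels. If
#' several qualify, the component with the greatest total intensity wins
#' (ties broken by lowest centroid row, then column). No qualifying region
#' is a valid outcome (`NULL`), mirroring frames where no polarity exists.
#'
#' @param image 2D numeric matrix (Y, X).
#' @param cell_mask 2D mask of the cell.
#' @param params a [polarity_params()].
#' @return `NULL` when undetected, else list with `region` (logical mask),
#'   `centroid_px` (0-based `(y, x)` pixel centroid), and `total_intensity`.
#' @export
detect_polarized_region <- function(image, cell_mask,
                                    params = polarity_params()) {
  cell <- cell_mask > 0
  if (!any(cell)) stop("cell mask is empty")
  peri <- periphery_mask(cell, params$erosion_radius_px)
  if (!any(peri)) stop("cell periphery is empty after erosion")
  mu <- mean(image[cell])
  sdv <- stats::sd(image[cell])
  cand <- peri & image > mu + params$sd_threshold * sdv
  if (!any(cand)) return(NULL)
  lab <- label_components(cand)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes > params$min_region_px)
  if (length(keep) == 0) return(NULL)
  totals <- vapply(keep, function(k) sum(image[lab == k]), numeric(1))
  best <- keep[totals == max(totals)]
  if (length(best) > 1) {  # deterministic tie-break: lowest row, then column
    cents <- t(vapply(best, function(k) {
      colMeans(which(lab == k, arr.ind = TRUE))
    }, numeric(2)))
    best <- best[order(cents[, 1], cents[, 2])[1]]
  }
  region <- lab == best
  ctr <- colMeans(which(region, arr.ind = TRUE)) - 1  # 0-based pixel centre
  names(ctr) <- c("y", "x")
  list(region = region, centroid_px = ctr,
       total_intensity = sum(image[region]))
}

#' Orientation angle between a polarity axis and a reference axis
#'
#' Angle in degrees between the vector from the cell point (nucleus or
#' centroid) to the polarized-region centroid and the vector from the cell
#' point to the reference point (e.g. the endoderm/cluster centre), in
#' `[0, 180]`.
#'
#' @param cell_point,region_centroid,reference_point numeric coordinates of
#'   matching length (2D or 3D), in a common space.
#' @return angle in degrees.
#' @export
orientation_angle <- function(cell_point, region_centroid, reference_point) {
  v1 <- region_centroid - cell_point
  v2 <- reference_point - cell_point
  if (vnorm(v1) == 0 || vnorm(v2) == 0) {
    stop("undefined orientation: zero-length vector")
  }
  acos_deg(sum(v1 * v2) / (vnorm(v1) * vnorm(v2)))
}

#' Count reorientation events in an orientation time series
#'
#' One event is scored for each consecutive pair of detected frames whose
#' absolute orientation change exceeds `threshold_deg`. Undetected frames
#' (`NA`) form gaps; by default the first detected value after a gap is
#' compared with the last detected value before it (`across_gaps = TRUE`),
#' otherwise pairs spanning a gap are skipped.
#'
#' @param angles numeric vector of per-frame orientation angles (degrees),
#'   `NA` = no polarity detected.
#' @param threshold_deg event threshold (default 60).
#' @param across_gaps compare across undetected gaps (default `TRUE`).
#' @return integer event count.
#' @export
reorientation_events <- function(angles, threshold_deg = 60,
                                 across_gaps = TRUE) {
  det <- which(!is.na(angles))
  if (length(det) < 2) {
    stop("need at least 2 detected frames to count reorientation events")
  }
  if (across_gaps) {
    vals <- angles[det]
    sum(abs(diff(vals)) > threshold_deg)
  } else {
    adj <- diff(det) == 1
    sum(abs(diff(angles[det]))[adj] > threshold_deg)
  }
}

## Rotate a 2D image so that the direction dir_yx = (dy, dx) maps to "down"
## (increasing row index). Intensity is interpolated bilinearly, masks use
## nearest neighbour; both share one output geometry.
rotate_to_down <- function(image, mask, dir_yx) {
  if (vnorm(dir_yx) == 0) stop("posterior direction must be non-zero")
  ang <- -atan2(dir_yx[2], dir_yx[1]) * 180 / pi
  img_r <- EBImage::rotate(image, ang, filter = "bilinear")
  msk_r <- EBImage::rotate(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)),
                           ang, filter = "none")
  list(image = as.matrix(img_r), mask = as.matrix(msk_r) > 0.5,
       angle_deg = ang)
}

#' Posterior intensity time course
#'
#' For each frame the cell image and mask are rotated in-plane so the given
#' posterior direction points down; the rows containing mask pixels are
#' counted, the lowest `posterior_fraction` of them (`ceiling`) define the
#' posterior compartment, and the mean intensity over posterior mask pixels
#' is returned. Cells spanning fewer than 5 rows trigger a warning and use
#' the single lowest row.
#'
#' @param frames list of per-frame `list(image, mask)` pairs (2D, the Z
#'   plane or projection carrying the polarity signal).
#' @param posterior_direction either one `(dy, dx)` vector used for all
#'   frames or a list of per-frame vectors (need not be unit length).
#' @param params a [polarity_params()].
#' @return numeric vector of per-frame posterior mean intensities.
#' @export
posterior_intensity_timecourse <- function(frames, posterior_direction,
                                           params = polarity_params()) {
  nT <- length(frames)
  if (nT == 0) stop("no frames")
  dirs <- if (is.list(posterior_direction)) posterior_direction
          else rep(list(posterior_direction), nT)
  if (length(dirs) != nT) stop("need one posterior direction per frame")
  vapply(seq_len(nT), function(t) {
    fr <- frames[[t]]
    rot <- rotate_to_down(fr$image, fr$mask, dirs[[t]])
    rows <- which(rowSums(rot$mask) > 0)
    if (length(rows) == 0) stop("mask vanished after rotation at frame ", t)
    if (length(rows) < 5) {
      warning("cell spans fewer than 5 rows at frame ", t,
              ": using the single lowest row")
      post_rows <- rows[length(rows)]
    } else {
      k <- ceiling(params$posterior_fraction * length(rows))
      post_rows <- rows[(length(rows) - k + 1):length(rows)]
    }
    sel <- rot$mask
    sel[setdiff(seq_len(nrow(sel)), post_rows), ] <- FALSE
    mean(rot$image[sel])
  }, numeric(1))
}

#' Per-cell polarity time course
#'
#' Composes automatic region detection, the intensity ratio, and the
#' orientation angle frame by frame for each tracked cell: the reporter
#' channel is reduced to 2D (maximum-intensity projection by default, or a
#' fixed slice), the polarized cortical region is detected, its ratio to the
#' eroded-cytoplasm signal computed, and its orientation measured at the
#' cell centroid relative to the reference point.
#'
#' @param mov a [movie()].
#' @param label_movie integer label array (T, Z, Y, X) assigning voxels to
#'   cells.
#' @param reference_um reference point `(y, x)` in µm (e.g. the projected
#'   cluster or endoderm centre).
#' @param params a [polarity_params()].
#' @param channel reporter channel name or index.
#' @param cells cell labels to analyse (default: all labels in frame 1).
#' @param view `"projection"` (max-intensity projection, default),
#'   `"best_slice"` (per cell and frame, the Z plane with the greatest total
#'   reporter intensity inside the cell mask), or `"slice"` with `slice_z`
#'   giving a fixed plane.
#' @param slice_z Z plane used when `view = "slice"`.
#' @return data frame of per-cell per-frame records: `cell`, `frame`,
#'   `detected`, `ratio`, `orientation_deg`, `region_y_um`, `region_x_um`
#'   (`NA` where no polarity was detected).
#' @export
polarity_timecourse <- function(mov, label_movie, reference_um,
                                params = polarity_params(),
                                channel = "reporter", cells = NULL,
                                view = c("projection", "best_slice", "slice"),
                                slice_z = NULL) {
  view <- match.arg(view)
  stopifnot(inherits(mov, "movie"))
  d <- dim(mov$data)
  nT <- d[1]
  sp_yx <- mov$spacing[2:3]
  if (is.null(cells)) {
    cells <- sort(setdiff(unique(as.vector(label_movie[1, , , ])), 0L))
  }
  recs <- vector("list", nT * length(cells))
  k <- 1
  for (t in seq_len(nT)) {
    vol <- get_channel(mov, channel, t)
    if (view == "projection") img2d <- apply(vol, c(2, 3), max)
    if (view == "slice") img2d <- matrix(vol[slice_z, , ], d[4], d[5])
    for (cid in cells) {
      mask3d <- label_movie[t, , , ] == cid
      dim(mask3d) <- d[3:5]
      if (view == "best_slice") {
        tot <- vapply(seq_len(d[3]), function(z) {
          sum(vol[z, , ][mask3d[z, , ]])
        }, numeric(1))
        zb <- which.max(tot)
        img2d <- matrix(vol[zb, , ], d[4], d[5])
        mask2d <- mask3d[zb, , ]
      } else {
        mask2d <- apply(mask3d, c(2, 3), any)
      }
      rec <- data.frame(cell = cid, frame = t, detected = FALSE,
                        ratio = NA_real_, orientation_deg = NA_real_,
                        region_y_um = NA_real_, region_x_um = NA_real_)
      if (any(mask2d)) {
        det <- detect_polarized_region(img2d, mask2d, params)
        if (!is.null(det)) {
          cyto <- erode_mask(mask2d, params$erosion_radius_px)
          if (any(cyto)) {
            pr <- polarity_ratio(img2d, det$region, cyto, params)
            cell_ctr <- cluster_centroid(mask2d, sp_yx)
            reg_um <- det$centroid_px * sp_yx
            ang <- tryCatch(
              orientation_angle(cell_ctr, reg_um, reference_um),
              error = function(e) NA_real_
            )
            rec$detected <- TRUE
            rec$ratio <- pr$ratio
            rec$orientation_deg <- ang
            rec$region_y_um <- reg_um[1]
            rec$region_x_um <- reg_um[2]
          }
        }
      }
      recs[[k]] <- rec
      k <- k + 1
    }
  }
  do.call(rbind, recs)
}
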