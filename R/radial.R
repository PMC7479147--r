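#' Intensity as a function of distance from the cluster centroid
#'
#' Each segmented voxel's intensity is first normalized to the mean intensity
#' of the background region in its own Z plane (so depth-dependent intensity
#' loss cancels), then its physical distance to the cluster centroid is
#' computed, and the distances are discretized into `n_bins` equally spaced
#' bins spanning `[0, max distance]`. Bins are half-open `[lo, hi)` with the
#' last bin closed, so every voxel is counted exactly once. Per-bin mean,
#' SEM (over voxel intensities), and voxel count are reported; empty bins get
#' `NA` means rather than zeros.
#'
#' @param image single-channel volume (Z, Y, X).
#' @param cluster_mask mask of the segmented cluster, same dimensions.
#' @param background_roi background mask, same dimensions; must contain at
#'   least one voxel in every Z plane occupied by the cluster mask.
#' @param n_bins number of distance bins.
#' @param normalization `"background"` (per-depth background division) or
#'   `"max"` (additionally rescale so the peak bin mean is 1).
#' @param spacing voxel spacing `(z, y, x)` in µm.
#' @return a `radial_profile`: data frame with columns `bin_center_um`,
#'   `mean`, `sem`, `n`, plus attributes `centroid_um`, `bin_width_um`,
#'   `normalization`.
#' @export
radial_intensity_profile <- function(image, cluster_mask, background_roi,
                                     n_bins = 50,
                                     normalization = c("background", "max"),
                                     spacing = c(1, 1, 1)) {
  normalization <- match.arg(normalization)
  if (!all(dim(image) == dim(cluster_mask))) stop("image/mask dimensions differ")
  if (!all(dim(image) == dim(background_roi))) stop("image/background dimensions differ")
  if (n_bins < 1) stop("n_bins must be >= 1")
  spacing <- check_spacing(spacing)
  idx <- which(cluster_mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("cluster mask is empty")

  bg_idx <- which(background_roi > 0, arr.ind = TRUE)
  z_used <- sort(unique(idx[, 1]))
  bg_mean <- vapply(z_used, function(z) {
    v <- image[bg_idx[bg_idx[, 1] == z, , drop = FALSE]]
    if (length(v) == 0) {
      stop("missing background: no background voxels at z plane ", z)
    }
    mean(v)
  }, numeric(1))
  if (any(bg_mean == 0)) {
    stop("background mean is zero at z plane ",
         z_used[which(bg_mean == 0)[1]], ": cannot normalize")
  }
  names(bg_mean) <- z_used

  vals <- image[idx] / bg_mean[as.character(idx[, 1])]
  ctr <- cluster_centroid(cluster_mask, spacing)
  dist_um <- sqrt(rowSums(sweep(idx_to_um(idx, spacing), 2, ctr, `-`)^2))

  dmax <- max(dist_um)
  if (dmax == 0) dmax <- .Machine$double.eps  # single-voxel mask: one bin at 0
  edges <- seq(0, dmax, length.out = n_bins + 1)
  bin <- findInterval(dist_um, edges, rightmost.closed = TRUE, all.inside = FALSE)
  bin[bin > n_bins] <- n_bins

  n <- tabulate(bin, nbins = n_bins)
  mu <- sem <- rep(NA_real_, n_bins)
  for (b in which(n > 0)) {
    v <- vals[bin == b]
    mu[b] <- mean(v)
    sem[b] <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  }
  if (normalization == "max") {
    peak <- max(mu, na.rm = TRUE)
    if (peak == 0) stop("all bin means are zero: cannot normalize to max")
    mu <- mu / peak
    sem <- sem / peak
  }
  out <- data.frame(bin_center_um = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                    mean = mu, sem = sem, n = n)
  structure(out, class = c("radial_profile", "data.frame"),
            centroid_um = ctr, bin_width_um = diff(edges[1:2]),
            normalization = normalization)
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("radial intensity profile: %d bins of %.3g µm (%s-normalized)\n",
              nrow(x), attr(x, "bin_width_um"), attr(x, "normalization")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Time-resolved radial profile (kymograph)
#'
#' Runs [radial_intensity_profile()] at every frame on a common distance
#' binning (bins span `[0, max distance over all frames]` so per-frame
#' profiles align), then bilinearly interpolates the (time x distance)
#' surface onto the requested grid. Values at source grid nodes are
#' preserved. With a single frame the static profile is returned unchanged.
#'
#' @param frames list of single-channel volumes, one per frame.
#' @param masks list of cluster masks, one per frame.
#' @param background_roi background mask shared by all frames.
#' @param n_bins,normalization,spacing as in [radial_intensity_profile()].
#' @param grid `c(n_t, n_d)`: output grid resolution in time and distance.
#' @param frame_times_min frame acquisition times in minutes.
#' @return a `radial_kymograph`: list with `time_min`, `distance_um`,
#'   `surface` (n_t x n_d matrix), and the per-frame source profiles.
#' @export
radial_profile_timecourse <- function(frames, masks, background_roi,
                                      n_bins = 50,
                                      normalization = c("background", "max"),
                                      spacing = c(1, 1, 1),
                                      grid = c(100, 100),
                                      frame_times_min = NULL) {
  normalization <- match.arg(normalization)
  nT <- length(frames)
  if (length(masks) != nT) stop("need one mask per frame")
  if (nT == 0) stop("no frames")
  if (is.null(frame_times_min)) frame_times_min <- (seq_len(nT) - 1) * 0.5
  spacing <- check_spacing(spacing)

  ## shared bin range across frames so rows of the surface are comparable
  dmax <- 0
  for (t in seq_len(nT)) {
    idx <- which(masks[[t]] > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("empty cluster mask at frame ", t)
    ctr <- cluster_centroid(masks[[t]], spacing)
    dmax <- max(dmax, sqrt(rowSums(sweep(idx_to_um(idx, spacing), 2, ctr, `-`)^2)))
  }

  profiles <- vector("list", nT)
  surface_src <- matrix(NA_real_, nT, n_bins)
  for (t in seq_len(nT)) {
    pr <- radial_profile_fixed(frames[[t]], masks[[t]], background_roi,
                               n_bins, normalization, spacing, dmax)
    profiles[[t]] <- pr
    surface_src[t, ] <- pr$mean
  }
  centers <- profiles[[1]]$bin_center_um

  if (nT == 1) {
    return(structure(list(time_min = frame_times_min, distance_um = centers,
                          surface = surface_src, profiles = profiles),
                     class = "radial_kymograph"))
  }
  tq <- seq(min(frame_times_min), max(frame_times_min), length.out = grid[1])
  dq <- seq(min(centers), max(centers), length.out = grid[2])
  qp <- expand.grid(d = dq, t = tq)
  vals <- pracma::interp2(x = centers, y = frame_times_min, Z = surface_src,
                          xp = qp$d, yp = qp$t, method = "linear")
  structure(list(time_min = tq, distance_um = dq,
                 surface = matrix(vals, nrow = grid[1], ncol = grid[2], byrow = TRUE),
                 profiles = profiles, source_times_min = frame_times_min,
                 source_distance_um = centers, source_surface = surface_src),
            class = "radial_kymograph")
}

## radial_intensity_profile with an externally fixed maximum distance, so
## several frames share one binning.
radial_profile_fixed <- function(image, cluster_mask, background_roi,
                                 n_bins, normalization, spacing, dmax) {
  idx <- which(cluster_mask > 0, arr.ind = TRUE)
  bg_idx <- which(background_roi > 0, arr.ind = TRUE)
  z_used <- sort(unique(idx[, 1]))
  bg_mean <- vapply(z_used, function(z) {
    v <- image[bg_idx[bg_idx[, 1] == z, , drop = FALSE]]
    if (length(v) == 0) stop("missing background at z plane ", z)
    m <- mean(v)
    if (m == 0) stop("background mean is zero at z plane ", z)
    m
  }, numeric(1))
  names(bg_mean) <- z_used
  vals <- image[idx] / bg_mean[as.character(idx[, 1])]
  ctr <- cluster_centroid(cluster_mask, spacing)
  dist_um <- sqrt(rowSums(sweep(idx_to_um(idx, spacing), 2, ctr, `-`)^2))
  edges <- seq(0, dmax, length.out = n_bins + 1)
  bin <- findInterval(dist_um, edges, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  n <- tabulate(bin, nbins = n_bins)
  mu <- sem <- rep(NA_real_, n_bins)
  for (b in which(n > 0)) {
    v <- vals[bin == b]
    mu[b] <- mean(v)
    sem[b] <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  }
  if (normalization == "max") {
    peak <- max(mu, na.rm = TRUE)
    mu <- mu / peak; sem <- sem / peak
  }
  data.frame(bin_center_um = (edges[-1] + edges[-(n_bins + 1)]) / 2,
             mean = mu, sem = sem, n = n)
}

#' Centre-to-mid-radius contrast of a radial profile
#'
#' Mean normalized intensity over the innermost occupied quarter of bins
#' divided by the mean over the middle half — a scalar summary of how
#' centre-enriched a profile is, used to compare inward-polarized and
#' randomly polarized clusters.
#'
#' @param profile a `radial_profile` (or data frame with `mean` and `n`).
#' @return contrast ratio (dimensionless).
#' @export
radial_contrast <- function(profile) {
  occ <- which(profile$n > 0)
  if (length(occ) < 4) stop("too few occupied bins for a contrast measure")
  qs <- stats::quantile(occ, c(0.25, 0.5, 0.75))
  inner <- occ[occ <= qs[1]]
  mid <- occ[occ > qs[1] & occ <= qs[3]]
  mean(profile$mean[inner]) / mean(profile$mean[mid])
}
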