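test_that("polarity ratio applies the 1.2-fold criterion", {
  img <- matrix(100, 20, 20)
  a <- matrix(FALSE, 20, 20); a[2:5, 2:5] <- TRUE
  b <- matrix(FALSE, 20, 20); b[10:13, 10:13] <- TRUE
  r <- polarity_ratio(img, a, b)
  expect_equal(r$ratio, 1.0)
  expect_false(r$meets_threshold)

  img[a] <- 150
  r2 <- polarity_ratio(img, a, b)
  expect_equal(r2$ratio, 1.5)
  expect_true(r2$meets_threshold)

  expect_error(polarity_ratio(matrix(0, 20, 20), a, b), "zero")
})

test_that("enrichment recovered from noisy renders matches the noiseless value", {
  ## 50 replicate single-cell movies; ROIs taken from each replicate's
  ## noiseless twin (identical geometry under the same seed)
  ratios <- vapply(1:50, function(s) {
    base <- cluster_sim_params(n_cells = 1, cell_radius_um = 3,
                               cluster_radius_um = 4.5,
                               cortex_thickness_um = 1,
                               voxel_spacing_um = c(0.5, 0.5, 0.5),
                               cap_enrichment = 2, seed = 9000 + s)
    clean <- get_channel(generate_cluster_movie(base)$movie, "reporter", 1)
    noisy_p <- base; noisy_p$noise <- "poisson_gaussian"
    noisy <- get_channel(generate_cluster_movie(noisy_p)$movie, "reporter", 1)
    cap_roi <- clean == 2 * base$cortex_level
    base_roi <- clean == base$cortex_level
    polarity_ratio(noisy, cap_roi, base_roi)$ratio
  }, numeric(1))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 2.0), 3 * se + 1e-6)
})

test_that("region detection obeys the size and SD criteria", {
  d <- disk_mask(12)
  set.seed(51)
  base <- matrix(0, nrow(d), ncol(d))
  base[d > 0] <- rnorm(sum(d), 100, 5)

  ## uniform-ish cortex: nothing 1.5 SD above the mean survives the size gate
  expect_null(detect_polarized_region(base, d))

  ## a 9-pixel bright patch is below the >10 px requirement
  peri <- periphery_mask(d, 2)
  pidx <- which(peri, arr.ind = TRUE)
  top9 <- pidx[order(pidx[, 1], pidx[, 2])[1:9], ]
  img9 <- base; img9[top9] <- 400
  expect_null(detect_polarized_region(img9, d))

  ## a 40-pixel contiguous arc far above threshold is detected, and the pixel
  ## set equals a brute-force 4-connected component oracle
  ctr <- (dim(d) + 1) / 2
  ang <- atan2(pidx[, 2] - ctr[2], pidx[, 1] - ctr[1])
  arc <- pidx[order(ang)[1:40], ]
  img40 <- base; img40[arc] <- 400
  det <- detect_polarized_region(img40, d)
  expect_false(is.null(det))
  mu <- mean(img40[d > 0]); sdv <- sd(img40[d > 0])
  cand <- peri & img40 > mu + 1.5 * sdv
  lab <- oracle_label_4conn(cand)
  sizes <- tabulate(lab[lab > 0])
  big <- which(sizes > 10)
  totals <- vapply(big, function(k) sum(img40[lab == k]), numeric(1))
  expect_identical(det$region, lab == big[which.max(totals)])
  ## centroid lies inside the planted arc's bounding box
  expect_true(det$centroid_px[1] + 1 >= min(arc[, 1]) - 1 &&
                det$centroid_px[1] + 1 <= max(arc[, 1]) + 1)
})

test_that("orientation angle matches constructed geometries and is rotation invariant", {
  expect_equal(orientation_angle(c(0, 0), c(0, 5), c(0, 9)), 0)
  expect_equal(orientation_angle(c(0, 0), c(0, 5), c(0, -3)), 180)
  expect_equal(orientation_angle(c(0, 0), c(5, 0), c(0, 7)), 90)
  expect_error(orientation_angle(c(0, 0), c(0, 0), c(1, 1)), "zero-length")

  set.seed(61)
  for (rep in 1:20) {
    cell <- rnorm(2); reg <- cell + rnorm(2); ref <- cell + rnorm(2)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    a0 <- orientation_angle(cell, reg, ref)
    a1 <- orientation_angle(drop(R %*% cell), drop(R %*% reg), drop(R %*% ref))
    expect_equal(a0, a1, tolerance = 1e-9)
  }
})

test_that("reorientation events are counted across gaps and match the oracle", {
  expect_equal(reorientation_events(c(30, 30, 30, 30)), 0)
  expect_equal(reorientation_events(c(10, 80)), 1)
  expect_equal(reorientation_events(c(10, NA, NA, 80)), 1)  # across the gap
  expect_equal(reorientation_events(c(10, NA, NA, 80), across_gaps = FALSE), 0)
  expect_error(reorientation_events(c(NA, 40, NA)), "at least 2")

  set.seed(71)
  series <- runif(300, 0, 180)
  series[runif(300) < 0.3] <- NA
  ## brute-force pairwise-difference oracle over consecutive detected values
  det <- series[!is.na(series)]
  cnt <- 0
  for (i in 2:length(det)) if (abs(det[i] - det[i - 1]) > 60) cnt <- cnt + 1
  expect_equal(reorientation_events(series), cnt)

  ## invariance under uniform angular offset
  expect_equal(reorientation_events(series + 17), cnt)
})

test_that("posterior intensity uses the lowest 20% of rows after rotation", {
  d <- disk_mask(12)
  img <- matrix(10, nrow(d), ncol(d)); img[d > 0] <- 100

  ## uniform cell: posterior mean equals whole-cell mean
  expect_equal(posterior_intensity_timecourse(list(list(image = img, mask = d)),
                                              c(1, 0)), 100)

  ## bottom 20% of rows carry 2x: rotation is identity, ratio exactly 2
  rows <- which(rowSums(d) > 0)
  k <- ceiling(0.2 * length(rows))
  bottom <- rows[(length(rows) - k + 1):length(rows)]
  img2 <- img; img2[bottom, ][d[bottom, ] > 0] <- 200
  post <- posterior_intensity_timecourse(list(list(image = img2, mask = d)),
                                         c(1, 0))
  in_bottom <- matrix(seq_len(nrow(d)) %in% bottom, nrow(d), ncol(d))
  upper_mean <- mean(img2[d > 0 & !in_bottom])
  expect_equal(post, 2 * upper_mean)

  ## cap rotated 90 degrees from down: mean over ground-truth cap pixels,
  ## measured in unrotated coordinates, within 2% after interpolation
  cols <- which(colSums(d) > 0)
  kc <- ceiling(0.2 * length(cols))
  right <- cols[(length(cols) - kc + 1):length(cols)]
  img3 <- img; img3[, right][d[, right] > 0] <- 200
  sel <- matrix(FALSE, nrow(d), ncol(d)); sel[, right] <- TRUE
  oracle <- mean(img3[sel & d > 0])
  post3 <- posterior_intensity_timecourse(list(list(image = img3, mask = d)),
                                          c(0, 1))
  expect_lt(abs(post3 - oracle) / oracle, 0.02)

  ## tiny cell: warns and falls back to the lowest row
  tiny <- matrix(0L, 8, 8); tiny[3:5, 3:5] <- 1L
  timg <- matrix(50, 8, 8)
  expect_warning(
    v <- posterior_intensity_timecourse(list(list(image = timg, mask = tiny)),
                                        c(1, 0)),
    "fewer than 5 rows")
  expect_equal(v, 50)
})

test_that("polarity time course composes its components consistently", {
  p <- cluster_sim_params(n_cells = 4, cell_radius_um = 3,
                          cluster_radius_um = 7, cortex_thickness_um = 1,
                          voxel_spacing_um = c(0.5, 0.3, 0.3),
                          orientation_mode = "random",
                          reorientation_rate_per_min = 2, n_frames = 2,
                          noise = "poisson_gaussian", seed = 81)
  sim <- generate_cluster_movie(p)
  ref <- sim$truth$cluster_centroid[1, c("y", "x")]
  pol <- polarity_timecourse(sim$movie, sim$truth$label_movie, ref,
                             view = "best_slice")
  expect_equal(nrow(pol), 4 * 2)
  expect_true(all(is.na(pol$orientation_deg) == !pol$detected))

  ## componentwise oracle: rerun detection/ratio/orientation by hand
  params <- polarity_params()
  d <- dim(sim$movie$data)
  for (row in seq_len(nrow(pol))) {
    t <- pol$frame[row]; cid <- pol$cell[row]
    vol <- get_channel(sim$movie, "reporter", t)
    mask3d <- array(sim$truth$label_movie[t, , , ] == cid, d[3:5])
    tot <- vapply(seq_len(d[3]), function(z) sum(vol[z, , ][mask3d[z, , ]]),
                  numeric(1))
    zb <- which.max(tot)
    img2d <- matrix(vol[zb, , ], d[4], d[5])
    mask2d <- mask3d[zb, , ]
    det <- detect_polarized_region(img2d, mask2d, params)
    expect_equal(pol$detected[row], !is.null(det))
    if (!is.null(det)) {
      cyto <- pgcquant:::erode_mask(mask2d, params$erosion_radius_px)
      pr <- polarity_ratio(img2d, det$region, cyto, params)
      expect_equal(pol$ratio[row], pr$ratio)
      sp_yx <- sim$movie$spacing[2:3]
      ang <- orientation_angle(cluster_centroid(mask2d, sp_yx),
                               det$centroid_px * sp_yx, ref)
      expect_equal(pol$orientation_deg[row], ang)
    }
  }

  ## an all-zero reporter yields no detections anywhere
  z <- sim$movie
  z$data[, 2, , , ] <- 0
  polz <- polarity_timecourse(z, sim$truth$label_movie, ref)
  expect_false(any(polz$detected))
})
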