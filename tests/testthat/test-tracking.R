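## Build a small label movie from explicit blob centres (frames x cells).
make_label_movie <- function(centres_list, dims = c(8, 16, 16), r = 1.4) {
  nT <- length(centres_list)
  labs <- array(0L, c(nT, dims))
  for (t in seq_len(nT)) {
    ctrs <- centres_list[[t]]
    for (i in seq_len(nrow(ctrs))) {
      for (z in seq_len(dims[1])) for (y in seq_len(dims[2])) for (x in seq_len(dims[3])) {
        if (sum((c(z, y, x) - ctrs[i, ])^2) <= r^2) labs[t, z, y, x] <- i
      }
    }
  }
  attr(labs, "spacing") <- c(1, 1, 1)
  labs
}

test_that("nearest-neighbour linking recovers static and moving cells", {
  ctr <- rbind(c(4, 4, 4), c(4, 12, 12))
  labs <- make_label_movie(list(ctr, ctr, ctr))
  tr <- link_centroids(labs, max_displacement_um = 3, frame_interval_s = 60)
  expect_equal(length(unique(tr$track_id)), 2)
  for (g in split(tr, tr$track_id)) {
    expect_equal(nrow(g), 3)
    expect_equal(sd(g$x), 0); expect_equal(sd(g$y), 0); expect_equal(sd(g$z), 0)
  }

  moving <- lapply(0:3, function(k) rbind(c(4, 4 + k, 4)))
  labs2 <- make_label_movie(moving)
  tr2 <- link_centroids(labs2, max_displacement_um = 3, frame_interval_s = 60)
  expect_equal(length(unique(tr2$track_id)), 1)
  expect_equal(diff(tr2$y), rep(1, 3))
})

test_that("linking matches simulated ground truth when motion is gated", {
  p <- small_cluster_params(seed = 11, n_frames = 4, n_cells = 6,
                            cell_step_um = 0.4)
  sim <- generate_cluster_movie(p)
  tr <- link_centroids(sim$truth$label_movie, sim$movie$spacing,
                       max_displacement_um = 2,
                       frame_interval_s = p$frame_interval_s)
  gt <- truth_tracks(sim$truth)
  expect_equal(length(unique(tr$track_id)), 6)
  m <- merge(tr, gt, by = c("track_id", "t"))
  expect_equal(nrow(m), nrow(gt))
  ## voxel-centre quantization bounds the centroid error well below spacing
  expect_lt(max(abs(m$x.x - m$x.y), abs(m$y.x - m$y.y), abs(m$z.x - m$z.y)),
            0.3)
})

test_that("speed and straightness match direct-sum oracles and closed cases", {
  tr <- data.frame(track_id = 1, t = seq(0, 4.5, by = 0.5),
                   x = seq(0, 9), y = 0, z = 0)
  expect_equal(track_speed(tr), 2)            # 1 µm per 30 s
  expect_equal(track_straightness(tr), 1)

  loop <- data.frame(track_id = 1, t = 0:4,
                     x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0), z = 0)
  expect_equal(track_straightness(loop), 0)

  stat <- data.frame(track_id = 1, t = 0:3, x = 1, y = 2, z = 3)
  expect_equal(track_speed(stat), 0)
  expect_error(track_straightness(stat), "zero path")
  expect_error(track_speed(stat[1, ]), "at least 2")

  set.seed(101)
  rnd <- data.frame(track_id = 1, t = cumsum(runif(20, 0.3, 1)),
                    x = cumsum(rnorm(20)), y = cumsum(rnorm(20)),
                    z = cumsum(rnorm(20)))
  steps <- 0
  for (i in 2:20) {
    steps <- steps + sqrt((rnd$x[i] - rnd$x[i - 1])^2 +
                            (rnd$y[i] - rnd$y[i - 1])^2 +
                            (rnd$z[i] - rnd$z[i - 1])^2)
  }
  expect_equal(track_speed(rnd), steps / (rnd$t[20] - rnd$t[1]),
               tolerance = 1e-12)
  net <- sqrt((rnd$x[20] - rnd$x[1])^2 + (rnd$y[20] - rnd$y[1])^2 +
                (rnd$z[20] - rnd$z[1])^2)
  expect_equal(track_straightness(rnd), net / steps, tolerance = 1e-12)
})

test_that("metrics are invariant under rigid motion", {
  set.seed(103)
  tr <- data.frame(track_id = 1, t = 0:9, x = cumsum(rnorm(10)),
                   y = cumsum(rnorm(10)), z = cumsum(rnorm(10)))
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- as.matrix(tr[, c("x", "y", "z")]) %*% R
  tr2 <- tr; tr2$x <- rot[, 1] + 5; tr2$y <- rot[, 2] - 3; tr2$z <- rot[, 3]
  expect_equal(track_speed(tr), track_speed(tr2), tolerance = 1e-12)
  expect_equal(track_straightness(tr), track_straightness(tr2),
               tolerance = 1e-12)
  expect_lte(track_straightness(tr), 1)
})

test_that("ensemble straightness matches a brute-force re-simulation oracle", {
  w <- generate_tracks(walk_params(mode = "persistent", persistence = 0.8,
                                   step_um = 1, n_tracks = 500, n_frames = 20,
                                   seed = 107))
  st <- track_metrics(w$tracks)$straightness
  set.seed(990)
  orc <- oracle_prw_straightness(500, 20, 0.8, 1)
  se <- sqrt(var(st) / 500 + var(orc) / 500)
  expect_lt(abs(mean(st) - mean(orc)), 2 * se)
})

test_that("distance-from-reference time course and relative mode", {
  tracks <- rbind(
    data.frame(track_id = 1, t = 0:2, x = 0, y = 0, z = 0),
    data.frame(track_id = 2, t = 0:2, x = c(3, 4, 5), y = 0, z = 0)
  )
  d0 <- distance_from_point_timecourse(tracks, c(0, 0, 0))
  expect_equal(d0$mean, c(1.5, 2, 2.5))
  expect_equal(d0$n, rep(2, 3))

  one <- distance_from_point_timecourse(tracks[tracks$track_id == 1, ],
                                        c(0, 0, 0))
  expect_equal(one$mean, rep(0, 3))

  rel <- distance_from_point_timecourse(tracks[tracks$track_id == 2, ],
                                        c(0, 0, 0), relative = TRUE)
  expect_equal(attr(rel, "per_track")$distance[1], 1)
  expect_error(distance_from_point_timecourse(tracks, c(0, 0, 0),
                                              relative = TRUE),
               "zero initial distance")

  ## directed walkers leave the reference faster than random walkers
  wd <- generate_tracks(walk_params(mode = "directed", bias_strength = 0.9,
                                    bias_target = c(500, 500, 500),
                                    step_um = 1, n_tracks = 30, n_frames = 15,
                                    box_um = 10, seed = 109))
  wr <- generate_tracks(walk_params(mode = "persistent", persistence = 0.2,
                                    step_um = 1, n_tracks = 30, n_frames = 15,
                                    box_um = 10, seed = 110))
  ref <- c(5, 5, 5)
  dd <- distance_from_point_timecourse(wd$tracks, ref)
  dr <- distance_from_point_timecourse(wr$tracks, ref)
  expect_true(all(diff(dd$mean) > 0))
  expect_gt(dd$mean[15], dr$mean[15])
})

test_that("reversal classification and the containment oracle agree", {
  roi <- list(type = "box", center = c(0, 0, 0), half_size = c(5, 5, 5))
  inside <- data.frame(track_id = 1, t = 0:5, x = 1, y = 1, z = 1)
  expect_false(classify_reversal(inside, roi, t_pulse = 1, window = 3))

  exiting <- data.frame(track_id = 1, t = 0:5, x = c(1, 1, 9, 9, 9, 9),
                        y = 0, z = 0)
  expect_true(classify_reversal(exiting, roi, t_pulse = 1, window = 3))
  expect_error(classify_reversal(exiting[1:2, ], roi, 1, 3),
               "does not cover")

  w <- generate_tracks(walk_params(mode = "persistent", persistence = 0.5,
                                   step_um = 2, n_tracks = 40, n_frames = 12,
                                   box_um = 8, seed = 113))
  sroi <- list(type = "sphere", center = c(4, 4, 4), radius = 6)
  flags <- vapply(split(w$tracks, w$tracks$track_id), classify_reversal,
                  logical(1), activation_roi = sroi, t_pulse = 0, window = 4)
  oracle <- vapply(split(w$tracks, w$tracks$track_id), function(tr) {
    sel <- tr$t > 0 & tr$t <= 4
    any(sqrt((tr$x[sel] - 4)^2 + (tr$y[sel] - 4)^2 + (tr$z[sel] - 4)^2) > 6)
  }, logical(1))
  expect_equal(mean(flags), mean(oracle))
  expect_identical(unname(flags), unname(oracle))
})

test_that("transmigration counts are cumulative and match exit times", {
  inside <- data.frame(track_id = 1, t = 0:5, x = 1, y = 0, z = 0)
  ct <- count_transmigrated(inside, c(0, 0, 0), radius_um = 10)
  expect_equal(ct$n_transmigrated, rep(0, 6))

  crosser <- data.frame(track_id = 2, t = 0:7, x = c(1, 3, 5, 7, 9, 12, 14, 16),
                        y = 0, z = 0)
  ct2 <- count_transmigrated(crosser, c(0, 0, 0), radius_um = 10)
  expect_equal(ct2$n_transmigrated, c(0, 0, 0, 0, 0, 1, 1, 1))

  w <- generate_tracks(walk_params(mode = "directed", bias_strength = 1,
                                   bias_target = c(1000, 0, 0), step_um = 3,
                                   n_tracks = 25, n_frames = 20, box_um = 10,
                                   seed = 117))
  ref <- c(5, 5, 5); R <- 25
  ct3 <- count_transmigrated(w$tracks, ref, radius_um = R)
  exits <- vapply(split(w$tracks, w$tracks$track_id), function(tr) {
    out <- sqrt((tr$x - ref[1])^2 + (tr$y - ref[2])^2 + (tr$z - ref[3])^2) > R
    if (any(out)) tr$t[which(out)[1]] else Inf
  }, numeric(1))
  oracle <- vapply(ct3$t, function(tt) sum(exits <= tt), numeric(1))
  expect_equal(ct3$n_transmigrated, oracle)
  expect_true(all(diff(ct3$n_transmigrated) >= 0))
})
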