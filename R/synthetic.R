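#' Parameters for the synthetic cluster-movie generator
#'
#' Describes a rosette-like cluster of spherical cells imaged in two channels:
#' a membrane channel (bright cortex) and a cortical-reporter channel whose
#' cortex carries an angular cap of enrichment. In `radial_inward` mode every
#' cap points from the cell centroid toward the cluster centroid (the
#' wild-type-like configuration); in `random` mode cap axes start uniform on
#' the sphere and evolve by small-step spherical diffusion punctuated by
#' Poisson-timed uniform resampling (the receptor-mutant-like configuration).
#' Fluorescence decays with imaging depth as `exp(-z / depth_attenuation_um)`
#' and applies to background and signal alike, emulating depth-dependent
#' intensity loss.
#'
#' @param n_cells number of cells (>= 1).
#' @param cell_radius_um,cluster_radius_um,cortex_thickness_um geometry in µm.
#' @param cap_half_angle_deg angular half-width of the enriched cap, degrees
#'   in (0, 180).
#' @param cap_enrichment fold enrichment of the cap over the cortex baseline
#'   (>= 1).
#' @param orientation_mode `"radial_inward"` or `"random"`.
#' @param reorientation_rate_per_min expected rate of uniform cap-axis
#'   resampling events (random mode).
#' @param frame_interval_s,n_frames temporal sampling.
#' @param voxel_spacing_um voxel spacing `(z, y, x)` in µm.
#' @param background_level mean intensity outside cells (before attenuation).
#' @param cortex_level,interior_level baseline cortex and cytoplasm intensity.
#' @param depth_attenuation_um length scale of depth decay; `Inf` disables it.
#' @param noise `"none"` or `"poisson_gaussian"` (Poisson shot noise on the
#'   expected signal plus additive Gaussian read noise).
#' @param gaussian_sd SD of the Gaussian read noise.
#' @param cell_step_um per-frame random-walk step of each cell centroid
#'   (0 = static cluster).
#' @param seed integer seed; identical parameters give bit-identical output.
#' @return A validated parameter list of class `cluster_sim_params`.
#' @export
cluster_sim_params <- function(n_cells = 30,
                               cell_radius_um = 4.5,
                               cluster_radius_um = 18,
                               cortex_thickness_um = 1,
                               cap_half_angle_deg = 60,
                               cap_enrichment = 2,
                               orientation_mode = c("radial_inward", "random"),
                               reorientation_rate_per_min = 0.5,
                               frame_interval_s = 30,
                               n_frames = 1,
                               voxel_spacing_um = c(0.5, 0.2, 0.2),
                               background_level = 10,
                               cortex_level = 100,
                               interior_level = 30,
                               depth_attenuation_um = Inf,
                               noise = c("none", "poisson_gaussian"),
                               gaussian_sd = 2,
                               cell_step_um = 0,
                               seed = 1) {
  orientation_mode <- match.arg(orientation_mode)
  noise <- match.arg(noise)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (cap_half_angle_deg <= 0 || cap_half_angle_deg >= 180) {
    stop("cap_half_angle_deg must lie in (0, 180)")
  }
  if (cap_enrichment < 1) stop("cap_enrichment must be >= 1")
  stopifnot_positive(cell_radius_um = cell_radius_um,
                     cluster_radius_um = cluster_radius_um,
                     cortex_thickness_um = cortex_thickness_um,
                     frame_interval_s = frame_interval_s,
                     background_level = background_level,
                     cortex_level = cortex_level)
  if (is.na(depth_attenuation_um) || depth_attenuation_um <= 0) {
    stop("depth_attenuation_um must be positive (Inf disables attenuation)")
  }
  check_spacing(voxel_spacing_um)
  if (cortex_thickness_um >= cell_radius_um) {
    stop("cortex_thickness_um must be smaller than cell_radius_um")
  }
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (cell_step_um < 0) stop("cell_step_um must be >= 0")
  structure(as.list(environment()), class = "cluster_sim_params")
}

## Fibonacci lattice of n near-uniform points on the unit sphere,
## columns (z, y, x).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(z = z, y = r * sin(phi), x = r * cos(phi))
}

## Deterministic shell packing: outermost shell first, shells separated by one
## cell diameter, one optional cell at the centre. Errors when the requested
## cell count cannot be placed without overlap.
pack_cluster <- function(n_cells, cell_r, cluster_r, jitter_sd = 0) {
  shell_capacity <- function(rho) {
    if (rho < cell_r * 0.999 && rho > 1e-9) return(0L)
    hi <- max(1L, floor(16 * (rho / (2 * cell_r))^2))
    for (m in seq(hi, 1L)) {
      pts <- fibonacci_sphere(m) * rho
      if (m == 1) return(1L)
      if (min(stats::dist(pts)) >= 2 * cell_r * 1.001) return(as.integer(m))
    }
    0L
  }
  pos <- NULL
  remaining <- n_cells
  rho <- cluster_r - cell_r
  while (remaining > 0 && rho > cell_r * 0.999) {
    cap <- shell_capacity(rho)
    m <- min(cap, remaining)
    if (m > 0) {
      pts <- fibonacci_sphere(m) * rho
      if (jitter_sd > 0) {
        j <- jitter_sd
        for (try in 1:6) {
          cand <- pts + matrix(stats::rnorm(3 * m, 0, j), ncol = 3)
          cand <- cand / sqrt(rowSums(cand^2)) * rho  # stay on the shell
          if (m == 1 || min(stats::dist(cand)) >= 2 * cell_r) { pts <- cand; break }
          j <- j / 2
        }
      }
      pos <- rbind(pos, pts)
      remaining <- remaining - m
    }
    rho <- rho - 2 * cell_r
  }
  if (remaining > 0 && rho > -cell_r * 0.5) {  # room for one central cell
    centre_ok <- is.null(pos) || min(sqrt(rowSums(pos^2))) >= 2 * cell_r
    if (centre_ok) { pos <- rbind(pos, c(0, 0, 0)); remaining <- remaining - 1 }
  }
  if (remaining > 0) {
    stop(sprintf(paste0("cannot pack %d cells of radius %g µm into a cluster of ",
                        "radius %g µm without overlap (placed %d)"),
                 n_cells, cell_r, cluster_r, n_cells - remaining))
  }
  colnames(pos) <- c("z", "y", "x")
  pos
}

## One step of the random cap-axis process: spherical diffusion with ~8
## degrees angular SD per frame, plus uniform resampling at the Poisson rate.
step_cap_axis <- function(axis, rate_per_min, dt_min, diff_deg = 8) {
  if (stats::runif(1) < 1 - exp(-rate_per_min * dt_min)) {
    return(drop(runif_sphere(1)))
  }
  unit(axis + stats::rnorm(3, 0, tan(diff_deg * pi / 180)))
}

#' Generate a synthetic two-channel cluster movie with ground truth
#'
#' Renders a rosette of spherical cells as a T x C x Z x Y x X movie with
#' channels `membrane` and `reporter`, plus a ground-truth record holding the
#' per-frame label masks, cell positions, cap axes, and cluster centroid.
#' Cells are packed deterministically on Fibonacci-lattice shells (with a
#' seed-controlled tangential jitter), so identical parameters reproduce the
#' output bit for bit.
#'
#' Pre-noise voxel values: cortex voxels carry `cortex_level` (times
#' `cap_enrichment` on the cap side of the reporter channel), cell interiors
#' `interior_level`, and voxels outside all cells `background_level`; every
#' value is multiplied by `exp(-z / depth_attenuation_um)`.
#'
#' @param params a [cluster_sim_params()].
#' @return list with elements `movie` (a [movie()]) and `truth` (class
#'   `ground_truth`: `label_movie` (T,Z,Y,X integer array with a `spacing`
#'   attribute), `positions` and `cap_axes` (T x n_cells x 3 arrays, axis
#'   order z,y,x, µm), `cluster_centroid` (T x 3, µm),
#'   `detachment_times` (NULL: no scripted detachment)).
#' @export
generate_cluster_movie <- function(params) {
  stopifnot(inherits(params, "cluster_sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    sp <- as.numeric(p$voxel_spacing_um)
    margin <- 2
    half <- p$cluster_radius_um + p$cell_radius_um + margin +
      p$cell_step_um * p$n_frames
    dims <- pmax(3L, as.integer(ceiling(2 * half / sp)) + 1L)
    centre <- (dims - 1) / 2 * sp
    base <- pack_cluster(p$n_cells, p$cell_radius_um, p$cluster_radius_um,
                         jitter_sd = 0.05 * p$cell_radius_um)

    nT <- p$n_frames; nC <- p$n_cells
    positions <- array(0, c(nT, nC, 3), dimnames = list(NULL, NULL, c("z", "y", "x")))
    positions[1, , ] <- sweep(base, 2, centre, `+`)
    if (nT > 1) for (t in 2:nT) {
      step <- if (p$cell_step_um > 0) p$cell_step_um * runif_sphere(nC) else 0
      pos <- positions[t - 1, , , drop = FALSE][1, , , drop = TRUE]
      if (nC == 1) pos <- matrix(pos, 1, 3)
      pos <- pos + step
      for (ax in 1:3) {  # keep cells inside the rendered field
        pos[, ax] <- pmin(pmax(pos[, ax], p$cell_radius_um),
                          (dims[ax] - 1) * sp[ax] - p$cell_radius_um)
      }
      positions[t, , ] <- pos
    }
    centroid <- t(vapply(seq_len(nT), function(t) {
      colMeans(matrix(positions[t, , ], nC, 3))
    }, numeric(3)))
    colnames(centroid) <- c("z", "y", "x")

    cap_axes <- array(0, c(nT, nC, 3), dimnames = dimnames(positions))
    if (p$orientation_mode == "radial_inward") {
      for (t in seq_len(nT)) for (i in seq_len(nC)) {
        v <- centroid[t, ] - positions[t, i, ]
        cap_axes[t, i, ] <- if (vnorm(v) < 1e-9) c(1, 0, 0) else unit(v)
      }
    } else {
      dt_min <- p$frame_interval_s / 60
      for (i in seq_len(nC)) {
        ax <- drop(runif_sphere(1))
        cap_axes[1, i, ] <- ax
        if (nT > 1) for (t in 2:nT) {
          ax <- step_cap_axis(ax, p$reorientation_rate_per_min, dt_min)
          cap_axes[t, i, ] <- ax
        }
      }
    }

    dat <- array(0, c(nT, 2, dims))
    labels <- array(0L, c(nT, dims))
    cos_cap <- cos(p$cap_half_angle_deg * pi / 180)
    attn <- if (is.finite(p$depth_attenuation_um)) {
      exp(-(seq_len(dims[1]) - 1) * sp[1] / p$depth_attenuation_um)
    } else rep(1, dims[1])

    for (t in seq_len(nT)) {
      mem <- array(0, dims); rep_ <- array(0, dims); lab <- array(0L, dims)
      for (i in seq_len(nC)) {
        ctr <- positions[t, i, ]
        rng <- lapply(1:3, function(ax) {
          lo <- max(1L, floor((ctr[ax] - p$cell_radius_um) / sp[ax]) + 1L)
          hi <- min(dims[ax], ceiling((ctr[ax] + p$cell_radius_um) / sp[ax]) + 1L)
          lo:hi
        })
        dz <- (rng[[1]] - 1) * sp[1] - ctr[1]
        dy <- (rng[[2]] - 1) * sp[2] - ctr[2]
        dx <- (rng[[3]] - 1) * sp[3] - ctr[3]
        d2 <- outer(dz^2, outer(dy^2, dx^2, `+`), `+`)
        inside <- d2 <= p$cell_radius_um^2
        if (!any(inside)) next
        cortex <- inside & d2 > (p$cell_radius_um - p$cortex_thickness_um)^2
        interior <- inside & !cortex
        ax <- cap_axes[t, i, ]
        dot <- outer(dz * ax[1], outer(dy * ax[2], dx * ax[3], `+`), `+`)
        cap <- cortex & dot >= cos_cap * sqrt(pmax(d2, 1e-12))

        memL <- array(0, dim(d2))
        memL[cortex] <- p$cortex_level
        memL[interior] <- p$interior_level
        repL <- array(0, dim(d2))
        repL[cortex] <- p$cortex_level
        repL[cap] <- p$cortex_level * p$cap_enrichment
        repL[interior] <- p$interior_level

        sub <- lab[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
        put <- inside & sub == 0L
        sub[put] <- i
        lab[rng[[1]], rng[[2]], rng[[3]]] <- sub
        msub <- mem[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
        msub[put] <- memL[put]
        mem[rng[[1]], rng[[2]], rng[[3]]] <- msub
        rsub <- rep_[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
        rsub[put] <- repL[put]
        rep_[rng[[1]], rng[[2]], rng[[3]]] <- rsub
      }
      mem[lab == 0L] <- p$background_level
      rep_[lab == 0L] <- p$background_level
      mem <- sweep(mem, 1, attn, `*`)
      rep_ <- sweep(rep_, 1, attn, `*`)
      if (p$noise == "poisson_gaussian") {
        n <- length(mem)
        mem <- array(stats::rpois(n, mem) + stats::rnorm(n, 0, p$gaussian_sd), dims)
        rep_ <- array(stats::rpois(n, rep_) + stats::rnorm(n, 0, p$gaussian_sd), dims)
      }
      dat[t, 1, , , ] <- mem
      dat[t, 2, , , ] <- rep_
      labels[t, , , ] <- lab
    }

    attr(labels, "spacing") <- sp
    truth <- structure(
      list(label_movie = labels, positions = positions, cap_axes = cap_axes,
           cluster_centroid = centroid, detachment_times = NULL,
           params = p),
      class = "ground_truth"
    )
    list(movie = movie(dat, spacing = sp, channels = c("membrane", "reporter"),
                       frame_interval_s = p$frame_interval_s),
         truth = truth)
  })
}

#' Serialize a ground-truth record
#'
#' Writes the label masks as a 16-bit TIFF stack (+ JSON sidecar) and the
#' numeric ground truth (positions, cap axes, cluster centroids, parameters)
#' as JSON, so simulated truths are inspectable and diffable.
#'
#' @param truth a `ground_truth` (from [generate_cluster_movie()]).
#' @param dir output directory (created if needed).
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_label_movie(truth$label_movie, attr(truth$label_movie, "spacing"),
                    file.path(dir, "labels.tif"))
  num <- list(positions_um = truth$positions, cap_axes = truth$cap_axes,
              cluster_centroid_um = truth$cluster_centroid,
              detachment_times = truth$detachment_times,
              params = unclass(truth$params))
  jsonlite::write_json(num, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Ground-truth cell positions as a track table
#'
#' @param truth a `ground_truth`.
#' @return data frame `track_id, t, x, y, z` (t in minutes, positions µm).
#' @export
truth_tracks <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  nT <- dim(truth$positions)[1]; nC <- dim(truth$positions)[2]
  t_min <- (seq_len(nT) - 1) * truth$params$frame_interval_s / 60
  do.call(rbind, lapply(seq_len(nC), function(i) {
    data.frame(track_id = i, t = t_min,
               x = truth$positions[, i, "x"],
               y = truth$positions[, i, "y"],
               z = truth$positions[, i, "z"])
  }))
}

#' Parameters for the synthetic 3D walk generator
#'
#' @param mode `"persistent"` (persistent random walk), `"directed"`
#'   (persistent walk with a bias toward `bias_target`), or `"stationary"`.
#' @param step_um displacement per frame in µm (exact in persistent/directed
#'   modes).
#' @param persistence directional correlation of successive steps in
#'   `[0, 1]`; 1 gives straight lines, 0 an uncorrelated walk.
#' @param bias_target point `(x, y, z)` in µm that directed walkers steer
#'   toward.
#' @param bias_strength mixing weight of the target direction in `[0, 1]`.
#' @param n_tracks,n_frames ensemble size and track length.
#' @param frame_interval_s time between frames (track times are minutes).
#' @param box_um side of the cube in which starting positions are drawn.
#' @param seed integer seed.
#' @export
walk_params <- function(mode = c("persistent", "directed", "stationary"),
                        step_um = 1, persistence = 0.8,
                        bias_target = c(0, 0, 0), bias_strength = 0.5,
                        n_tracks = 10, n_frames = 20,
                        frame_interval_s = 30, box_um = 50, seed = 1) {
  mode <- match.arg(mode)
  if (step_um < 0) stop("step_um must be >= 0")
  if (persistence < 0 || persistence > 1) stop("persistence must be in [0, 1]")
  if (bias_strength < 0 || bias_strength > 1) stop("bias_strength must be in [0, 1]")
  if (n_tracks < 1) stop("n_tracks must be >= 1")
  structure(as.list(environment()), class = "walk_params")
}

#' Generate synthetic 3D tracks
#'
#' Persistent random walks (optionally biased toward a target) with constant
#' per-frame step length, the substrate for validating the motility metrics.
#'
#' @param params a [walk_params()].
#' @return list with `tracks` (data frame `track_id, t, x, y, z`) and `truth`
#'   (per-track net displacement and path length computed by the generator).
#' @export
generate_tracks <- function(params) {
  stopifnot(inherits(params, "walk_params"))
  p <- params
  if (p$n_frames < 2) stop("n_frames must be >= 2: no displacement is defined")
  withr::with_seed(p$seed, {
    t_min <- (seq_len(p$n_frames) - 1) * p$frame_interval_s / 60
    out <- vector("list", p$n_tracks)
    net <- path <- numeric(p$n_tracks)
    for (k in seq_len(p$n_tracks)) {
      pos <- matrix(0, p$n_frames, 3)
      pos[1, ] <- stats::runif(3, 0, p$box_um)
      d <- drop(runif_sphere(1))
      for (t in 2:p$n_frames) {
        if (p$mode == "stationary") { pos[t, ] <- pos[t - 1, ]; next }
        if (p$persistence < 1) {
          d <- unit(p$persistence * d + (1 - p$persistence) * drop(runif_sphere(1)))
        }
        if (p$mode == "directed") {
          to_target <- p$bias_target - pos[t - 1, ]  # both are (x, y, z)
          if (vnorm(to_target) > 1e-9 && p$bias_strength > 0) {
            d <- unit((1 - p$bias_strength) * d + p$bias_strength * unit(to_target))
          }
        }
        pos[t, ] <- pos[t - 1, ] + p$step_um * d
      }
      net[k] <- vnorm(pos[p$n_frames, ] - pos[1, ])
      path[k] <- sum(sqrt(rowSums(diff(pos)^2)))
      out[[k]] <- data.frame(track_id = k, t = t_min,
                             x = pos[, 1], y = pos[, 2], z = pos[, 3])
    }
    list(tracks = do.call(rbind, out),
         truth = list(mode = p$mode, step_um = p$step_um,
                      persistence = p$persistence,
                      net_displacement_um = net, path_length_um = path))
  })
}

#' Rasterize simple test shapes as label masks
#'
#' Exact lattice rasterization of a disk, square, axis-aligned ellipse, or
#' ring, used as morphology fixtures. A pixel belongs to the shape when its
#' (integer) centre satisfies the analytic inequality.
#'
#' @param shape one of `"disk"`, `"square"`, `"ellipse"`, `"ring"`.
#' @param r disk radius (pixels).
#' @param s square side (pixels).
#' @param a,b ellipse semi-axes along rows and columns.
#' @param r_in,r_out ring radii (`r_in < d <= r_out`).
#' @param pad background margin around the shape, pixels.
#' @return integer matrix of 0/1 labels.
#' @export
generate_shape_mask <- function(shape = c("disk", "square", "ellipse", "ring"),
                                r = NULL, s = NULL, a = NULL, b = NULL,
                                r_in = NULL, r_out = NULL, pad = 3) {
  shape <- match.arg(shape)
  mk_radial <- function(rmax, keep) {
    n <- 2 * ceiling(rmax) + 1 + 2 * pad
    c0 <- (n + 1) / 2
    d2 <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`)
    m <- matrix(0L, n, n); m[keep(sqrt(d2))] <- 1L; m
  }
  m <- switch(shape,
    disk = {
      if (is.null(r) || r < 0.5) stop("disk: radius must cover at least one pixel")
      mk_radial(r, function(d) d <= r)
    },
    square = {
      if (is.null(s) || s < 1) stop("square: side must be >= 1 pixel")
      n <- s + 2 * pad
      m <- matrix(0L, n, n); m[pad + seq_len(s), pad + seq_len(s)] <- 1L; m
    },
    ellipse = {
      if (is.null(a) || is.null(b) || a < 0.5 || b < 0.5) {
        stop("ellipse: both semi-axes must cover at least one pixel")
      }
      n1 <- 2 * ceiling(a) + 1 + 2 * pad; n2 <- 2 * ceiling(b) + 1 + 2 * pad
      ci <- (n1 + 1) / 2; cj <- (n2 + 1) / 2
      q <- outer(((seq_len(n1) - ci) / a)^2, ((seq_len(n2) - cj) / b)^2, `+`)
      m <- matrix(0L, n1, n2); m[q <= 1] <- 1L; m
    },
    ring = {
      if (is.null(r_in) || is.null(r_out) || r_out <= r_in) {
        stop("ring: need r_out > r_in (zero-area ring requested)")
      }
      mk_radial(r_out, function(d) d > r_in & d <= r_out)
    })
  if (sum(m) == 0) stop(shape, ": requested shape rasterizes to zero pixels")
  m
}

#' Scripted posterior-contraction fixture
#'
#' A deterministic time series in which a posterior region shrinks while its
#' reporter intensity rises frame by frame — the idealized contraction
#' phenomenology used to validate posterior area/intensity read-outs.
#'
#' @param n_frames number of frames.
#' @param r0 initial posterior radius in pixels.
#' @param shrink_px radius decrease per frame (pixels).
#' @param intensity0 initial posterior intensity.
#' @param intensity_step intensity increase per frame.
#' @param background image background level.
#' @return list with `frames` (each `list(image, roi)`) and `schedule`
#'   (data frame of the programmed radius, area, and intensity).
#' @export
generate_contraction_series <- function(n_frames = 10, r0 = 18, shrink_px = 1.5,
                                        intensity0 = 100, intensity_step = 10,
                                        background = 10) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (r0 - (n_frames - 1) * shrink_px < 1.5) {
    stop("posterior radius would shrink below one pixel; reduce n_frames or shrink_px")
  }
  n <- 2 * ceiling(r0) + 7
  c0 <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`))
  frames <- vector("list", n_frames)
  sched <- data.frame(frame = seq_len(n_frames), radius_px = NA_real_,
                      area_px = NA_integer_, intensity = NA_real_)
  for (t in seq_len(n_frames)) {
    rt <- r0 - (t - 1) * shrink_px
    vt <- intensity0 + (t - 1) * intensity_step
    roi <- matrix(0L, n, n); roi[d <= rt] <- 1L
    img <- matrix(background, n, n); img[roi == 1L] <- vt
    frames[[t]] <- list(image = img, roi = roi)
    sched$radius_px[t] <- rt
    sched$area_px[t] <- sum(roi)
    sched$intensity[t] <- vt
  }
  list(frames = frames, schedule = sched)
}
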