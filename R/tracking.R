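#' Build tracks from a labeled movie by nearest-neighbour linking
#'
#' Computes per-frame label centroids (in µm) and links them frame to frame
#' by greedy global nearest-neighbour assignment under a maximum-displacement
#' gate. Unmatched objects start new tracks; objects that disappear end
#' their track (no gap closing — a missing frame splits the track). Distance
#' ties are resolved deterministically by smallest label.
#'
#' @param label_movie integer array (T, Z, Y, X); 0 = background. A
#'   `spacing` attribute is honoured when `spacing` is not given.
#' @param spacing voxel spacing `(z, y, x)` in µm.
#' @param max_displacement_um linking gate; centroid pairs further apart are
#'   never linked.
#' @param frame_interval_s frame interval; track times are minutes.
#' @return data frame `track_id, t, x, y, z` (positions µm, t minutes), with
#'   the originating label per row in column `label`.
#' @export
link_centroids <- function(label_movie, spacing = NULL,
                           max_displacement_um = 10, frame_interval_s = 30) {
  stopifnot(length(dim(label_movie)) == 4)
  nT <- dim(label_movie)[1]
  if (nT < 2) stop("need at least 2 frames to link tracks")
  spacing <- check_spacing(spacing %||% attr(label_movie, "spacing"))

  centroids <- function(t) {
    arr <- array(label_movie[t, , , ], dim(label_movie)[2:4])
    labs <- sort(setdiff(unique(as.vector(arr)), 0L))
    if (length(labs) == 0) return(NULL)
    pos <- t(vapply(labs, function(l) {
      cluster_centroid(arr == l, spacing)
    }, numeric(3)))
    list(labels = labs, pos = pos)  # pos columns are (z, y, x)
  }

  rows <- list()
  next_id <- 1L
  prev <- centroids(1)
  active <- if (is.null(prev)) integer(0) else {
    ids <- seq_len(length(prev$labels)) ; next_id <- length(ids) + 1L; ids
  }
  t_min <- (seq_len(nT) - 1) * frame_interval_s / 60
  emit <- function(id, t, pos, label) {
    data.frame(track_id = id, t = t_min[t],
               x = pos[3], y = pos[2], z = pos[1], label = label)
  }
  if (!is.null(prev)) {
    for (i in seq_along(prev$labels)) {
      rows[[length(rows) + 1]] <- emit(active[i], 1, prev$pos[i, ], prev$labels[i])
    }
  }
  for (t in 2:nT) {
    cur <- centroids(t)
    if (is.null(cur)) { prev <- NULL; active <- integer(0); next }
    n_cur <- length(cur$labels)
    assign_id <- rep(NA_integer_, n_cur)
    if (!is.null(prev)) {
      dmat <- outer(seq_len(length(prev$labels)), seq_len(n_cur),
                    Vectorize(function(i, j) vnorm(prev$pos[i, ] - cur$pos[j, ])))
      dmat[dmat > max_displacement_um] <- Inf
      repeat {
        if (all(!is.finite(dmat))) break
        best <- which(dmat == min(dmat), arr.ind = TRUE)
        ## deterministic tie-break: smallest previous label, then current
        best <- best[order(prev$labels[best[, 1]], cur$labels[best[, 2]])[1], , drop = FALSE]
        i <- best[1]; j <- best[2]
        assign_id[j] <- active[i]
        dmat[i, ] <- Inf; dmat[, j] <- Inf
      }
    }
    for (j in seq_len(n_cur)) {
      if (is.na(assign_id[j])) { assign_id[j] <- next_id; next_id <- next_id + 1L }
      rows[[length(rows) + 1]] <- emit(assign_id[j], t, cur$pos[j, ], cur$labels[j])
    }
    prev <- cur
    active <- assign_id
  }
  out <- do.call(rbind, rows)
  out[order(out$track_id, out$t), ]
}

## Split a track table into per-track position matrices, validating order.
split_tracks <- function(tracks) {
  lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$t), ]
    if (nrow(tr) >= 2 && any(diff(tr$t) <= 0)) stop("track times must strictly increase")
    tr
  })
}

#' Mean track speed
#'
#' Total path length divided by total elapsed time.
#'
#' @param track data frame with columns `t` (minutes) and `x, y, z` (µm) for
#'   one track.
#' @return speed in µm/min.
#' @export
track_speed <- function(track) {
  track <- track[order(track$t), ]
  if (nrow(track) < 2) stop("need at least 2 samples")
  dt <- track$t[nrow(track)] - track$t[1]
  if (dt <= 0) stop("zero elapsed time: speed undefined")
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2 + diff(track$z)^2)
  sum(steps) / dt
}

#' Track straightness
#'
#' Net displacement (first to last position) divided by total path length;
#' 1 for a straight monotone track, 0 for a closed loop.
#'
#' @inheritParams track_speed
#' @return straightness in `[0, 1]`.
#' @export
track_straightness <- function(track) {
  track <- track[order(track$t), ]
  if (nrow(track) < 2) stop("need at least 2 samples")
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2 + diff(track$z)^2)
  path <- sum(steps)
  if (path == 0) stop("zero path length: straightness undefined")
  net <- vnorm(c(track$x[nrow(track)] - track$x[1],
                 track$y[nrow(track)] - track$y[1],
                 track$z[nrow(track)] - track$z[1]))
  net / path
}

#' Distance from a reference point over time
#'
#' Euclidean distance of every cell to a fixed reference point per frame,
#' optionally divided by each track's initial distance (`relative = TRUE`),
#' aggregated across cells as mean and SEM.
#'
#' @param tracks track table (`track_id, t, x, y, z`).
#' @param reference reference point `(x, y, z)` in µm.
#' @param relative normalize each track by its first distance.
#' @return data frame `t, mean, sem, n` plus per-track distances in
#'   attribute `"per_track"` (data frame `track_id, t, distance`).
#' @export
distance_from_point_timecourse <- function(tracks, reference,
                                           relative = FALSE) {
  per <- lapply(split_tracks(tracks), function(tr) {
    d <- sqrt((tr$x - reference[1])^2 + (tr$y - reference[2])^2 +
                (tr$z - reference[3])^2)
    if (relative) {
      if (d[1] == 0) stop("track ", tr$track_id[1],
                          ": zero initial distance, relative mode undefined")
      d <- d / d[1]
    }
    data.frame(track_id = tr$track_id[1], t = tr$t, distance = d)
  })
  per <- do.call(rbind, per)
  agg <- lapply(split(per, per$t), function(g) {
    data.frame(t = g$t[1], mean = mean(g$distance),
               sem = if (nrow(g) > 1) stats::sd(g$distance) / sqrt(nrow(g)) else 0,
               n = nrow(g))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$t), ]
  rownames(out) <- NULL
  attr(out, "per_track") <- per
  out
}

## Is a position (x, y, z) inside an activation/boundary region?
## Regions are list(type="sphere", center, radius) or
## list(type="box", center, half_size) with center (x, y, z) in µm.
point_in_region <- function(pos, region) {
  ctr <- region$center
  if (identical(region$type, "box")) {
    all(abs(pos - ctr) <= region$half_size)
  } else {
    vnorm(pos - ctr) <= region$radius
  }
}

#' Classify a post-activation trajectory as a reversal
#'
#' Scores a cell as reversed when its position leaves the activation ROI
#' within a time window after the light pulse.
#'
#' @param track one track (`t, x, y, z`), covering
#'   `[t_pulse, t_pulse + window]`.
#' @param activation_roi region: `list(type = "sphere", center, radius)` or
#'   `list(type = "box", center, half_size)`, coordinates `(x, y, z)` µm.
#' @param t_pulse activation time (minutes).
#' @param window classification window after the pulse (minutes).
#' @return logical: `TRUE` if the cell exits the ROI within the window.
#' @export
classify_reversal <- function(track, activation_roi, t_pulse, window) {
  track <- track[order(track$t), ]
  if (min(track$t) > t_pulse || max(track$t) < t_pulse + window) {
    stop("track does not cover the classification window")
  }
  sel <- track$t > t_pulse & track$t <= t_pulse + window
  if (!any(sel)) return(FALSE)
  pos <- track[sel, c("x", "y", "z")]
  any(!apply(pos, 1, point_in_region, region = activation_roi))
}

#' Cumulative transmigration count over time
#'
#' A track counts as transmigrated from the first frame at which it lies
#' outside the boundary (a sphere of `radius_um` around `reference`, or an
#' explicit region), and stays counted from then on, giving a monotone
#' cumulative series.
#'
#' @param tracks track table.
#' @param reference boundary centre `(x, y, z)` µm (ignored when `region`
#'   given).
#' @param radius_um boundary radius in µm.
#' @param region optional explicit region (see [classify_reversal()]).
#' @return data frame `t, n_transmigrated` over all frames present in
#'   `tracks`.
#' @export
count_transmigrated <- function(tracks, reference = c(0, 0, 0),
                                radius_um = NULL, region = NULL) {
  if (is.null(region)) {
    if (is.null(radius_um)) stop("give either 'radius_um' or 'region'")
    region <- list(type = "sphere", center = reference, radius = radius_um)
  }
  times <- sort(unique(tracks$t))
  exit_t <- vapply(split_tracks(tracks), function(tr) {
    outside <- !vapply(seq_len(nrow(tr)), function(i) {
      point_in_region(c(tr$x[i], tr$y[i], tr$z[i]), region)
    }, logical(1))
    if (any(outside)) tr$t[which(outside)[1]] else Inf
  }, numeric(1))
  data.frame(t = times,
             n_transmigrated = vapply(times, function(tt) sum(exit_t <= tt),
                                      numeric(1)))
}

#' Summary metrics for every track in a table
#'
#' @param tracks track table (`track_id, t, x, y, z`).
#' @return data frame `track_id, speed_um_min, straightness, n_samples`
#'   (straightness is `NA` for tracks with zero path length).
#' @export
track_metrics <- function(tracks) {
  do.call(rbind, lapply(split_tracks(tracks), function(tr) {
    data.frame(track_id = tr$track_id[1],
               speed_um_min = track_speed(tr),
               straightness = tryCatch(track_straightness(tr),
                                       error = function(e) NA_real_),
               n_samples = nrow(tr))
  }))
}
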