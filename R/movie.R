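#' Multi-channel 4D movie container
#'
#' A `movie` holds voxel data for a multi-channel time-lapse Z-stack in the
#' canonical axis order T x C x Z x Y x X, together with the physical voxel
#' spacing, channel names, and the frame interval. All distances elsewhere in
#' the package are computed in micrometres using `spacing`.
#'
#' @param data 5D numeric array with dimensions (T, C, Z, Y, X). Arrays with
#'   fewer dimensions are promoted by inserting length-1 leading axes
#'   (a 3D (Z, Y, X) array becomes a single-frame, single-channel movie).
#' @param spacing voxel spacing `(z, y, x)` in micrometres.
#' @param channels character vector naming the channels (length C).
#' @param frame_interval_s time between frames in seconds.
#' @return An object of class `movie`.
#' @export
movie <- function(data, spacing, channels = NULL, frame_interval_s = 30) {
  if (!is.array(data)) stop("'data' must be an array")
  nd <- length(dim(data))
  if (nd < 2 || nd > 5) stop("'data' must have between 2 and 5 dimensions")
  if (nd < 5) dim(data) <- c(rep(1L, 5 - nd), dim(data))
  spacing <- check_spacing(spacing)
  nc <- dim(data)[2]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc) stop("'channels' must name every channel")
  stopifnot_positive(frame_interval_s = frame_interval_s)
  structure(
    list(data = data, spacing = spacing, channels = channels,
         frame_interval_s = frame_interval_s),
    class = "movie"
  )
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("movie: T=%d C=%d Z=%d Y=%d X=%d\n", d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  cat(sprintf("  spacing (z,y,x): %s µm; frame interval %.1f s\n",
              paste(signif(x$spacing, 3), collapse = " x "), x$frame_interval_s))
  invisible(x)
}

#' @export
dim.movie <- function(x) dim(x$data)

#' Extract one channel volume from a movie
#'
#' @param m a [movie()].
#' @param channel channel name or index.
#' @param frame frame index (1-based).
#' @return 3D numeric array (Z, Y, X).
#' @export
get_channel <- function(m, channel, frame = 1) {
  stopifnot(inherits(m, "movie"))
  if (is.character(channel)) {
    channel <- match(channel, m$channels)
    if (is.na(channel)) stop("unknown channel name")
  }
  d <- dim(m$data)
  if (frame < 1 || frame > d[1]) stop("frame out of range")
  array(m$data[frame, channel, , , ], dim = d[3:5])
}

#' Times of the movie frames in minutes
#' @param m a [movie()] (or anything with `frame_interval_s` and a T axis).
#' @param n_frames number of frames; defaults to the movie's T extent.
#' @return numeric vector of frame times, starting at 0.
#' @export
frame_times_min <- function(m, n_frames = dim(m$data)[1]) {
  (seq_len(n_frames) - 1) * m$frame_interval_s / 60
}

#' Read and write movies as multi-page TIFF with a JSON sidecar
#'
#' Voxel data are stored as 32-bit float TIFF pages (page order: T, then C,
#' then Z, slowest to fastest), rescaled to `[0, 1]` by a single global
#' intensity scale. Axis sizes, spacing, channel names, frame interval, and
#' the intensity scale are stored in `<path>.json` next to the TIFF, so a
#' write/read round trip restores the movie (to 32-bit float precision).
#'
#' @param m a [movie()].
#' @param path path to the TIFF file; the sidecar is written at `<path>.json`.
#' @return `write_movie` returns `path` invisibly; `read_movie` returns a
#'   [movie()].
#' @export
write_movie <- function(m, path) {
  stopifnot(inherits(m, "movie"))
  d <- dim(m$data)
  scale <- max(m$data, 1e-12)
  pages <- vector("list", d[1] * d[2] * d[3])
  k <- 1
  for (t in seq_len(d[1])) for (c in seq_len(d[2])) for (z in seq_len(d[3])) {
    pages[[k]] <- matrix(m$data[t, c, z, , ], d[4], d[5]) / scale
    k <- k + 1
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(
    axes = "TCZYX", shape = as.integer(d), spacing_um = m$spacing,
    channels = m$channels, frame_interval_s = m$frame_interval_s,
    intensity_scale = scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @param spacing,channels,frame_interval_s overrides used when the sidecar
#'   is missing (bare TIFF); ignored when `<path>.json` exists.
#' @export
read_movie <- function(path, spacing = NULL, channels = NULL,
                       frame_interval_s = 30) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    d <- as.integer(meta$shape)
    dat <- array(0, dim = d)
    k <- 1
    for (t in seq_len(d[1])) for (c in seq_len(d[2])) for (z in seq_len(d[3])) {
      dat[t, c, z, , ] <- pages[[k]] * meta$intensity_scale
      k <- k + 1
    }
    movie(dat, spacing = meta$spacing_um, channels = meta$channels,
          frame_interval_s = meta$frame_interval_s)
  } else {
    if (is.null(spacing)) {
      stop("no sidecar metadata found for '", path,
           "': axis interpretation is ambiguous; pass 'spacing' ",
           "(pages are then read as a single-frame single-channel Z-stack)")
    }
    dat <- array(0, dim = c(1, 1, length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_along(pages)) dat[1, 1, z, , ] <- pages[[z]]
    movie(dat, spacing = spacing, channels = channels,
          frame_interval_s = frame_interval_s)
  }
}

#' Read and write per-frame integer label movies
#'
#' Label movies (dimensions T, Z, Y, X; 0 = background) are stored as 16-bit
#' TIFF pages with a JSON sidecar recording shape and spacing. Labels are
#' restored exactly for label values up to 65535.
#'
#' @param labels 4D integer array (T, Z, Y, X).
#' @param spacing voxel spacing `(z, y, x)` in µm.
#' @param path TIFF path; sidecar at `<path>.json`.
#' @export
write_label_movie <- function(labels, spacing, path) {
  stopifnot(is.array(labels), length(dim(labels)) == 4)
  spacing <- check_spacing(spacing)
  d <- dim(labels)
  if (max(labels) > 65535) stop("labels above 65535 are not supported")
  pages <- vector("list", d[1] * d[2])
  k <- 1
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    pages[[k]] <- matrix(labels[t, z, , ], d[3], d[4]) / 65535
    k <- k + 1
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(axes = "TZYX", shape = as.integer(d),
                            spacing_um = spacing),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_movie
#' @export
read_label_movie <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$shape)
  labels <- array(0L, dim = d)
  k <- 1
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    labels[t, z, , ] <- as.integer(round(pages[[k]] * 65535))
    k <- k + 1
  }
  attr(labels, "spacing") <- as.numeric(meta$spacing_um)
  labels
}

#' Read and write track tables
#'
#' Tracks are plain CSV with columns `track_id, t, x, y, z`; positions in
#' micrometres, `t` in minutes.
#'
#' @param tracks data frame with the five track columns.
#' @param path CSV path.
#' @export
write_tracks <- function(tracks, path) {
  need <- c("track_id", "t", "x", "y", "z")
  if (!all(need %in% names(tracks))) {
    stop("tracks must have columns track_id, t, x, y, z")
  }
  utils::write.csv(tracks[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tr <- utils::read.csv(path)
  need <- c("track_id", "t", "x", "y", "z")
  if (!all(need %in% names(tr))) {
    stop("'", path, "' is not a track table (needs track_id, t, x, y, z)")
  }
  tr[order(tr$track_id, tr$t), need]
}
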