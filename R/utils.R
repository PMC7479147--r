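# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero-length vector")
  v / n
}

## Clamped arc-cosine in degrees; guards against |dot| > 1 from rounding.
acos_deg <- function(x) acos(pmin(1, pmax(-1, x))) * 180 / pi

stopifnot_positive <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    if (any(!is.finite(vals[[i]])) || any(vals[[i]] <= 0)) {
      stop(sprintf("'%s' must be strictly positive and finite", nms[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

## Uniform random unit vector(s) in R^3, rows = samples, columns (z, y, x).
runif_sphere <- function(n = 1) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

## spacing is always a length-3 numeric (z, y, x) in micrometres.
check_spacing <- function(spacing) {
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be three strictly positive values (z, y, x) in µm")
  }
  as.numeric(spacing)
}

## 0-based voxel-centre coordinates in um for array indices (1-based in R).
idx_to_um <- function(idx, spacing) {
  sweep(idx - 1, 2, spacing, `*`)
}
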