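# Independent oracle implementations used to cross-check package routines.
# These deliberately use naive loops / enumeration, not the package's code
# paths.

## 4-connected flood fill labelling of a 2D logical matrix.
oracle_label_4conn <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
              mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
  }
  lab
}

## Exhaustive-search threshold: minimize total within-class variance (sum of
## squared deviations) over candidate thresholds = the 256-bin edges spanning
## the value range.
oracle_min_intraclass_threshold <- function(vals, levels = 256) {
  edges <- seq(min(vals), max(vals), length.out = levels + 1)
  best <- Inf; best_t <- NA_real_
  for (t in edges[2:levels]) {
    a <- vals[vals < t]; b <- vals[vals >= t]
    if (length(a) == 0 || length(b) == 0) next
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best) { best <- ss; best_t <- t }
  }
  best_t
}

## Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_ranksum_enum <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

## Two-sided Fisher p by explicit hypergeometric summation over all tables
## with the observed margins (probability-mass criterion).
oracle_fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  k <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(k, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

## Persistent-random-walk straightness by direct re-simulation of the same
## process (step = unit(p * d + (1 - p) * u), constant step length).
oracle_prw_straightness <- function(n_tracks, n_frames, persistence, step) {
  rsphere <- function() { v <- stats::rnorm(3); v / sqrt(sum(v^2)) }
  vapply(seq_len(n_tracks), function(k) {
    pos <- matrix(0, n_frames, 3)
    d <- rsphere()
    for (t in 2:n_frames) {
      if (persistence < 1) {
        d <- persistence * d + (1 - persistence) * rsphere()
        d <- d / sqrt(sum(d^2))
      }
      pos[t, ] <- pos[t - 1, ] + step * d
    }
    net <- sqrt(sum((pos[n_frames, ] - pos[1, ])^2))
    path <- sum(sqrt(rowSums(diff(pos)^2)))
    net / path
  }, numeric(1))
}

## Boundary walk of a convex 2D blob: order the boundary pixels (foreground
## pixels with a 4-neighbour background) by angle around the centroid and sum
## the closed-polygon edge lengths through the pixel centres.
oracle_boundary_walk_length <- function(mask) {
  m <- mask > 0
  pad <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  core <- pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
  nb_bg <- !pad[1:nrow(m), 2:(ncol(m) + 1)] | !pad[3:(nrow(m) + 2), 2:(ncol(m) + 1)] |
    !pad[2:(nrow(m) + 1), 1:ncol(m)] | !pad[2:(nrow(m) + 1), 3:(ncol(m) + 2)]
  bdry <- which(core & nb_bg, arr.ind = TRUE)
  ctr <- colMeans(which(m, arr.ind = TRUE))
  ord <- order(atan2(bdry[, 2] - ctr[2], bdry[, 1] - ctr[1]))
  pts <- bdry[ord, , drop = FALSE]
  pts <- rbind(pts, pts[1, ])  # close the polygon
  sum(sqrt(rowSums(diff(pts)^2)))
}

## Tiny helpers shared by tests.
disk_mask <- function(r, pad = 3) generate_shape_mask("disk", r = r, pad = pad)

small_cluster_params <- function(mode = "radial_inward", seed = 1, n_frames = 1,
                                 n_cells = 8, ...) {
  cluster_sim_params(n_cells = n_cells, cell_radius_um = 2,
                     cluster_radius_um = 7, cortex_thickness_um = 0.8,
                     voxel_spacing_um = c(0.5, 0.5, 0.5),
                     orientation_mode = mode, n_frames = n_frames,
                     seed = seed, ...)
}
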