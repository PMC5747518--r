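# Shared in-code fixtures: tiny constructed tracks and brute-force oracles.

# Track moving along +x with prescribed per-step speeds (um/min).
track_from_speeds <- function(speeds_um_min, dt_s = 10, cell_id = "c1") {
  steps_um <- speeds_um_min / 60 * dt_s
  x <- c(0, cumsum(steps_um))
  track(cell_id, seq(0, by = dt_s, length.out = length(x)),
        cbind(x, 0))
}

# Track through prescribed 2D/3D waypoints at a fixed interval.
track_from_points <- function(pts, dt_s = 10, cell_id = "c1") {
  pts <- as.matrix(pts)
  track(cell_id, seq(0, by = dt_s, length.out = nrow(pts)), pts)
}

# O(n^2) brute-force MSD over all ordered frame pairs, per lag.
brute_msd <- function(pos) {
  n <- nrow(pos)
  vapply(seq_len(n - 1L), function(k) {
    acc <- 0
    cnt <- 0L
    for (i in seq_len(n - k)) {
      acc <- acc + sum((pos[i + k, ] - pos[i, ])^2)
      cnt <- cnt + 1L
    }
    acc / cnt
  }, numeric(1))
}

# Exact Mann-Whitney two-tailed p by full enumeration of group assignments.
brute_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  mu <- na * length(b) / 2
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2L, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Spearman rho by the rank formula (no ties assumed).
brute_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Rasterize a uniform disc of radius r_px into an image of side n.
raster_disc <- function(n, cx, cy, r_px, value = 100L) {
  img <- matrix(0L, n, n)
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      if ((x - 1 - cx)^2 + (y - 1 - cy)^2 <= r_px^2) img[y, x] <- value
    }
  }
  img
}

# Two-channel stack from a list of green frames (constant red background).
stack_from_frames <- function(frames, pixel_um = 1, dt_s = 1, red_value = 0L) {
  ny <- nrow(frames[[1L]]); nx <- ncol(frames[[1L]])
  g <- array(0L, c(ny, nx, length(frames)))
  for (k in seq_along(frames)) g[, , k] <- frames[[k]]
  image_stack(g, array(red_value, dim(g)), pixel_um, dt_s)
}
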