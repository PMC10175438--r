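# shared synthetic fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

# small split cylinder (r = 15, h = 20) used by unit tests; the acceptance
# tests use the full-size r = 25 geometry
small_phantom <- function(g, s, r = 15, h = 20, spacing = 0.5) {
  key <- paste("ph", g, s, r, h, spacing, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  ph <- make_phantom(split_cylinder_spec(g, s, r = r, h = h,
                                         spacing = spacing))
  .fixture_cache[[key]] <- ph
  ph
}

# axis-aligned box volume in HU, voxel centres at half-spacing offsets
box_volume <- function(half = 10, spacing = 0.5, extent = 15,
                       bone = 700, air = -1000) {
  xs <- seq(-extent + spacing / 2, extent, by = spacing)
  d <- length(xs)
  X <- array(rep(xs, times = d * d), dim = c(d, d, d))
  Y <- array(rep(rep(xs, each = d), times = d), dim = c(d, d, d))
  Z <- array(rep(xs, each = d * d), dim = c(d, d, d))
  arr <- array(air, dim = c(d, d, d))
  arr[abs(X) <= half & abs(Y) <= half & abs(Z) <= half] <- bone
  ct_volume(arr, spacing = rep(spacing, 3), origin = rep(xs[1], 3))
}

# two disjoint cubes (half-sizes h1, h2), centres +/- offset on x
two_cube_volume <- function(h1 = 5, h2 = 3, offset = 9, spacing = 0.5,
                            extent = 16) {
  xs <- seq(-extent + spacing / 2, extent, by = spacing)
  d <- length(xs)
  X <- array(rep(xs, times = d * d), dim = c(d, d, d))
  Y <- array(rep(rep(xs, each = d), times = d), dim = c(d, d, d))
  Z <- array(rep(xs, each = d * d), dim = c(d, d, d))
  arr <- array(-1000, dim = c(d, d, d))
  arr[abs(X + offset) <= h1 & abs(Y) <= h1 & abs(Z) <= h1] <- 700
  arr[abs(X - offset) <= h2 & abs(Y) <= h2 & abs(Z) <= h2] <- 700
  ct_volume(arr, spacing = rep(spacing, 3), origin = rep(xs[1], 3))
}

sphere_volume <- function(r = 15, spacing = 0.5, extent = NULL) {
  if (is.null(extent)) extent <- r + 3
  xs <- seq(-extent + spacing / 2, extent, by = spacing)
  d <- length(xs)
  X <- array(rep(xs, times = d * d), dim = c(d, d, d))
  Y <- array(rep(rep(xs, each = d), times = d), dim = c(d, d, d))
  Z <- array(rep(xs, each = d * d), dim = c(d, d, d))
  arr <- array(-1000, dim = c(d, d, d))
  arr[X^2 + Y^2 + Z^2 <= r^2] <- 700
  ct_volume(arr, spacing = rep(spacing, 3), origin = rep(xs[1], 3))
}

# a random rigid rotation matrix from a seeded draw
random_rotation <- function(seed) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])),
              c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0),
              c(0, 0, 1))
  Rz %*% Ry %*% Rx
}
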