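# Shared fixtures: random polygon generators and small oracle
# implementations that are independent of the package's primitives.

# random convex 20-gon with optional area, centred near the origin
rand20 <- function(area = NULL) iknm:::random_convex_20gon(area)

# rasterization oracle for polygon area: count grid cells whose centre
# lies inside the polygon (crossing test re-implemented locally)
raster_area <- function(p, pitch = 1e-3) {
  xr <- range(p[, 1]); zr <- range(p[, 2])
  xs <- seq(xr[1] + pitch / 2, xr[2], by = pitch)
  zs <- seq(zr[1] + pitch / 2, zr[2], by = pitch)
  g <- expand.grid(x = xs, z = zs)
  n <- nrow(p)
  inside <- rep(FALSE, nrow(g))
  j <- n
  for (i in seq_len(n)) {
    zi <- p[i, 2]; zj <- p[j, 2]
    cross <- (zi > g$z) != (zj > g$z)
    xint <- (p[j, 1] - p[i, 1]) * (g$z - zi) / (zj - zi) + p[i, 1]
    inside <- xor(inside, cross & (g$x < xint))
    j <- i
  }
  sum(inside) * pitch^2
}

# rasterization oracle for the intersection area of two polygons
raster_overlap <- function(p, q, pitch = 1e-3) {
  xr <- range(c(p[, 1], q[, 1])); zr <- range(c(p[, 2], q[, 2]))
  xs <- seq(xr[1] + pitch / 2, xr[2], by = pitch)
  zs <- seq(zr[1] + pitch / 2, zr[2], by = pitch)
  g <- expand.grid(x = xs, z = zs)
  inside_of <- function(p) {
    n <- nrow(p); ins <- rep(FALSE, nrow(g)); j <- n
    for (i in seq_len(n)) {
      zi <- p[i, 2]; zj <- p[j, 2]
      cross <- (zi > g$z) != (zj > g$z)
      xint <- (p[j, 1] - p[i, 1]) * (g$z - zi) / (zj - zi) + p[i, 1]
      ins <- xor(ins, cross & (g$x < xint))
      j <- i
    }
    ins
  }
  sum(inside_of(p) & inside_of(q)) * pitch^2
}

# a unit square expressed as a 20-gon (collinear extra vertices), CCW
square20 <- function(side = 1, origin = c(0, 0)) {
  s <- seq(0, side, length.out = 6L)
  pts <- rbind(
    cbind(s[-6L], 0),
    cbind(side, s[-6L]),
    cbind(rev(s[-1L]), side),
    cbind(0, rev(s[-1L]))
  )
  sweep(pts, 2L, origin, "+")
}

# minimal one/two-nucleus states for mechanics tests
single_nucleus_state <- function(params, center = c(2.5, 1.2),
                                 area = pi / 4, phase = "G1",
                                 anchored = TRUE) {
  n <- new_nucleus(1L, regular_polygon(center, area), phase = phase,
                   phase_entry_time = params$t_start, target_area = area,
                   birth_area = min(area, pi / 4),
                   ax = center[1L], bx = center[1L], anchored = anchored,
                   cable_active = anchored)
  new_state(params$t_start, new_box(params), list(n))
}
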