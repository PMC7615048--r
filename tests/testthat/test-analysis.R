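# Summary statistics on hand-built snapshots and event logs.

# build a minimal snapshot data.frame from a list of (id, phase, center,
# area) specs, with a flat apical boundary at height `apical`
mk_snapshot <- function(specs, time = 90, apical = 3) {
  rows <- lapply(specs, function(s) {
    v <- regular_polygon(s$center, s$area)
    V <- as.vector(t(v))
    names(V) <- paste0(rep(c("x", "z"), 20), rep(1:20, each = 2))
    data.frame(time = time, id = s$id, phase = s$phase,
               cx = s$center[1], cz = s$center[2], area = s$area,
               min_z = min(v[, 2]), max_z = max(v[, 2]), apical_z = apical,
               anchored = TRUE, as.list(V))
  })
  do.call(rbind, rows)
}

mk_traj <- function(snapshots, events = NULL, frames = NULL) {
  structure(list(snapshots = snapshots, events = events, frames = frames,
                 config = model_params(), seed = 1L),
            class = "iknm_trajectory")
}

test_that("phase fractions follow the census definition, M pooled with G2", {
  sn <- mk_snapshot(list(
    list(id = 1, phase = "G1", center = c(1, 1), area = 0.7),
    list(id = 2, phase = "G1", center = c(2, 1), area = 0.7),
    list(id = 3, phase = "S",  center = c(3, 1), area = 0.9),
    list(id = 4, phase = "G2", center = c(4, 1), area = 1.5)))
  pf <- phase_fractions(mk_traj(sn))
  expect_equal(pf$f_G1, 0.5)
  expect_equal(pf$f_S, 0.25)
  expect_equal(pf$f_G2, 0.25)
  expect_equal(pf$f_G1 + pf$f_S + pf$f_G2, 1, tolerance = 1e-9)

  snM <- mk_snapshot(list(
    list(id = 1, phase = "M", center = c(1, 1), area = 1.5),
    list(id = 2, phase = "G1", center = c(2, 1), area = 0.7)))
  pfM <- phase_fractions(mk_traj(snM))
  expect_equal(pfM$f_G2, 0.5)  # M counted with G2
  pfM2 <- phase_fractions(mk_traj(snM), M_with_G2 = FALSE)
  expect_equal(pfM2$f_G2, 0)
})

test_that("apical-basal distribution bins by depth and conserves mass", {
  sn <- mk_snapshot(list(
    list(id = 1, phase = "G1", center = c(1, 2.9), area = 0.5),  # depth 0.1
    list(id = 2, phase = "S",  center = c(2, 2.2), area = 0.5),  # depth 0.8
    list(id = 3, phase = "G2", center = c(3, 0.4), area = 0.5)), # depth 2.6
    apical = 3)
  ab <- ab_distribution(sn)
  expect_equal(sum(ab$fraction), 1, tolerance = 1e-9)
  expect_equal(ab$bin_lo[ab$phase == "G1" & ab$fraction > 0], 0)
  expect_equal(ab$bin_lo[ab$phase == "S" & ab$fraction > 0], 0.5)
  expect_equal(ab$bin_lo[ab$phase == "G2" & ab$fraction > 0], 2.5)
  # marginal consistency with the phase census
  pf <- phase_fractions(mk_traj(sn))
  agg <- tapply(ab$fraction, ab$phase, sum)
  expect_equal(unname(agg["G1"]), pf$f_G1, tolerance = 1e-9)
  expect_equal(unname(agg["G2"]), pf$f_G2, tolerance = 1e-9)
})

test_that("crowding index is 0 when isolated and counts neighbors correctly", {
  fr <- data.frame(time = 90, n = 2, n_G1 = 2, n_S = 0, n_G2 = 0, n_M = 0,
                   xL = 0, xR = 10, h_mean = 3, h_min = 3, h_max = 3)
  sn <- mk_snapshot(list(
    list(id = 1, phase = "G1", center = c(5, 1.5), area = 0.7),
    list(id = 2, phase = "G1", center = c(9, 1.5), area = 0.7)))
  ci <- crowding_indices(mk_traj(sn, frames = fr), time = 90)
  expect_equal(ci$crowding[ci$id == 1], 0)

  # place a neighbor inside the focal rectangle; occupancy is the overlap
  # of the neighbor with the rectangle over the available area
  sn2 <- mk_snapshot(list(
    list(id = 1, phase = "G1", center = c(5, 1.5), area = 0.7),
    list(id = 2, phase = "G1", center = c(5.9, 1.5), area = 0.7)))
  ci2 <- crowding_indices(mk_traj(sn2, frames = fr), time = 90)
  polys <- iknm:::snap_polygons(sn2)
  rect <- cbind(c(5 - 0.75, 5.9, 5.9, 5 - 0.75) * 0 , 0)  # placeholder
  x0 <- min(polys[[1]][, 1]) - 0.75; x1 <- max(polys[[1]][, 1]) + 0.75
  z0 <- max(min(polys[[1]][, 2]) - 0.25, 0)
  z1 <- min(max(polys[[1]][, 2]) + 0.25, 3)
  rect <- cbind(c(x0, x1, x1, x0), c(z0, z0, z1, z1))
  expected <- overlap_area(polys[[2]], rect) /
    ((x1 - x0) * (z1 - z0) - overlap_area(polys[[1]], rect))
  expect_equal(ci2$crowding[ci2$id == 1], expected, tolerance = 1e-9)
  expect_true(all(ci2$crowding >= 0 & ci2$crowding <= 1))

  # border nuclei are excluded
  snB <- mk_snapshot(list(
    list(id = 1, phase = "G1", center = c(0.5, 1.5), area = 0.7)))
  ciB <- crowding_indices(mk_traj(snB, frames = fr), time = 90)
  expect_true(is.null(ciB) || !1 %in% ciB$id)
})

test_that("crowding index saturates at 1 when the neighborhood is tiled", {
  fr <- data.frame(time = 90, n = 1, n_G1 = 1, n_S = 0, n_G2 = 0, n_M = 0,
                   xL = 0, xR = 20, h_mean = 3, h_min = 3, h_max = 3)
  specs <- list(list(id = 1, phase = "G1", center = c(10, 1.5), area = 0.5))
  k <- 2
  for (dx in seq(-2, 2, by = 0.55)) for (dz in seq(-1.4, 1.4, by = 0.55)) {
    if (abs(dx) < 0.5 && abs(dz) < 0.5) next
    specs[[length(specs) + 1]] <- list(id = k, phase = "G1",
                                       center = c(10 + dx, 1.5 + dz),
                                       area = 0.5)
    k <- k + 1
  }
  sn <- mk_snapshot(specs)
  ci <- crowding_indices(mk_traj(sn, frames = fr), time = 90)
  expect_gt(ci$crowding[ci$id == 1], 0.9)
  expect_lte(ci$crowding[ci$id == 1], 1)
})

test_that("G2 durations and arrests partition the set of G2 entries", {
  ev <- data.frame(
    time  = c(80, 84, 85, 90, 100, 101),
    event = c("SG2", "DIVISION", "SG2", "SG2", "DIVISION", "SG2"),
    id    = c(1L, 1L, 2L, 3L, 3L, 4L),
    parent_id = NA_integer_, x = 0, z = 0)
  gd <- g2_durations(ev)
  expect_equal(sort(gd$durations$duration), c(4, 10))
  expect_equal(gd$durations$g2_entry[gd$durations$id == 1], 80)
  ga <- g2_arrested(ev, t_end = 116)
  expect_equal(max(ga$cumulative), 2)   # ids 2 and 4 never divide
  expect_true(all(diff(ga$cumulative) >= 0))
  expect_equal(nrow(gd$durations) + max(ga$cumulative),
               sum(ev$event == "SG2"))

  # orphan DIVISION without SG2 errors
  bad <- rbind(ev, data.frame(time = 105, event = "DIVISION", id = 9L,
                              parent_id = NA_integer_, x = 0, z = 0))
  expect_error(g2_durations(bad), "orphan")

  # a log where every G2 divides yields an all-zero arrest series
  ok <- ev[ev$id %in% c(1L, 3L), ]
  ga2 <- g2_arrested(ok, t_end = 116)
  expect_true(all(ga2$cumulative == 0))
})

test_that("terminal velocity recovers hand-computed finite differences", {
  # nucleus 1 rises 1 G1d over the final hour; nucleus 2 is stationary
  times <- seq(80, 84, by = 0.25)
  sn <- do.call(rbind, lapply(times, function(tm) {
    mk_snapshot(list(
      list(id = 1, phase = "G2", center = c(2, 1 + max(0, tm - 83) * 1), area = 1),
      list(id = 2, phase = "G2", center = c(4, 1), area = 1)),
      time = tm)
  }))
  ev <- data.frame(time = c(84, 84), event = "DIVISION", id = c(1L, 2L),
                   parent_id = NA_integer_, x = 0, z = 0)
  # pad with two more dividing nuclei so the fit has enough points
  sn2 <- do.call(rbind, lapply(times, function(tm) {
    mk_snapshot(list(
      list(id = 3, phase = "G2", center = c(6, 1 + max(0, tm - 83) * 0.5), area = 1),
      list(id = 4, phase = "G2", center = c(8, 1 + max(0, tm - 83) * 0.25), area = 1)),
      time = tm)
  }))
  ev2 <- data.frame(time = c(84, 84), event = "DIVISION", id = c(3L, 4L),
                    parent_id = NA_integer_, x = 0, z = 0)
  tr <- mk_traj(rbind(sn, sn2), events = rbind(ev, ev2))
  tv <- terminal_velocity(tr)
  v <- setNames(tv$velocities$velocity, tv$velocities$id)
  expect_equal(unname(v["1"]), 1, tolerance = 1e-9)
  expect_equal(unname(v["2"]), 0, tolerance = 1e-9)
  expect_equal(unname(v["3"]), 0.5, tolerance = 1e-9)

  # too coarse a cadence errors with a clear message
  coarse <- mk_traj(sn[sn$time %in% c(80, 81, 82, 83, 84), ], events = ev)
  expect_error(terminal_velocity(coarse), "cadence")
})

test_that("thickness and layer estimates match constructed layering", {
  fr <- data.frame(time = 90, n = 8, n_G1 = 8, n_S = 0, n_G2 = 0, n_M = 0,
                   xL = 0, xR = 10, h_mean = 3, h_min = 3, h_max = 3)
  one <- mk_snapshot(lapply(1:8, function(i)
    list(id = i, phase = "G1", center = c(i, 0.5), area = pi / 4)))
  tl1 <- thickness_and_layers(mk_traj(one, frames = fr), time = 90)
  expect_equal(tl1$layers, 1, tolerance = 0.35)

  two <- mk_snapshot(c(
    lapply(1:4, function(i) list(id = i, phase = "G1", center = c(i, 0.5), area = pi / 4)),
    lapply(5:8, function(i) list(id = i, phase = "G1", center = c(i - 4, 1.5), area = pi / 4))))
  tl2 <- thickness_and_layers(mk_traj(two, frames = fr), time = 90)
  expect_equal(tl2$layers, 2, tolerance = 0.35)
  expect_gt(tl2$layers, tl1$layers)

  # the occupied span is invariant to lateral translation
  two_sh <- two; two_sh$cx <- two_sh$cx + 3
  tl3 <- thickness_and_layers(mk_traj(two_sh, frames = fr), time = 90)
  expect_equal(tl3$span, tl2$span, tolerance = 1e-12)
})

test_that("shape index has its closed form and penalizes elongation", {
  p <- regular_polygon(c(0, 0), pi / 4)
  R <- sqrt(2 * (pi / 4) / (20 * sin(2 * pi / 20)))
  expect_equal(shape_index(p), (pi / 4) / (2 * R), tolerance = 1e-12)
  # stretch at fixed area: index strictly decreases
  s <- 1.6
  p_ell <- cbind(p[, 1] * s, p[, 2] / s)
  expect_lt(shape_index(p_ell), shape_index(p))
})
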