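# Phase state machine: timers, gates, growth, division bookkeeping.

test_that("S durations are uniform on mean +/- halfwidth and reproducible", {
  p <- model_params()
  set.seed(31)
  draws <- replicate(1e5, draw_S_duration(p))
  expect_gte(min(draws), 6)
  expect_lte(max(draws), 10)
  # mean of U[6,10] is 8 with sd 2/sqrt(12); 3 sigma band for 1e5 draws
  expect_lt(abs(mean(draws) - 8), 3 * (2 / sqrt(3)) / sqrt(1e5))

  set.seed(42); a <- replicate(10, draw_S_duration(p))
  set.seed(42); b <- replicate(10, draw_S_duration(p))
  expect_identical(a, b)

  p0 <- model_params(S_halfwidth = 0)
  expect_equal(draw_S_duration(p0), 8)
})

test_that("G1 duration ramps linearly from 2 h to 10 h over the run", {
  p <- model_params()
  expect_equal(g1_duration_at(72, p), 2)
  expect_equal(g1_duration_at(116, p), 10)
  expect_equal(g1_duration_at(94, p), 6)
  expect_warning(g1_duration_at(200, p), "clamped")
  expect_equal(suppressWarnings(g1_duration_at(200, p)), 10)
})

test_that("target area doubles during S only, linearly in elapsed time", {
  p <- model_params()
  n <- new_nucleus(1L, regular_polygon(c(2, 1), pi / 4), phase = "S",
                   phase_entry_time = 80, S_duration = 8,
                   target_area = pi / 4, birth_area = pi / 4)
  expect_equal(update_target_area(n, 80, p), pi / 4)
  expect_equal(update_target_area(n, 84, p), 1.5 * pi / 4)
  expect_equal(update_target_area(n, 88, p), 2 * pi / 4)
  expect_equal(update_target_area(n, 95, p), 2 * pi / 4)  # capped

  nG2 <- n; nG2$phase <- "G2"; nG2$target_area <- 0.9
  expect_equal(update_target_area(nG2, 90, p), 0.9)  # frozen outside S
})

test_that("the basal gate opens within range lambda and is monotone in lambda", {
  n_low <- new_nucleus(1L, regular_polygon(c(2, 0.5), pi / 4))
  n_high <- new_nucleus(2L, regular_polygon(c(2, 5.5), pi / 4))
  expect_true(basal_signal_gate(n_low, lambda = 2))
  expect_false(basal_signal_gate(n_high, lambda = 2))
  expect_true(basal_signal_gate(n_high, lambda = 10))
  set.seed(32)
  for (k in 1:50) {
    n <- new_nucleus(1L, regular_polygon(c(2, runif(1, 0.6, 8)), pi / 4))
    l1 <- runif(1, 0, 6); l2 <- l1 + runif(1, 0, 6)
    expect_false(basal_signal_gate(n, l1) && !basal_signal_gate(n, l2))
  }
})

test_that("phase transitions follow the automaton with their gates", {
  p <- model_params()
  box_state <- single_nucleus_state(p, center = c(2.5, 1))

  # timer-mode G1 entered at t_start advances to S after exactly G1_start h
  n <- box_state$nuclei[[1]]
  st <- box_state; st$t <- 72 + 1.99
  set.seed(33)
  expect_identical(advance_phase(n, st, p)$nucleus$phase, "G1")
  st$t <- 72 + 2.001
  res <- advance_phase(n, st, p)
  expect_identical(res$nucleus$phase, "S")
  expect_identical(res$events$event, "G1S")
  expect_true(res$nucleus$S_duration >= 6 && res$nucleus$S_duration <= 10)

  # S -> G2 exactly doubles the target
  nS <- res$nucleus
  st$t <- nS$phase_entry_time + nS$S_duration + 1e-6
  res2 <- advance_phase(nS, st, p)
  expect_identical(res2$nucleus$phase, "G2")
  expect_equal(res2$nucleus$target_area, 2 * nS$birth_area)

  # G2 without apical contact stays G2 forever (no timer)
  nG2 <- res2$nucleus
  st$t <- st$t + 30
  expect_identical(advance_phase(nG2, st, p)$nucleus$phase, "G2")

  # G2 touching the apical boundary with centroid in the gate enters M,
  # and the cable is inactivated (mitotic rounding)
  nTop <- nG2
  shift <- apical_height_at(st$box, 2.5) - max(nTop$verts[, 2])
  nTop$verts <- sweep(nTop$verts, 2, c(0, shift), "+")
  res3 <- advance_phase(nTop, st, p)
  expect_identical(res3$nucleus$phase, "M")
  expect_false(res3$nucleus$cable_active)
  expect_equal(res3$nucleus$m_end, st$t + p$M_duration)

  # basal-gate mode: a G1 nucleus beyond lambda never starts S
  pb <- model_params(mode = "basal_gate", lambda = 2)
  nFar <- new_nucleus(5L, regular_polygon(c(2.5, 4), pi / 4),
                      phase = "G1", phase_entry_time = 0, ax = 2.5, bx = 2.5)
  stb <- st; stb$box$h <- rep(6, length(stb$box$h))
  expect_identical(advance_phase(nFar, stb, pb)$nucleus$phase, "G1")
})

test_that("division conserves area and anchors exactly one daughter", {
  p <- model_params()
  set.seed(34)
  for (k in 1:20) {
    A <- runif(1, 0.8, 1.7)
    m <- new_nucleus(7L, regular_polygon(runif(2, 1.5, 2.5), A),
                     phase = "M", target_area = A, birth_area = A / 2,
                     ax = 2, bx = 2, m_end = 79.9)
    d <- divide_nucleus(m, t = 80, params = p, ids = c(10L, 11L))
    areas <- vapply(d$daughters, function(x) polygon_area(x$verts), 0)
    expect_equal(sum(areas), A, tolerance = 1e-9)
    expect_equal(areas[1], areas[2], tolerance = 1e-9)
    anch <- vapply(d$daughters, `[[`, TRUE, "anchored")
    expect_identical(sum(anch), 1L)
    expect_true(all(vapply(d$daughters, `[[`, "", "phase") == "G1"))
    expect_true(all(vapply(d$daughters, function(x)
      abs(x$birth_area - A / 2) < 1e-12, TRUE)))
    un <- d$daughters[[which(!anch)]]
    expect_true(min(abs((un$reanchor_time - 80) - p$reanchor_delays)) < 1e-12)
    expect_false(un$cable_active)
    expect_true(all(vapply(d$daughters, function(x) is_convex(x$verts), TRUE)))
  }
  expect_error(divide_nucleus(new_nucleus(1L, regular_polygon(c(1, 1), 1)),
                              80, p, c(2L, 3L)), "not in M")
})

test_that("both reanchoring delays occur across many divisions", {
  p <- model_params()
  set.seed(35)
  m <- new_nucleus(1L, regular_polygon(c(2, 2), 1.2), phase = "M",
                   target_area = 1.2, birth_area = 0.6, ax = 2, bx = 2,
                   m_end = 0)
  delays <- replicate(200, {
    d <- divide_nucleus(m, t = 80, params = p, ids = c(2L, 3L))
    un <- Filter(function(x) !x$anchored, d$daughters)[[1]]
    un$reanchor_time - 80
  })
  expect_setequal(round(sort(unique(delays)), 6), round(p$reanchor_delays, 6))
  # fair draw: both options occur with roughly equal frequency
  expect_gt(min(table(round(delays, 6))), 60)
})

test_that("an unanchored daughter re-anchors at its scheduled time", {
  p <- model_params()
  st <- single_nucleus_state(p, center = c(2.5, 1))
  n <- st$nuclei[[1]]
  n$anchored <- FALSE; n$cable_active <- FALSE
  n$phase_entry_time <- 79.9  # fresh G1, timer far from firing
  n$reanchor_time <- 80.05; n$ax <- NA_real_; n$bx <- NA_real_
  st$t <- 80.0
  r1 <- advance_phase(n, st, p)
  expect_false(r1$nucleus$anchored)
  st$t <- 80.05
  r2 <- advance_phase(n, st, p)
  expect_true(r2$nucleus$anchored)
  expect_true(r2$nucleus$cable_active)
  expect_identical(r2$events$event, "REANCHOR")
  expect_equal(r2$nucleus$ax, polygon_centroid(n$verts)[1], tolerance = 1e-9)
})
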