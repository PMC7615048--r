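# Energy terms against closed forms; analytic gradient against central
# differences; the constrained minimizer's contracts.

params0 <- model_params()

test_that("deformation energy vanishes at the rest shape and grows off it", {
  st <- single_nucleus_state(params0)
  n <- st$nuclei[[1]]
  expect_equal(deformation_energy(n, params0), 0, tolerance = 1e-20)

  n2 <- n
  n2$verts <- iknm:::scale_to_area(n$verts, 1.5 * n$target_area)
  expect_gt(deformation_energy(n2, params0), 0)

  # line scan: energy decreases monotonically back toward the rest shape
  set.seed(11)
  for (k in 1:5) {
    stretch <- n$verts + matrix(rnorm(40, sd = 0.08), ncol = 2)
    es <- vapply(seq(1, 0, length.out = 11), function(a) {
      nn <- n; nn$verts <- n$verts + a * (stretch - n$verts)
      deformation_energy(nn, params0)
    }, 0)
    expect_true(all(diff(es) <= 1e-12))
  }
})

test_that("cable energy follows the point-segment form and gates on activity", {
  p <- model_params()
  box <- new_box(p)
  # all vertices on the cable line -> 0 (degenerate polygon, bypass ctor)
  n <- single_nucleus_state(p)$nuclei[[1]]
  n$ax <- 2.5; n$bx <- 2.5
  flat <- cbind(rep(2.5, 20), seq(0.5, 2, length.out = 20))
  n_flat <- n; n_flat$verts <- flat
  expect_equal(cable_energy(n_flat, box, p), 0, tolerance = 1e-20)

  # single vertex at perpendicular distance d, rest on the cable
  d <- 0.37
  v <- flat; v[7, 1] <- 2.5 + d
  n_one <- n; n_one$verts <- v
  expect_equal(cable_energy(n_one, box, p), p$k_cable * d^2 / 2,
               tolerance = 1e-12)

  # inactive cable -> 0 regardless of geometry
  n_off <- n_one; n_off$cable_active <- FALSE
  expect_equal(cable_energy(n_off, box, p), 0)
  n_un <- n_one; n_un$anchored <- FALSE
  expect_equal(cable_energy(n_un, box, p), 0)
})

test_that("apical spring acts only on G2 nuclei without apical contact", {
  p <- model_params()
  box <- new_box(p)
  st <- single_nucleus_state(p, center = c(2.5, 1), phase = "G1")
  expect_equal(apical_spring_energy(st$nuclei[[1]], box, p), 0)

  stG2 <- single_nucleus_state(p, center = c(2.5, 1), phase = "G2")
  n <- stG2$nuclei[[1]]
  ctr <- colMeans(n$verts)
  d2 <- sum((ctr - c(n$ax, apical_height_at(box, n$ax)))^2)
  expect_equal(apical_spring_energy(n, box, p), p$k_spring * d2 / 2,
               tolerance = 1e-12)

  # a vertex touching the apical boundary switches the spring off
  n_top <- n
  n_top$verts <- sweep(n$verts, 2, c(0, box$h0 - max(n$verts[, 2])), "+")
  expect_equal(apical_spring_energy(n_top, box, p), 0)
})

test_that("box energy is zero at rest and quadratic in uniform apical displacement", {
  p <- model_params()
  box <- new_box(p)
  expect_equal(box_energy(box, p), 0)
  delta <- 0.23
  box2 <- box; box2$h <- box$h + delta
  expect_equal(box_energy(box2, p),
               p$k_box_apical / 2 * length(box$h) * delta^2,
               tolerance = 1e-12)
  # relabeling symmetry: reversing the chain leaves the energy unchanged
  box3 <- box2; box3$h <- rev(box3$h)
  expect_equal(box_energy(box3, p), box_energy(box2, p))
})

test_that("gradient-flow energy has the implicit-Euler form", {
  p <- model_params()
  st <- single_nucleus_state(p)
  expect_equal(gradient_flow_energy(st, st, p), 0)
  st2 <- st
  d <- 0.11
  st2$nuclei[[1]]$verts[3, 2] <- st2$nuclei[[1]]$verts[3, 2] + d
  expect_equal(gradient_flow_energy(st, st2, p),
               p$eta * d^2 / (2 * p$dt), tolerance = 1e-12)
  # doubling dt halves the energy of a fixed displacement
  p2 <- model_params(dt = 2 * p$dt)
  expect_equal(gradient_flow_energy(st, st2, p2),
               gradient_flow_energy(st, st2, p) / 2, tolerance = 1e-12)
  # topology mismatch
  st3 <- st
  st3$nuclei[[1]]$id <- 99L
  expect_error(gradient_flow_energy(st, st3, p), "topology")
})

test_that("R total_energy and the compiled energy agree exactly", {
  p <- model_params()
  set.seed(21)
  st <- seed_initial_state(p)
  a <- iknm:::mech_args(st, p)
  Ec <- iknm:::cpp_energy(a$V, a$bx, a$ax, a$ay, a$cable_on, a$spring_on,
                          a$is_M, a$target_area, a$h, a$hx, a$xL, a$xR,
                          a$par)
  expect_equal(total_energy(st, NULL, p), Ec, tolerance = 1e-12)

  # additivity: two far-apart nuclei sum their single-nucleus energies
  s1 <- single_nucleus_state(p, center = c(1, 1))
  s2 <- single_nucleus_state(p, center = c(4, 1))
  s12 <- s1
  n2 <- s2$nuclei[[1]]; n2$id <- 2L
  s12$nuclei <- list(s1$nuclei[[1]], n2)
  expect_equal(total_energy(s12, NULL, p),
               total_energy(s1, NULL, p) + total_energy(s2, NULL, p),
               tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  p <- model_params()
  set.seed(22)
  st <- seed_initial_state(p)
  st$nuclei[[2]]$phase <- "G2"   # exercise the spring term
  a <- iknm:::mech_args(st, p)
  Vp <- a$V + matrix(rnorm(length(a$V), sd = 5e-3), ncol = 2)
  args <- function(V) list(V, a$bx, a$ax, a$ay, a$cable_on, a$spring_on,
                           a$is_M, a$target_area, a$h, a$hx, a$xL, a$xR,
                           a$par)
  g <- do.call(iknm:::cpp_gradient, c(args(Vp), list(Vprev = a$V)))
  h <- 1e-6
  idx <- c(1, 7, 33, 80, 155, 301)  # a spread of vertex coordinates
  for (q in idx) {
    r <- (q - 1) %/% 2 + 1; cc <- (q - 1) %% 2 + 1
    Va <- Vp; Va[r, cc] <- Va[r, cc] + h
    Vb <- Vp; Vb[r, cc] <- Vb[r, cc] - h
    Ea <- do.call(iknm:::cpp_energy, c(args(Va), list(Vprev = a$V)))
    Eb <- do.call(iknm:::cpp_energy, c(args(Vb), list(Vprev = a$V)))
    fd <- (Ea - Eb) / (2 * h)
    expect_equal(g[q], fd, tolerance = 1e-5)
  }
})

test_that("constraint_residuals flags overlap, protrusion and area errors", {
  p <- model_params()
  st <- single_nucleus_state(p)
  r <- constraint_residuals(st, p)
  expect_true(r$feasible)

  # two coincident nuclei: overlap residual equals the polygon area
  st2 <- st
  n2 <- st$nuclei[[1]]; n2$id <- 2L
  st2$nuclei <- list(st$nuclei[[1]], n2)
  r2 <- constraint_residuals(st2, p)
  expect_equal(max(r2$max_overlap), pi / 4, tolerance = 1e-9)
  expect_false(r2$feasible)

  # nucleus straddling the basal line: protrusion equals the half-plane clip
  st3 <- single_nucleus_state(p, center = c(2.5, 0))
  r3 <- constraint_residuals(st3, p)
  expect_equal(r3$protrusion[1], pi / 8, tolerance = 1e-9)
})

test_that("a single resting nucleus is a fixed point of minimize_state", {
  p <- model_params()
  st <- single_nucleus_state(p, center = c(2.5, 1.2))
  st2 <- minimize_state(st, p)
  ctr1 <- polygon_centroid(st$nuclei[[1]]$verts)
  ctr2 <- polygon_centroid(st2$nuclei[[1]]$verts)
  expect_lt(sqrt(sum((ctr2 - ctr1)^2)), 1e-3)
})

test_that("a lone G2 nucleus migrates apically until contact", {
  p <- model_params()
  st <- single_nucleus_state(p, center = c(2.5, 1), area = pi / 2,
                             phase = "G2")
  st$nuclei[[1]]$birth_area <- pi / 4
  zs <- polygon_centroid(st$nuclei[[1]]$verts)[2]
  for (k in 1:60) {
    st <- minimize_state(st, p)
    z <- polygon_centroid(st$nuclei[[1]]$verts)[2]
    if (iknm:::apical_contact(st$nuclei[[1]], st$box, p$tol_apical)) break
    expect_gt(z, zs - 1e-9)  # monotone apical-ward
    zs <- z
  }
  expect_true(iknm:::apical_contact(st$nuclei[[1]], st$box, p$tol_apical))
})

test_that("two overlapping nuclei are separated symmetrically", {
  p <- model_params()
  mkst <- function() {
    n1 <- new_nucleus(1L, regular_polygon(c(2.2, 1.2), pi / 4),
                      target_area = pi / 4, ax = 2.2, bx = 2.2)
    n2 <- new_nucleus(2L, regular_polygon(c(2.8, 1.2), pi / 4),
                      target_area = pi / 4, ax = 2.8, bx = 2.8)
    new_state(72, new_box(p), list(n1, n2))
  }
  st <- mkst()
  expect_gt(overlap_area(st$nuclei[[1]]$verts, st$nuclei[[2]]$verts), 0.01)
  st2 <- suppressWarnings(minimize_state(st, p))
  expect_lte(overlap_area(st2$nuclei[[1]]$verts, st2$nuclei[[2]]$verts),
             p$tol_constraint)
  # the mirrored initial condition produces the mirrored outcome
  mirror <- function(state) {
    W <- state$box$W0
    state$nuclei <- lapply(rev(state$nuclei), function(n) {
      n$verts <- cbind(W - n$verts[, 1], n$verts[, 2])[20:1, ]
      n$ax <- W - n$ax; n$bx <- W - n$bx
      n
    })
    state
  }
  # mirrored runs agree to within the solver's position resolution
  # (polish step scale), not to machine precision: floating-point
  # summation order differs between the two orientations
  stM <- suppressWarnings(minimize_state(mirror(mkst()), p))
  c2 <- polygon_centroid(st2$nuclei[[1]]$verts)
  c2M <- polygon_centroid(stM$nuclei[[2]]$verts)
  expect_lt(abs(c2[1] - (p$box_width - c2M[1])), 0.02)
  expect_lt(abs(c2[2] - c2M[2]), 0.02)
})

test_that("minimize_state descends energy and restores feasibility per step", {
  p <- model_params()
  set.seed(23)
  st <- seed_initial_state(p)
  for (k in 1:10) {
    # non-convergence warnings on stiff early steps are informational;
    # the descent and feasibility invariants below are what must hold
    s <- suppressWarnings(step(st, p))
    m <- attr(s$state, "mech")
    expect_lte(m$objective, m$objective_ref + 1e-9)
    expect_true(m$residuals$feasible)
    st <- s$state
  }
})

test_that("minimize_state is deterministic", {
  p <- model_params()
  set.seed(24)
  st <- seed_initial_state(p)
  a <- suppressWarnings(minimize_state(st, p))
  b <- suppressWarnings(minimize_state(st, p))
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$box, b$box)
})
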