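# Energy functional, constraints, and the per-step constrained
# minimization. The R functions here define the model term by term (and are
# what the documentation and tests refer to); the compiled code in
# src/mechanics.cpp evaluates the identical forms inside the minimizer, and
# the test suite asserts exact agreement between the two routes.

#' Nuclear deformation energy
#'
#' Edge-spring regularization about the regular rest 20-gon of the
#' nucleus's current target area:
#' `k_deform/2 * sum_e (l_e - l*)^2`, where `l*` is the edge length of the
#' regular 20-gon with area `target_area`. Zero exactly at the rest shape.
#'
#' @param nucleus an `iknm_nucleus`.
#' @param params an `iknm_params`.
#' @return energy (model units).
#' @export
deformation_energy <- function(nucleus, params) {
  v <- nucleus$verts
  n <- nrow(v)
  l0 <- sqrt(4 * nucleus$target_area * tan(pi / n) / n)
  e <- v[c(2:n, 1L), , drop = FALSE] - v
  len <- sqrt(rowSums(e^2))
  params$k_deform / 2 * sum((len - l0)^2)
}

# internal: stiff area-conservation penalty (the equality constraint is
# finished off by an exact projection after each minimization)
#' @keywords internal
area_penalty_energy <- function(nucleus, params) {
  dA <- polygon_area(nucleus$verts) - nucleus$target_area
  params$k_area / 2 * dA^2
}

# internal: convexity penalty on negative consecutive-edge cross products
#' @keywords internal
convexity_penalty_energy <- function(nucleus, params) {
  if (params$k_convex <= 0) return(0)
  v <- nucleus$verts
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  e <- v[nxt, , drop = FALSE] - v
  cr <- e[, 1L] * e[nxt, 2L] - e[, 2L] * e[nxt, 1L]
  params$k_convex / 2 * sum(pmin(cr, 0)^2)
}

#' Cable-to-nuclei energy
#'
#' Quadratic attraction of all 20 vertices to the virtual apical-to-basal
#' cable: `k_cable/2 * sum_v dist(v, [a, b])^2` with `a = (ax, apical(ax))`
#' and `b = (bx, 0)`. Returns 0 when the cable is inactive (mitotic
#' rounding) or the nucleus is unanchored.
#'
#' @inheritParams deformation_energy
#' @param box the `iknm_box` (supplies the apical anchor height).
#' @export
cable_energy <- function(nucleus, box, params) {
  if (!isTRUE(nucleus$anchored) || !isTRUE(nucleus$cable_active)) return(0)
  a <- c(nucleus$ax, apical_height_at(box, nucleus$ax))
  b <- c(nucleus$bx, 0)
  if (sum((a - b)^2) == 0) stop("degenerate cable: coincident anchors")
  d <- apply(nucleus$verts, 1L, point_segment_distance, a = a, b = b)
  params$k_cable / 2 * sum(d^2)
}

#' Apical pulling-spring energy (G2 only)
#'
#' A zero-rest-length spring from the nucleus's centre of mass (vertex
#' mean) to the apical cable anchor, representing the active apical-ward
#' force on G2 nuclei. Inactive for non-G2 phases and inactivated as soon
#' as any vertex reaches the apical boundary (within `tol_apical`).
#'
#' @inheritParams cable_energy
#' @export
apical_spring_energy <- function(nucleus, box, params) {
  if (nucleus$phase != "G2" || !isTRUE(nucleus$anchored) ||
      !isTRUE(nucleus$cable_active)) return(0)
  if (apical_contact(nucleus, box, params$tol_apical)) return(0)
  a <- c(nucleus$ax, apical_height_at(box, nucleus$ax))
  ctr <- colMeans(nucleus$verts)
  params$k_spring / 2 * sum((ctr - a)^2)
}

#' Box elasticity energy
#'
#' Quadratic penalty of the apical control heights about the rest height
#' `h0`, a second-difference curvature penalty along the apical chain, and
#' quadratic penalties of the lateral wall positions about the rest width.
#'
#' @param box an `iknm_box`.
#' @param params an `iknm_params`.
#' @export
box_energy <- function(box, params) {
  h <- box$h
  m <- length(h)
  e <- params$k_box_apical / 2 * sum((h - box$h0)^2)
  if (m >= 3L) {
    d2 <- h[1:(m - 2L)] - 2 * h[2:(m - 1L)] + h[3:m]
    e <- e + params$k_box_curv / 2 * sum(d2^2)
  }
  e + params$k_box_lateral / 2 * (box$xL^2 + (box$xR - box$W0)^2)
}

#' Gradient-flow (friction) energy between two states
#'
#' `eta/(2 dt) * sum |v - v_prev|^2` over all nucleus vertices; the term
#' that makes each per-step minimization an implicit-Euler gradient flow
#' and prevents large movements in a single iteration.
#'
#' @param state_prev,state_candidate `iknm_state` objects sharing topology
#'   (same nuclei in the same order).
#' @param params an `iknm_params`.
#' @export
gradient_flow_energy <- function(state_prev, state_candidate, params) {
  idp <- vapply(state_prev$nuclei, `[[`, 0L, "id")
  idc <- vapply(state_candidate$nuclei, `[[`, 0L, "id")
  if (length(idp) != length(idc) || any(idp != idc))
    stop("topology mismatch: states do not share the same nuclei")
  s <- 0
  for (i in seq_along(idp))
    s <- s + sum((state_candidate$nuclei[[i]]$verts -
                  state_prev$nuclei[[i]]$verts)^2)
  params$eta / (2 * params$dt) * s
}

# internal: one-sided penalties (containment, mitotic zone) in R,
# mirroring the compiled forms
#' @keywords internal
containment_penalty_energy <- function(state, params) {
  box <- state$box
  e <- 0
  for (n in state$nuclei) {
    x <- n$verts[, 1L]; z <- n$verts[, 2L]
    ha <- apical_height_at(box, x)
    e <- e + params$k_contact / 2 * (sum(pmin(z, 0)^2) +
                                     sum(pmax(z - ha, 0)^2) +
                                     sum(pmax(box$xL - x, 0)^2) +
                                     sum(pmax(x - box$xR, 0)^2))
    if (n$phase != "M")
      e <- e + params$k_mz / 2 * sum(pmax(z - (ha - box$d_mz), 0)^2)
  }
  e
}

# internal: pairwise overlap penalty on penetrating vertices
#' @keywords internal
overlap_penalty_energy <- function(state, params) {
  nuc <- state$nuclei
  n <- length(nuc)
  if (n < 2L) return(0)
  e <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    vi <- nuc[[i]]$verts; vj <- nuc[[j]]$verts
    if (max(vi[, 1L]) < min(vj[, 1L]) || max(vj[, 1L]) < min(vi[, 1L]) ||
        max(vi[, 2L]) < min(vj[, 2L]) || max(vj[, 2L]) < min(vi[, 2L])) next
    e <- e + .pen_vertices(vi, vj, params$k_overlap) +
             .pen_vertices(vj, vi, params$k_overlap)
  }
  e
}

#' @keywords internal
.pen_vertices <- function(va, vb, k) {
  e <- 0
  nb <- nrow(vb)
  for (r in seq_len(nrow(va))) {
    pt <- va[r, ]
    if (!point_in_polygon(pt, vb)) next
    d <- min(vapply(seq_len(nb), function(q) {
      point_segment_distance(pt, vb[q, ], vb[if (q == nb) 1L else q + 1L, ])
    }, 0))
    e <- e + k / 2 * d^2
  }
  e
}

# crossing-number point-in-polygon test
#' @keywords internal
point_in_polygon <- function(pt, p) {
  n <- nrow(p)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    zi <- p[i, 2L]; zj <- p[j, 2L]
    if ((zi > pt[2L]) != (zj > pt[2L]) &&
        pt[1L] < (p[j, 1L] - p[i, 1L]) * (pt[2L] - zi) / (zj - zi) + p[i, 1L])
      inside <- !inside
    j <- i
  }
  inside
}

#' Total energy of a state
#'
#' Sum of box elasticity, all nuclear deformation energies, all
#' cable-to-nuclei energies, all G2 apical-spring energies, the soft
#' area-conservation / containment / mitotic-zone / overlap penalties, and
#' (when `state_prev` is given) the gradient-flow term. This is exactly
#' the objective minimized at every step.
#'
#' @param state the candidate `iknm_state`.
#' @param state_prev the previous equilibrium (`NULL` drops the
#'   gradient-flow term).
#' @param params an `iknm_params`.
#' @return total energy (model units).
#' @export
total_energy <- function(state, state_prev = NULL, params) {
  e <- box_energy(state$box, params)
  for (n in state$nuclei) {
    e <- e + deformation_energy(n, params) + area_penalty_energy(n, params) +
      convexity_penalty_energy(n, params) +
      cable_energy(n, state$box, params) +
      apical_spring_energy(n, state$box, params)
  }
  e <- e + containment_penalty_energy(state, params) +
    overlap_penalty_energy(state, params)
  if (!is.null(state_prev))
    e <- e + gradient_flow_energy(state_prev, state, params)
  e
}

# polygon tracing the interior of the box (CCW): basal edge, right wall,
# apical chain, left wall
#' @keywords internal
box_polygon <- function(box) {
  inner <- box$hx > box$xL & box$hx < box$xR
  ap_x <- c(box$xR, rev(box$hx[inner]), box$xL)
  ap_h <- c(apical_height_at(box, box$xR), rev(box$h[inner]),
            apical_height_at(box, box$xL))
  rbind(c(box$xL, 0), c(box$xR, 0), cbind(ap_x, ap_h))
}

# area of `p` clipped to the half-plane left of the directed line a -> b
#' @keywords internal
.halfplane_area <- function(p, a, b) {
  r <- clip_halfplane(p, a, b)
  if (is.null(r)) 0 else abs(polygon_area(r))
}

# area of a nucleus polygon lying outside the box: below the basal line,
# beyond either wall, or above the apical chain. The outside regions are
# clipped to disjoint pieces so the total is exact.
#' @keywords internal
protrusion_area <- function(p, box) {
  out <- 0
  # beyond the walls (full height)
  out <- out + .halfplane_area(p, c(box$xL, 0), c(box$xL, 1))  # x < xL
  out <- out + .halfplane_area(p, c(box$xR, 1), c(box$xR, 0))  # x > xR
  # clip the rest to the wall strip first, so pieces stay disjoint
  q <- clip_halfplane(p, c(box$xL, 1), c(box$xL, 0))
  if (!is.null(q)) q <- clip_halfplane(q, c(box$xR, 0), c(box$xR, 1))
  if (is.null(q)) return(out)
  # below the basal line
  out <- out + .halfplane_area(q, c(1, 0), c(0, 0))
  # above each apical segment (within its vertical strip), including the
  # constant extensions beyond the ends of the control grid
  hx <- box$hx; h <- box$h
  m <- length(hx)
  xs <- c(box$xL, hx, box$xR)
  hs <- c(h[1L], h, h[m])
  for (k in seq_len(length(xs) - 1L)) {
    x0 <- xs[k]; x1 <- xs[k + 1L]
    if (x1 <= x0) next
    s <- clip_halfplane(q, c(x0, 1), c(x0, 0))
    if (is.null(s)) next
    s <- clip_halfplane(s, c(x1, 0), c(x1, 1))
    if (is.null(s)) next
    # above the segment: left of the directed line (x0,h0) -> (x1,h1)
    out <- out + .halfplane_area(s, c(x0, hs[k]), c(x1, hs[k + 1L]))
  }
  out
}

#' Constraint residuals of a state
#'
#' Measures how well a state fulfils the model's constraints: per-nucleus
#' area error `|A - target|`, convexity violation (most negative
#' consecutive-edge cross product, scaled), protrusion area outside the
#' box, maximum pairwise overlap area, and box deformation (apical height
#' and wall displacement from rest).
#'
#' @param state an `iknm_state`.
#' @param params an `iknm_params`.
#' @return a list with per-nucleus vectors (`area_error`, `protrusion`,
#'   `max_overlap`, `convex`) plus box residuals and the overall
#'   `feasible` flag at `tol_constraint`.
#' @export
constraint_residuals <- function(state, params) {
  nuc <- state$nuclei
  n <- length(nuc)
  tol <- params$tol_constraint
  area_error <- numeric(n); protrusion <- numeric(n)
  convex <- logical(n); max_ov <- numeric(n)
  for (i in seq_len(n)) {
    v <- nuc[[i]]$verts
    A <- polygon_area(v)
    area_error[i] <- abs(A - nuc[[i]]$target_area)
    convex[i] <- is_convex(v, tol = params$convex_tol)
    protrusion[i] <- protrusion_area(v, state$box)
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      vi <- nuc[[i]]$verts; vj <- nuc[[j]]$verts
      if (max(vi[, 1L]) < min(vj[, 1L]) || max(vj[, 1L]) < min(vi[, 1L]) ||
          max(vi[, 2L]) < min(vj[, 2L]) || max(vj[, 2L]) < min(vi[, 2L])) next
      ov <- overlap_area(vi, vj)
      max_ov[i] <- max(max_ov[i], ov)
      max_ov[j] <- max(max_ov[j], ov)
    }
  }
  box_dev <- c(apical = max(abs(state$box$h - state$box$h0)),
               walls = max(abs(state$box$xL),
                           abs(state$box$xR - state$box$W0)))
  list(
    area_error = area_error, protrusion = protrusion,
    max_overlap = max_ov, convex = convex, box_deviation = box_dev,
    feasible = (n == 0L) ||
      (max(c(0, area_error)) <= max(tol, tol * max(c(1, vapply(nuc, `[[`, 0, "target_area")))) &&
       max(c(0, protrusion)) <= tol && max(c(0, max_ov)) <= tol && all(convex))
  )
}

#' Advance a state to the next constrained energy minimum
#'
#' Minimizes the total energy (including the gradient-flow term anchored at
#' the input state) over all nucleus vertices, basal cable anchors, apical
#' control heights and wall positions, then enforces the area equality
#' constraint by exact uniform scaling and restores convexity if a
#' polygon's convexity predicate fails. Deterministic given identical
#' inputs.
#'
#' @param state the previous equilibrium `iknm_state`.
#' @param params an `iknm_params`.
#' @return the new `iknm_state`, with an attribute `mech` carrying solver
#'   diagnostics (`iterations`, `converged`, `grad_inf`, objective values,
#'   and the post-step [constraint_residuals()] summary).
#' @export
minimize_state <- function(state, params) {
  write_back <- function(st, res) {
    st$box$h <- as.numeric(res$h)
    st$box$xL <- res$xL
    st$box$xR <- res$xR
    V <- res$V
    for (i in seq_along(st$nuclei)) {
      v <- V[((i - 1L) * N_VERTICES + 1L):(i * N_VERTICES), , drop = FALSE]
      if (!is_convex(v, tol = params$convex_tol))
        v <- convexify(v, tol = params$convex_tol)
      st$nuclei[[i]]$verts <- v
      st$nuclei[[i]]$bx <- res$bx[i]
    }
    st
  }
  a <- mech_args(state, params)
  res <- cpp_minimize(a$V, a$bx, a$ax, a$ay, a$cable_on, a$spring_on,
                      a$is_M, a$target_area, a$h, a$hx, a$xL, a$xR, a$par,
                      gtol = params$gtol, max_iter = params$max_iter)
  out <- write_back(state, res)
  resid <- constraint_residuals(out, params)
  # stiff steps (divisions, crowded growth) occasionally need continued
  # relaxation to restore feasibility within the same time step
  retries <- 0L
  while (!resid$feasible && retries < 3L) {
    retries <- retries + 1L
    a2 <- mech_args(out, params)
    res2 <- cpp_minimize(a2$V, a2$bx, a2$ax, a2$ay, a2$cable_on,
                         a2$spring_on, a2$is_M, a2$target_area, a2$h, a2$hx,
                         a2$xL, a2$xR, a2$par,
                         gtol = params$gtol, max_iter = params$max_iter)
    out <- write_back(out, res2)
    res$V <- res2$V; res$bx <- res2$bx; res$h <- res2$h
    res$iterations <- res$iterations + res2$iterations
    res$converged <- res2$converged
    res$grad_inf <- res2$grad_inf
    res$objective <- res2$objective
    resid <- constraint_residuals(out, params)
  }
  if (!res$converged && res$grad_inf > 100 * params$gtol)
    warning(sprintf(
      "minimizer did not converge at t = %.2f h (grad %.2e after %d iterations); best feasible iterate kept",
      state$t, res$grad_inf, res$iterations))
  if (!resid$feasible)
    warning(sprintf(
      "constraint residuals exceed tolerance at t = %.2f h (max overlap %.2e, max area error %.2e)",
      state$t, max(c(0, resid$max_overlap)), max(c(0, resid$area_error))))
  attr(out, "mech") <- list(
    iterations = res$iterations, converged = res$converged,
    grad_inf = res$grad_inf, objective_start = res$objective_start,
    objective_ref = res$objective_ref,
    objective = res$objective, residuals = resid, retries = retries,
    trace = res$trace)
  out
}
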