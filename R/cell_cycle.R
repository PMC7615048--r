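# Cell-cycle state machine: phase timers, spatial gates, S-phase nuclear
# growth, mitosis and division. Phases advance strictly in the order
# G1 -> S -> G2 -> M -> division -> G1. G1 and S durations are inputs
# (timer mode) or gated by space (basal_gate mode for G1); G2 duration is
# always an output of the mechanics: a G2 nucleus divides only once it has
# reached the apical surface.

#' Draw an S-phase duration
#'
#' S lasts `S_mean +/- S_halfwidth` hours; by default the draw is uniform
#' on `[S_mean - S_halfwidth, S_mean + S_halfwidth]` (bounded support; no
#' negative durations). With `S_dist = "gaussian"` the draw is normal with
#' sd `S_halfwidth`, truncated below at 0.1 h.
#'
#' @param params an `iknm_params`.
#' @return duration in hours. Consumes one draw from the R RNG stream.
#' @export
draw_S_duration <- function(params) {
  if (params$S_dist == "uniform") {
    stats::runif(1L, params$S_mean - params$S_halfwidth,
                 params$S_mean + params$S_halfwidth)
  } else {
    max(0.1, stats::rnorm(1L, params$S_mean, params$S_halfwidth))
  }
}

#' G1 duration as a function of developmental time (timer mode)
#'
#' Linear interpolation from `G1_start` hours at `t_start` to `G1_end`
#' hours at `t_end`, mimicking the lengthening of G1 as the disc ages.
#' Times outside the simulated range are clamped with a warning.
#'
#' @param t time (h AEL) at which the nucleus entered G1.
#' @param params an `iknm_params`.
#' @return duration in hours.
#' @export
g1_duration_at <- function(t, params) {
  if (any(t < params$t_start | t > params$t_end)) {
    warning("t outside [t_start, t_end]; clamped")
    t <- pmin(pmax(t, params$t_start), params$t_end)
  }
  f <- (t - params$t_start) / (params$t_end - params$t_start)
  params$G1_start + f * (params$G1_end - params$G1_start)
}

#' Update a nucleus's target area
#'
#' Nuclei double in area during S phase only: the target grows from
#' `birth_area` at S entry to `2 * birth_area` at S completion (linearly in
#' time by default, exponentially with `growth_shape = "exponential"`),
#' and is frozen in G1, G2 and M.
#'
#' @param nucleus an `iknm_nucleus`.
#' @param t current time (h).
#' @param params an `iknm_params`.
#' @return the new target area (`G1d^2`).
#' @export
update_target_area <- function(nucleus, t, params) {
  if (nucleus$phase != "S") return(nucleus$target_area)
  f <- (t - nucleus$phase_entry_time) / nucleus$S_duration
  f <- min(max(f, 0), 1)
  if (params$growth_shape == "linear") {
    min(nucleus$birth_area * (1 + f), 2 * nucleus$birth_area)
  } else {
    min(nucleus$birth_area * 2^f, 2 * nucleus$birth_area)
  }
}

#' Basal signal gate for S entry
#'
#' In the two-gate model, G1 -> S requires the nucleus to lie within range
#' `lambda` (in `G1d`) of the basal surface: TRUE iff the nucleus's minimal
#' vertex z is `<= lambda`.
#'
#' @param nucleus an `iknm_nucleus`.
#' @param lambda basal signal range in `G1d`.
#' @return logical.
#' @export
basal_signal_gate <- function(nucleus, lambda) {
  min(nucleus$verts[, 2L]) <= lambda
}

# one event-log row
#' @keywords internal
event_row <- function(time, event, id, parent_id = NA_integer_,
                      x = NA_real_, z = NA_real_) {
  data.frame(time = time, event = event, id = as.integer(id),
             parent_id = as.integer(parent_id), x = x, z = z)
}

#' Advance the cell-cycle state of one nucleus
#'
#' Applies at most one phase transition per call (the engine calls this
#' every `dt`): G1 -> S by timer or basal gate; S -> G2 when the assigned S
#' duration has elapsed (the target area is then exactly doubled);
#' G2 -> M when the nucleus touches the apical boundary with its centroid
#' within `gate_depth` of it (the apical mitotic gate; the cable is
#' inactivated on M entry for mitotic rounding). M -> division is handled
#' by the engine via [divide_nucleus()]. Unanchored daughters re-establish
#' their cable once their re-anchoring time has passed.
#'
#' @param nucleus an `iknm_nucleus`.
#' @param state the current `iknm_state` (for gates and anchors).
#' @param params an `iknm_params`.
#' @return `list(nucleus = updated nucleus, events = data.frame)`.
#' @export
advance_phase <- function(nucleus, state, params) {
  t <- state$t
  events <- NULL
  n <- nucleus
  ctr <- polygon_centroid(n$verts)

  # junction remodeling: a cable whose apical anchor has been left far
  # behind laterally (nuclei move past each other, walls yield) re-attaches
  # above the nucleus, keeping the cell axis roughly apical-basal
  if (isTRUE(n$anchored) && !is.na(n$ax) &&
      abs(n$ax - ctr[1L]) > params$anchor_remodel) {
    eps <- 0.05
    n$ax <- min(max(ctr[1L], state$box$xL + eps), state$box$xR - eps)
  }

  if (!isTRUE(n$anchored) && !is.na(n$reanchor_time) && t >= n$reanchor_time) {
    n$anchored <- TRUE
    n$cable_active <- TRUE
    eps <- 0.05
    xa <- min(max(ctr[1L], state$box$xL + eps), state$box$xR - eps)
    n$ax <- xa
    n$bx <- xa
    n$reanchor_time <- NA_real_
    events <- rbind(events, event_row(t, "REANCHOR", n$id, n$parent_id,
                                      ctr[1L], ctr[2L]))
  }

  if (n$phase == "G1") {
    go <- if (params$mode == "timer") {
      (t - n$phase_entry_time) >= g1_duration_at(n$phase_entry_time, params)
    } else {
      basal_signal_gate(n, params$lambda)
    }
    if (go) {
      n$phase <- "S"
      n$phase_entry_time <- t
      n$S_duration <- draw_S_duration(params)
      events <- rbind(events, event_row(t, "G1S", n$id, n$parent_id,
                                        ctr[1L], ctr[2L]))
    }
  } else if (n$phase == "S") {
    if ((t - n$phase_entry_time) >= n$S_duration) {
      n$phase <- "G2"
      n$phase_entry_time <- t
      n$target_area <- 2 * n$birth_area
      events <- rbind(events, event_row(t, "SG2", n$id, n$parent_id,
                                        ctr[1L], ctr[2L]))
    }
  } else if (n$phase == "G2") {
    depth <- apical_height_at(state$box, ctr[1L]) - ctr[2L]
    if (isTRUE(n$anchored) &&
        apical_contact(n, state$box, params$tol_apical) &&
        depth <= params$gate_depth) {
      n$phase <- "M"
      n$phase_entry_time <- t
      n$m_end <- t + params$M_duration
      n$cable_active <- FALSE  # mitotic rounding
      events <- rbind(events, event_row(t, "G2M", n$id, n$parent_id,
                                        ctr[1L], ctr[2L]))
    }
  }
  list(nucleus = n, events = events)
}

#' Divide a mitotic nucleus into two daughters
#'
#' Splits the mother polygon by a line through its centroid perpendicular
#' to the apical surface, resamples each half to a 20-gon of exactly half
#' the mother's area, and creates two G1 daughters with
#' `birth_area = mother_area / 2`. One daughter, chosen by a fair coin,
#' inherits the mother's apical and basal connections; the other is
#' unanchored (no cable, no spring) until its re-anchoring time, drawn
#' fairly from `reanchor_delays` after division. Basal-ward motion after
#' division is passive.
#'
#' @param nucleus an `iknm_nucleus` in phase M with its M duration elapsed.
#' @param t division time (h).
#' @param params an `iknm_params`.
#' @param ids length-2 integer vector of fresh ids for the daughters.
#' @return `list(daughters = list of two nuclei, events = data.frame)`.
#'   Consumes two RNG draws (daughter choice, re-anchoring delay).
#' @export
divide_nucleus <- function(nucleus, t, params, ids) {
  if (nucleus$phase != "M")
    stop("divide_nucleus called on a nucleus not in M phase")
  v <- nucleus$verts
  A <- polygon_area(v)
  ctr <- polygon_centroid(v)
  xc <- ctr[1L]
  left  <- clip_halfplane(v, c(xc, 0), c(xc, 1))
  right <- clip_halfplane(v, c(xc, 1), c(xc, 0))
  if (is.null(left) || is.null(right))
    stop("degenerate division: centroid split produced an empty half")
  half <- A / 2
  mk <- function(p, shift) {
    p <- scale_to_area(resample_polygon(p, N_VERTICES), half)
    p[, 1L] <- p[, 1L] + shift
    if (!is_convex(p)) p <- convexify(p)
    p
  }
  vl <- mk(left, -0.01)
  vr <- mk(right, 0.01)

  keep_left <- stats::runif(1L) < 0.5           # fair coin: who keeps anchors
  delays <- params$reanchor_delays              # re-anchoring delay, fair draw
  delta <- delays[sample.int(length(delays), 1L)]

  mk_daughter <- function(id, verts, anchored) {
    new_nucleus(
      id = id, verts = verts, phase = "G1", phase_entry_time = t,
      target_area = half, birth_area = half,
      anchored = anchored,
      ax = if (anchored) nucleus$ax else NA_real_,
      bx = if (anchored) nucleus$bx else NA_real_,
      cable_active = anchored,
      reanchor_time = if (anchored) NA_real_ else t + delta,
      parent_id = nucleus$id)
  }
  d1 <- mk_daughter(ids[1L], vl, keep_left)
  d2 <- mk_daughter(ids[2L], vr, !keep_left)
  events <- event_row(t, "DIVISION", nucleus$id, nucleus$parent_id,
                      ctr[1L], ctr[2L])
  list(daughters = list(d1, d2), events = events)
}
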