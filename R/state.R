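# Simulation state containers: nuclei, the elastic box, and the state the
# minimizer advances.

#' Construct a nucleus
#'
#' @param id integer id (stable across the run; daughters get fresh ids).
#' @param verts 20 x 2 vertex matrix (CCW).
#' @param phase one of `"G1"`, `"S"`, `"G2"`, `"M"`.
#' @param phase_entry_time time (h) the nucleus entered `phase`.
#' @param target_area current mechanical target area (`G1d^2`).
#' @param birth_area area at birth; the target is capped at `2 * birth_area`.
#' @param S_duration assigned S duration (h; `NA` until S entry).
#' @param G1_duration assigned G1 duration (h; `NA` in basal-gate mode).
#' @param anchored whether apical/basal connections exist.
#' @param ax,bx apical / basal cable anchor x positions.
#' @param cable_active whether the cable-to-nuclei energy acts (off in M and
#'   while unanchored).
#' @param reanchor_time when an unanchored daughter re-establishes contacts
#'   (`NA` otherwise).
#' @param parent_id id of the mother nucleus (`NA` for seeded nuclei).
#' @param m_end scheduled end of M phase (`NA` outside M).
#' @return a list of class `iknm_nucleus`.
#' @export
new_nucleus <- function(id, verts, phase = "G1", phase_entry_time = 0,
                        target_area = pi / 4, birth_area = pi / 4,
                        S_duration = NA_real_, G1_duration = NA_real_,
                        anchored = TRUE, ax = NA_real_, bx = NA_real_,
                        cable_active = TRUE, reanchor_time = NA_real_,
                        parent_id = NA_integer_, m_end = NA_real_) {
  stopifnot(phase %in% c("G1", "S", "G2", "M"))
  validate_polygon(verts, n_required = N_VERTICES)
  structure(list(
    id = as.integer(id), verts = verts, phase = phase,
    phase_entry_time = phase_entry_time, target_area = target_area,
    birth_area = birth_area, S_duration = S_duration,
    G1_duration = G1_duration, anchored = anchored, ax = ax, bx = bx,
    cable_active = cable_active, reanchor_time = reanchor_time,
    parent_id = as.integer(parent_id), m_end = m_end
  ), class = "iknm_nucleus")
}

#' Construct the elastic box
#'
#' The basal surface is the rigid line `z = 0`; the apical boundary is a
#' piecewise-linear chain of control heights over a fixed lateral grid;
#' the lateral walls are elastic about rest positions `0` and `box_width`.
#'
#' @param params an `iknm_params` object.
#' @return a list of class `iknm_box` with fields `xL`, `xR`, `hx`
#'   (apical grid), `h` (control heights), `h0`, `W0`, `d_mz`.
#' @export
new_box <- function(params) {
  structure(list(
    xL = 0, xR = params$box_width,
    hx = seq(0, params$box_width, length.out = params$n_apical),
    h = rep(params$box_height, params$n_apical),
    h0 = params$box_height, W0 = params$box_width, d_mz = params$d_mz
  ), class = "iknm_box")
}

#' Apical boundary height at lateral position x
#'
#' Piecewise-linear interpolation of the apical control heights; constant
#' extrapolation beyond the grid.
#'
#' @param box an `iknm_box`.
#' @param x lateral position(s).
#' @return height(s) of the apical boundary.
#' @export
apical_height_at <- function(box, x) {
  stats::approx(box$hx, box$h, xout = pmin(pmax(x, box$hx[1L]),
                                           box$hx[length(box$hx)]))$y
}

#' Construct a simulation state
#'
#' @param t simulated time (h AEL).
#' @param box an `iknm_box`.
#' @param nuclei list of `iknm_nucleus` objects.
#' @param step_index step counter.
#' @return a list of class `iknm_state`.
#' @export
new_state <- function(t, box, nuclei, step_index = 0L) {
  structure(list(t = t, box = box, nuclei = nuclei,
                 step_index = as.integer(step_index)),
            class = "iknm_state")
}

#' @export
print.iknm_state <- function(x, ...) {
  ph <- vapply(x$nuclei, `[[`, "", "phase")
  cat(sprintf("IKNM state at t = %.2f h: %d nuclei (G1 %d, S %d, G2 %d, M %d)\n",
              x$t, length(ph), sum(ph == "G1"), sum(ph == "S"),
              sum(ph == "G2"), sum(ph == "M")))
  invisible(x)
}

# Apical contact predicate: any vertex within tol of the apical boundary.
#' @keywords internal
apical_contact <- function(nucleus, box, tol) {
  ha <- apical_height_at(box, nucleus$verts[, 1L])
  any(nucleus$verts[, 2L] >= ha - tol)
}

# Assemble the argument list shared by the compiled energy/gradient/
# minimizer entry points. The apical cable anchors are evaluated
# quasi-statically: their height is the apical boundary height at ax for
# the *current* state and is held fixed during the minimization.
#' @keywords internal
mech_args <- function(state, params) {
  nuc <- state$nuclei
  n <- length(nuc)
  V <- do.call(rbind, lapply(nuc, `[[`, "verts"))
  phase <- vapply(nuc, `[[`, "", "phase")
  anchored <- vapply(nuc, `[[`, TRUE, "anchored")
  cable_active <- vapply(nuc, `[[`, TRUE, "cable_active")
  ax <- vapply(nuc, `[[`, 0, "ax")
  bx <- vapply(nuc, `[[`, 0, "bx")
  ax[is.na(ax)] <- 0; bx[is.na(bx)] <- 0
  cable_on <- anchored & cable_active
  spring_on <- logical(n)
  for (i in seq_len(n)) {
    spring_on[i] <- phase[i] == "G2" && cable_on[i] &&
      !apical_contact(nuc[[i]], state$box, params$tol_apical)
  }
  list(
    V = V, bx = bx, ax = ax, ay = apical_height_at(state$box, ax),
    cable_on = cable_on, spring_on = spring_on, is_M = phase == "M",
    target_area = vapply(nuc, `[[`, 0, "target_area"),
    h = state$box$h, hx = state$box$hx,
    xL = state$box$xL, xR = state$box$xR,
    par = unclass(params)
  )
}
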