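# Simulation engine: seeding, the step loop (cell-cycle updates before
# mechanics), trajectory and event recording, ensembles.
#
# RNG contract: each replicate uses a single R RNG stream seeded with its
# own seed. Draws occur in a documented order: seeding (position jitters,
# phase permutation, per-S elapsed fraction and duration), then per step in
# nucleus list order (S-duration draws at G1->S, daughter choice and
# re-anchoring delay at division). Identical (config, seed) pairs give
# bit-identical trajectories.

#' Seed the initial state
#'
#' Places `n_seed_G1 + n_seed_S` nuclei (default 7 G1 and 3 S, no G2, the
#' phase ratios of young discs) on a jittered grid in the box at `t_start`,
#' then relaxes the configuration mechanically (repeated [minimize_state()]
#' calls at fixed time) until all constraint residuals are within
#' tolerance. G1 seeds enter G1 at `t_start`; S seeds get a uniformly drawn
#' elapsed fraction of a drawn S duration, and an initial area consistent
#' with it.
#'
#' @param params an `iknm_params`. The RNG must already be seeded.
#' @return a feasible `iknm_state` at `t = t_start`.
#' @export
seed_initial_state <- function(params) {
  box <- new_box(params)
  n_tot <- params$n_seed_G1 + params$n_seed_S
  ncol_ <- max(1L, round(params$box_width))
  nrow_ <- ceiling(n_tot / ncol_)
  z_rows <- 0.55 + (seq_len(nrow_) - 1L) * 1.05
  if (max(z_rows) + 0.55 > params$box_height - params$d_mz)
    stop("configuration error: cannot place ", n_tot,
         " non-overlapping nuclei in the configured box")
  pitch <- params$box_width / ncol_
  centers <- do.call(rbind, lapply(z_rows, function(z)
    cbind(pitch / 2 + (seq_len(ncol_) - 1L) * pitch, z)))[seq_len(n_tot), , drop = FALSE]
  centers <- centers + matrix(stats::runif(2L * n_tot, -0.03, 0.03), ncol = 2L)

  phases <- c(rep("G1", params$n_seed_G1),
              rep("S", params$n_seed_S))[sample.int(n_tot)]
  nuclei <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    if (phases[i] == "S") {
      f <- stats::runif(1L)                    # elapsed fraction of S
      Sdur <- draw_S_duration(params)
      a0 <- pi / 4 * (1 + f)                   # linear growth from birth area
      nuclei[[i]] <- new_nucleus(
        id = i, verts = regular_polygon(centers[i, ], a0),
        phase = "S", phase_entry_time = params$t_start - f * Sdur,
        target_area = a0, birth_area = pi / 4, S_duration = Sdur,
        ax = centers[i, 1L], bx = centers[i, 1L])
    } else {
      nuclei[[i]] <- new_nucleus(
        id = i, verts = regular_polygon(centers[i, ], pi / 4),
        phase = "G1", phase_entry_time = params$t_start,
        target_area = pi / 4, birth_area = pi / 4,
        ax = centers[i, 1L], bx = centers[i, 1L])
    }
  }
  state <- new_state(params$t_start, box, nuclei)
  # mechanical relaxation at fixed time until feasible
  for (k in seq_len(30L)) {
    state <- suppressWarnings(minimize_state(state, params))
    if (attr(state, "mech")$residuals$feasible) break
  }
  if (!attr(state, "mech")$residuals$feasible)
    stop("configuration error: seeded state could not be relaxed to feasibility")
  state
}

#' Advance the simulation by one time step
#'
#' Applies, in order: (1) cell-cycle updates in nucleus list order (phase
#' advances, target-area growth, divisions of mitotic nuclei whose M
#' duration has elapsed, re-anchorings), then (2) the mechanical
#' minimization, and advances time by `dt`.
#'
#' @param state the current `iknm_state`.
#' @param params an `iknm_params`.
#' @param next_id the next unused nucleus id.
#' @return `list(state, events, next_id)`; `events` is a data.frame (or
#'   `NULL`) of the step's discrete events.
#' @export
step <- function(state, params, next_id = max(vapply(state$nuclei, `[[`, 0L, "id")) + 1L) {
  t <- state$t
  events <- list()
  new_nuclei <- list()
  for (n in state$nuclei) {
    res <- advance_phase(n, state, params)
    n <- res$nucleus
    if (!is.null(res$events)) events[[length(events) + 1L]] <- res$events
    if (n$phase == "M" && !is.na(n$m_end) && t >= n$m_end) {
      div <- divide_nucleus(n, t, params, ids = c(next_id, next_id + 1L))
      next_id <- next_id + 2L
      events[[length(events) + 1L]] <- div$events
      new_nuclei <- c(new_nuclei, div$daughters)
    } else {
      n$target_area <- update_target_area(n, t, params)
      new_nuclei[[length(new_nuclei) + 1L]] <- n
    }
  }
  state$nuclei <- new_nuclei
  state <- minimize_state(state, params)
  state$t <- t + params$dt
  state$step_index <- state$step_index + 1L
  ev <- if (length(events)) do.call(rbind, events) else NULL
  list(state = state, events = ev, next_id = next_id)
}

# one snapshot: per-nucleus rows with serialized vertices
#' @keywords internal
snapshot_rows <- function(state) {
  nuc <- state$nuclei
  n <- length(nuc)
  if (n == 0L) return(NULL)
  V <- do.call(rbind, lapply(nuc, function(x) as.vector(t(x$verts))))
  colnames(V) <- paste0(rep(c("x", "z"), N_VERTICES),
                        rep(seq_len(N_VERTICES), each = 2L))
  ctr <- t(vapply(nuc, function(x) polygon_centroid(x$verts), numeric(2L)))
  data.frame(
    time = state$t,
    id = vapply(nuc, `[[`, 0L, "id"),
    phase = vapply(nuc, `[[`, "", "phase"),
    cx = ctr[, 1L], cz = ctr[, 2L],
    area = vapply(nuc, function(x) polygon_area(x$verts), 0),
    min_z = vapply(nuc, function(x) min(x$verts[, 2L]), 0),
    max_z = vapply(nuc, function(x) max(x$verts[, 2L]), 0),
    apical_z = apical_height_at(state$box, ctr[, 1L]),
    anchored = vapply(nuc, `[[`, TRUE, "anchored"),
    V, row.names = NULL)
}

#' @keywords internal
frame_row <- function(state) {
  ph <- vapply(state$nuclei, `[[`, "", "phase")
  data.frame(
    time = state$t, n = length(ph),
    n_G1 = sum(ph == "G1"), n_S = sum(ph == "S"),
    n_G2 = sum(ph == "G2"), n_M = sum(ph == "M"),
    xL = state$box$xL, xR = state$box$xR,
    h_mean = mean(state$box$h), h_min = min(state$box$h),
    h_max = max(state$box$h))
}

#' Run a full simulation
#'
#' Seeds the box at `t_start`, advances to `t_end`, and records snapshots
#' at the configured cadence plus every discrete event. With `output_dir`,
#' snapshots/frames/events are appended to tab-delimited files as the run
#' progresses (together with the config echo), so an interrupted run
#' leaves usable partial output.
#'
#' @param params an `iknm_params`.
#' @param seed integer RNG seed; the run is bit-reproducible per
#'   (config, seed).
#' @param output_dir optional directory for continuous tabular output.
#' @param quiet suppress per-step non-convergence warnings (they are still
#'   counted in the diagnostics).
#' @return an `iknm_trajectory`: list with `snapshots`, `frames`, `events`
#'   data.frames, the `config` echo, `seed`, `final_state`, and
#'   `diagnostics`.
#' @export
run <- function(params, seed = 1L, output_dir = NULL, quiet = TRUE) {
  params <- validate_params(params)
  set.seed(as.integer(seed))
  steps_per_snap <- max(1L, round(params$snapshot_dt / params$dt))
  n_steps <- round((params$t_end - params$t_start) / params$dt)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(params, file.path(output_dir, "config.yaml"))
    writeLines(as.character(seed), file.path(output_dir, "seed.txt"))
  }

  n_warn <- 0L
  withCallingHandlers(
    state <- seed_initial_state(params),
    warning = function(w) {
      n_warn <<- n_warn + 1L
      if (quiet) invokeRestart("muffleWarning")
    })

  snaps <- vector("list", n_steps %/% steps_per_snap + 2L)
  frames <- vector("list", length(snaps))
  events <- list()
  isnap <- 1L
  snaps[[1L]] <- snapshot_rows(state)
  frames[[1L]] <- frame_row(state)
  if (!is.null(output_dir)) {
    append_tsv(snaps[[1L]], file.path(output_dir, "snapshots.tsv"), TRUE)
    append_tsv(frames[[1L]], file.path(output_dir, "frames.tsv"), TRUE)
  }

  next_id <- length(state$nuclei) + 1L
  wrote_events_header <- FALSE
  for (k in seq_len(n_steps)) {
    withCallingHandlers(
      st <- step(state, params, next_id),
      warning = function(w) {
        n_warn <<- n_warn + 1L
        if (quiet) invokeRestart("muffleWarning")
      })
    state <- st$state
    next_id <- st$next_id
    state$t <- params$t_start + k * params$dt  # avoid fp drift
    if (!is.null(st$events)) {
      events[[length(events) + 1L]] <- st$events
      if (!is.null(output_dir)) {
        append_tsv(st$events, file.path(output_dir, "events.tsv"),
                   !wrote_events_header)
        wrote_events_header <- TRUE
      }
    }
    if (k %% steps_per_snap == 0L) {
      isnap <- isnap + 1L
      snaps[[isnap]] <- snapshot_rows(state)
      frames[[isnap]] <- frame_row(state)
      if (!is.null(output_dir)) {
        append_tsv(snaps[[isnap]], file.path(output_dir, "snapshots.tsv"), FALSE)
        append_tsv(frames[[isnap]], file.path(output_dir, "frames.tsv"), FALSE)
      }
    }
  }
  # terminal bookkeeping: nuclei that entered G2 but never divided
  arrested <- Filter(function(n) n$phase %in% c("G2", "M"), state$nuclei)
  if (length(arrested)) {
    rows <- do.call(rbind, lapply(arrested, function(n) {
      ctr <- polygon_centroid(n$verts)
      event_row(state$t, "ARREST", n$id, n$parent_id, ctr[1L], ctr[2L])
    }))
    events[[length(events) + 1L]] <- rows
    if (!is.null(output_dir))
      append_tsv(rows, file.path(output_dir, "events.tsv"), !wrote_events_header)
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), event = character(0), id = integer(0),
               parent_id = integer(0), x = numeric(0), z = numeric(0))
  structure(list(
    snapshots = do.call(rbind, snaps[seq_len(isnap)]),
    frames = do.call(rbind, frames[seq_len(isnap)]),
    events = ev, config = params, seed = as.integer(seed),
    final_state = state,
    diagnostics = list(n_warnings = n_warn, n_steps = n_steps)
  ), class = "iknm_trajectory")
}

#' @keywords internal
append_tsv <- function(df, path, header) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = header, append = !header, quote = FALSE)
}

#' @export
print.iknm_trajectory <- function(x, ...) {
  cat(sprintf(
    "IKNM trajectory: seed %d, t = %.0f..%.0f h, %d -> %d nuclei, %d events\n",
    x$seed, min(x$frames$time), max(x$frames$time),
    x$frames$n[1L], tail(x$frames$n, 1L), nrow(x$events)))
  invisible(x)
}

#' Run an ensemble of independent replicates
#'
#' Replicate `i` uses seed `seed + i - 1`; replicates are independent and
#' their results do not depend on execution order.
#'
#' @param params an `iknm_params`.
#' @param n number of replicates.
#' @param seed base seed.
#' @param output_dir optional; replicate `i` writes under
#'   `output_dir/rep<i>`.
#' @return an `iknm_ensemble`: list of `iknm_trajectory` objects.
#' @export
run_ensemble <- function(params, n = 20L, seed = 1L, output_dir = NULL) {
  stopifnot(n >= 1L)
  out <- lapply(seq_len(n), function(i) {
    od <- if (is.null(output_dir)) NULL else
      file.path(output_dir, sprintf("rep%02d", i))
    run(params, seed = seed + i - 1L, output_dir = od)
  })
  structure(out, class = "iknm_ensemble")
}

#' Read a trajectory back from an output directory
#'
#' Reconstructs an `iknm_trajectory` (without the final state) from the
#' tabular files written by [run()], so analyses can be re-run on stored
#' output.
#'
#' @param dir directory written by `run(..., output_dir = dir)`.
#' @return an `iknm_trajectory`.
#' @export
read_trajectory <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  ev <- rd("events.tsv")
  if (is.null(ev))
    ev <- data.frame(time = numeric(0), event = character(0),
                     id = integer(0), parent_id = integer(0),
                     x = numeric(0), z = numeric(0))
  structure(list(
    snapshots = rd("snapshots.tsv"), frames = rd("frames.tsv"),
    events = ev,
    config = read_config(file.path(dir, "config.yaml")),
    seed = as.integer(readLines(file.path(dir, "seed.txt"))[1L]),
    final_state = NULL,
    diagnostics = NULL
  ), class = "iknm_trajectory")
}
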