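# Scripted experiments that compute the simulator's headline statistics
# from ensembles, plus a randomized property suite that doubles as
# executable documentation of the model's invariants.

# content hash of a config echo, for traceable reports
#' @keywords internal
config_hash <- function(params) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_config(params, f)
  unname(tools::md5sum(f))
}

#' Timer-mode growth experiment
#'
#' Runs an ensemble of timer-mode replicates over the full simulated
#' interval and computes the statistics that characterise crowding-limited
#' IKNM: begin/end G2 fractions (both instantaneous and averaged over the
#' first/last 12 h windows), the terminal pre-mitotic velocity trend and
#' its end/begin ratio, the G2-duration series with its fold increase and
#' late plateau, cumulative G2 arrests, and apical-basal distributions at
#' 12 h intervals.
#'
#' @param params an `iknm_params` (timer mode).
#' @param n_rep replicates (20 for the full experiment).
#' @param seed base seed.
#' @return a report list (config echo + hash, per-statistic tables).
#' @export
experiment_growth <- function(params = model_params(), n_rep = 20L, seed = 1L) {
  stopifnot(params$mode == "timer")
  ens <- run_ensemble(params, n = n_rep, seed = seed)
  summarize_growth(ens)
}

#' Summarise a timer-mode ensemble
#'
#' The analysis half of [experiment_growth()], reusable on an already-run
#' ensemble.
#'
#' @param ens an `iknm_ensemble`.
#' @return report list; see [experiment_growth()].
#' @export
summarize_growth <- function(ens) {
  params <- ens[[1L]]$config
  pf <- phase_fractions(ens)
  early_win <- params$t_start + c(0, 12)
  late_win <- params$t_end - c(12, 0)
  win_mean <- function(w, col) {
    rows <- pf$time >= w[1L] & pf$time <= w[2L]
    mean(pf[[col]][rows])
  }
  win_sd <- function(w) {
    # across-replicate SD of the window-averaged G2 fraction
    vals <- vapply(unclass(ens), function(tr) {
      p1 <- phase_fractions(tr)
      mean(p1$f_G2[p1$time >= w[1L] & p1$time <= w[2L]])
    }, 0)
    stats::sd(vals)
  }
  tv <- terminal_velocity(ens)
  gd <- g2_durations(ens)
  ga <- g2_arrested(ens, t_end = params$t_end)
  fold <- if (nrow(gd$series) >= 2L)
    gd$series$mean[nrow(gd$series)] / gd$series$mean[1L] else NA_real_
  plateau <- mean(gd$durations$duration[gd$durations$g2_entry >= 90])
  ab_times <- seq(params$t_start, params$t_end, by = 12)
  ab <- lapply(ab_times, function(tm) ab_distribution(ens, time = tm))
  names(ab) <- paste0("t", ab_times)
  list(
    config = unclass(params), config_hash = config_hash(params),
    n_rep = length(ens), seeds = vapply(unclass(ens), `[[`, 0L, "seed"),
    phase_fractions = pf,
    G2_begin_instant = pf$f_G2[which.min(pf$time)],
    G2_end_instant = pf$f_G2[which.max(pf$time)],
    G2_begin_window = win_mean(early_win, "f_G2"),
    G2_end_window = win_mean(late_win, "f_G2"),
    G2_begin_window_sd = win_sd(early_win),
    G2_end_window_sd = win_sd(late_win),
    S_begin_window = win_mean(early_win, "f_S"),
    S_end_window = win_mean(late_win, "f_S"),
    terminal_velocity = tv$velocities,
    velocity_trend_coef = stats::coef(tv$trend),
    velocity_ratio_end_begin = tv$ratio_end_begin,
    g2_duration_series = gd$series,
    g2_duration_fold_increase = fold,
    g2_duration_plateau = plateau,
    g2_arrested = ga,
    ab_distributions = ab)
}

#' Basal-gate experiment: layering versus signal range
#'
#' Runs basal-gate-mode ensembles for each value of the basal signal range
#' `lambda` and reports layering, thickness and phase censuses, to test
#' that a longer-ranged basal signal yields more nuclear layers.
#'
#' @param params an `iknm_params`; `mode` is forced to `"basal_gate"`.
#' @param lambdas basal signal ranges to sweep (in `G1d`).
#' @param n_rep replicates per lambda.
#' @param seed base seed.
#' @return report list with one entry per lambda plus the layer ordering.
#' @export
experiment_basal_gate <- function(params = model_params(mode = "basal_gate"),
                                  lambdas = c(2, 4, 10), n_rep = 20L,
                                  seed = 1L) {
  per <- lapply(lambdas, function(lam) {
    p <- model_params(modifyList(unclass(params),
                                 list(mode = "basal_gate", lambda = lam)))
    ens <- run_ensemble(p, n = n_rep, seed = seed)
    tl <- thickness_and_layers(ens, time = p$t_end)
    pf <- phase_fractions(ens)
    list(lambda = lam, config_hash = config_hash(p),
         layers_mean = mean(tl$layers), layers_sd = stats::sd(tl$layers),
         thickness_mean = mean(tl$thickness),
         phase_fractions = pf,
         G2_end = pf$f_G2[which.max(pf$time)],
         G2_begin = pf$f_G2[which.min(pf$time)])
  })
  names(per) <- paste0("lambda", lambdas)
  layers <- vapply(per, `[[`, 0, "layers_mean")
  list(lambdas = lambdas, per_lambda = per, layers_mean = layers,
       layering_increases_with_lambda = all(diff(layers) > 0),
       n_rep = n_rep, seed = seed)
}

#' Write / read an experiment report
#'
#' Reports are plain lists of tables and scalars; they serialize to YAML
#' (data.frames as column lists) and round-trip through [read_report()].
#'
#' @param report a report list.
#' @param path file path.
#' @return `path` invisibly / the report list.
#' @export
write_report <- function(report, path) {
  strip <- function(x) {
    if (is.data.frame(x)) as.list(x)
    else if (inherits(x, "lm")) list(coefficients = as.list(stats::coef(x)))
    else if (is.list(x)) lapply(x, strip)
    else x
  }
  yaml::write_yaml(strip(report), path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  yaml::read_yaml(path)
}

#' Randomized property suite
#'
#' Executes the model's invariants on randomized instances under a fixed
#' seed: geometric identities (invariance under rigid motions, overlap
#' symmetry and bounds, extent scaling), energy descent and post-step
#' feasibility along a short simulation, exact area conservation at
#' division with exactly one anchored daughter, bit-reproducibility per
#' seed, and monotonicity of the basal gate in lambda. Returns a table of
#' per-invariant results; any failure names the invariant and the seed.
#'
#' @param seed RNG seed for the randomized instances.
#' @param n_geom randomized instances per geometric identity.
#' @return data.frame `invariant`, `instances`, `pass`.
#' @export
property_suite <- function(seed = 1L, n_geom = 100L) {
  set.seed(seed)
  res <- list()
  ok <- function(name, n, pass)
    res[[length(res) + 1L]] <<- data.frame(invariant = name, instances = n,
                                           pass = pass)

  # geometry: rigid-motion invariance, overlap symmetry/bounds, scaling
  pass_rigid <- TRUE; pass_sym <- TRUE; pass_scale <- TRUE
  for (k in seq_len(n_geom)) {
    p <- random_convex_20gon()
    th <- runif(1L, 0, 2 * pi); sh <- runif(2L, -5, 5)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    p2 <- sweep(p %*% t(Rm), 2L, sh, "+")
    if (abs(polygon_area(p2) - polygon_area(p)) > 1e-10 * polygon_area(p))
      pass_rigid <- FALSE
    q <- sweep(random_convex_20gon(), 2L, runif(2L, -0.5, 0.5), "+")
    o1 <- overlap_area(p, q); o2 <- overlap_area(q, p)
    if (abs(o1 - o2) > 1e-10 || o1 > min(polygon_area(p), polygon_area(q)) + 1e-10)
      pass_sym <- FALSE
    s <- runif(1L, 0.5, 2)
    if (abs(max_extent(p * s) - s * max_extent(p)) > 1e-10 * max_extent(p))
      pass_scale <- FALSE
  }
  ok("geometry: rigid-motion invariance of area", n_geom, pass_rigid)
  ok("geometry: overlap symmetry and bounds", n_geom, pass_sym)
  ok("geometry: linear scaling of max extent", n_geom, pass_scale)

  # mechanics along a short run: energy descent + feasibility each step
  p <- model_params(t_end = 74, max_iter = 300)
  set.seed(seed)
  state <- seed_initial_state(p)
  descent <- TRUE; feasible <- TRUE
  nsteps <- 20L
  for (k in seq_len(nsteps)) {
    st <- suppressWarnings(step(state, p))
    m <- attr(st$state, "mech")
    if (m$objective > m$objective_ref + 1e-9) descent <- FALSE
    if (!m$residuals$feasible) feasible <- FALSE
    state <- st$state
  }
  ok("mechanics: energy descent every step", nsteps, descent)
  ok("mechanics: post-step constraint feasibility", nsteps, feasible)

  # division conservation: daughters sum to mother, exactly one anchored
  pass_div <- TRUE; pass_delay <- TRUE
  for (k in seq_len(20L)) {
    A <- runif(1L, 0.5, 1.6)
    m <- new_nucleus(1L, regular_polygon(runif(2L, 1, 3), A), phase = "M",
                     target_area = A, birth_area = A / 2, ax = 2, bx = 2,
                     m_end = 0)
    d <- divide_nucleus(m, t = 80, params = p, ids = c(2L, 3L))
    areas <- vapply(d$daughters, function(x) polygon_area(x$verts), 0)
    if (abs(sum(areas) - A) > 1e-9) pass_div <- FALSE
    anch <- vapply(d$daughters, `[[`, TRUE, "anchored")
    if (sum(anch) != 1L) pass_div <- FALSE
    un <- d$daughters[[which(!anch)]]
    if (min(abs((un$reanchor_time - 80) - p$reanchor_delays)) > 1e-12)
      pass_delay <- FALSE
  }
  ok("division: area conservation, one anchored daughter", 20L, pass_div)
  ok("division: re-anchoring delay drawn from the configured set", 20L, pass_delay)

  # determinism: bit-identical short re-run
  p2 <- model_params(t_end = 73)
  r1 <- run(p2, seed = seed)
  r2 <- run(p2, seed = seed)
  ok("engine: bit-identical trajectory per (config, seed)", 1L,
     identical(r1$snapshots, r2$snapshots) && identical(r1$events, r2$events))

  # basal gate monotone in lambda
  set.seed(seed)
  pass_gate <- TRUE
  for (k in seq_len(50L)) {
    nuc <- new_nucleus(1L, regular_polygon(c(2.5, runif(1L, 0.6, 8)), pi / 4))
    l1 <- runif(1L, 0, 5); l2 <- l1 + runif(1L, 0, 5)
    if (basal_signal_gate(nuc, l1) && !basal_signal_gate(nuc, l2))
      pass_gate <- FALSE
  }
  ok("cell cycle: basal gate monotone in lambda", 50L, pass_gate)

  out <- do.call(rbind, res)
  attr(out, "seed") <- seed
  out
}

# random convex 20-gon generator used by the property suite and tests:
# jittered radii on sorted angles, convexified, ~unit scale
#' @keywords internal
random_convex_20gon <- function(area = NULL) {
  th <- sort(runif(N_VERTICES, 0, 2 * pi))
  r <- runif(N_VERTICES, 0.3, 0.6)
  p <- cbind(r * cos(th), r * sin(th))
  h <- grDevices::chull(p)
  hull <- p[rev(h), , drop = FALSE]
  p <- resample_polygon(hull, N_VERTICES)
  if (!is.null(area)) p <- scale_to_area(p, area)
  p
}
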