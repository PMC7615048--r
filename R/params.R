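# Model configuration: the single source of truth for every stiffness,
# timing, gate mode and numerical control. Values are in model units:
# lengths in G1d (diameter of a spherical G1 nucleus), areas in G1d^2,
# times in hours.

.param_schema <- function() {
  list(
    # -- mechanics ----------------------------------------------------------
    k_deform      = list(default = 0.5,     min = 0,  desc = "nuclear edge-spring deformation stiffness"),
    k_cable       = list(default = 0.5,     min = 0,  desc = "cable-to-nuclei stiffness"),
    k_spring      = list(default = 6,     min = 0,  desc = "apical pulling-spring stiffness (G2 only)"),
    k_area        = list(default = 100,   min = 0,  desc = "area-conservation penalty stiffness"),
    k_overlap     = list(default = 200,   min = 0,  desc = "nucleus-nucleus overlap penalty stiffness"),
    k_contact     = list(default = 4000,  min = 0,  desc = "nucleus-box containment penalty stiffness"),
    k_mz          = list(default = 0.5,   min = 0,  desc = "mitotic-zone repulsion stiffness (non-M nuclei)"),
    k_box_apical  = list(default = 5,     min = 0,  desc = "apical boundary height stiffness"),
    k_box_curv    = list(default = 1,     min = 0,  desc = "apical boundary curvature (second-difference) stiffness"),
    k_box_lateral = list(default = 0.5,    min = 0,  desc = "lateral wall stiffness about rest width"),
    k_convex      = list(default = 500,   min = 0,  desc = "convexity penalty stiffness (negative edge cross products)"),
    convex_tol    = list(default = 1e-5,  min = 0,  desc = "relative convexity tolerance used by the feasibility check"),
    eta           = list(default = 0.15,  min = 1e-12, desc = "gradient-flow friction coefficient (energy h / G1d^2)"),
    tol_constraint = list(default = 1e-3, min = 0,  desc = "feasibility tolerance on overlap/protrusion areas (G1d^2)"),
    gtol          = list(default = 5e-4,  min = 0,  desc = "minimizer gradient-norm stopping tolerance"),
    max_iter      = list(default = 400,   min = 1,  desc = "max minimizer iterations per step", integer = TRUE),
    polish_eps    = list(default = 4e-4,  min = 0,  desc = "max residual vertex penetration after the contact polish (G1d)"),
    polish_sweeps = list(default = 120,   min = 0,  desc = "max contact-polish sweeps per step", integer = TRUE),
    # -- box ----------------------------------------------------------------
    box_width     = list(default = 5,     min = 0.5, desc = "rest width W0 of the box (G1d)"),
    box_height    = list(default = 3,     min = 0.5, desc = "rest height h0 of the apical boundary (G1d)"),
    n_apical      = list(default = 11,    min = 3,  desc = "apical boundary control points", integer = TRUE),
    d_mz          = list(default = 0.5,   min = 0,  desc = "mitotic zone depth below the apical boundary (G1d)"),
    # -- cell cycle ---------------------------------------------------------
    mode          = list(default = "timer", choices = c("timer", "basal_gate"),
                         desc = "G1->S control: a priori timer or basal signal gate"),
    S_mean        = list(default = 8,     min = 0,  desc = "mean S-phase duration (h)"),
    S_halfwidth   = list(default = 2,     min = 0,  desc = "half-width of the S duration distribution (h)"),
    S_dist        = list(default = "uniform", choices = c("uniform", "gaussian"),
                         desc = "shape of the S duration distribution about S_mean"),
    G1_start      = list(default = 2,     min = 0,  desc = "G1 duration at t_start (h, timer mode)"),
    G1_end        = list(default = 10,    min = 0,  desc = "G1 duration at t_end (h, timer mode)"),
    lambda        = list(default = 4,     min = 0,  desc = "basal signal range (G1d, basal_gate mode)"),
    M_duration    = list(default = 0.5,   min = 0,  desc = "duration of M phase (h)"),
    reanchor_delays = list(default = c(0.1, 0.2), min = 0,
                         desc = "re-anchoring delay options after division (h); a fair draw", vector = TRUE),
    tol_apical    = list(default = 0.1,   min = 0,  desc = "apical contact detection tolerance (G1d)"),
    gate_depth    = list(default = 1.5,   min = 0,  desc = "max centroid depth below apical surface for M entry (G1d)"),
    anchor_remodel = list(default = 1.5,  min = 0,  desc = "lateral apical-anchor offset (G1d) beyond which the junction remodels to the nucleus position"),
    growth_shape  = list(default = "linear", choices = c("linear", "exponential"),
                         desc = "target-area growth law during S"),
    # -- engine -------------------------------------------------------------
    t_start       = list(default = 72,    min = 0,  desc = "simulation start (h AEL)"),
    t_end         = list(default = 116,   min = 0,  desc = "simulation end (h AEL)"),
    dt            = list(default = 0.05,  min = 1e-6, desc = "time step (h; default 3 min)"),
    snapshot_dt   = list(default = 0.25,  min = 1e-6, desc = "snapshot cadence (h)"),
    n_seed_G1     = list(default = 7,     min = 0,  desc = "seeded G1 nuclei", integer = TRUE),
    n_seed_S      = list(default = 3,     min = 0,  desc = "seeded S nuclei", integer = TRUE),
    census_M_with_G2 = list(default = TRUE, logical = TRUE,
                         desc = "count M-phase nuclei with G2 in three-way censuses")
  )
}

#' Construct a validated parameter set
#'
#' Returns the full model configuration, starting from the package's
#' calibrated defaults and applying any overrides given as named arguments.
#' Every parameter of the model appears here; see the methods vignette for
#' the rationale behind each default.
#'
#' @param ... named overrides, e.g. `model_params(mode = "basal_gate", lambda = 10)`.
#' @return an object of class `iknm_params` (a named list).
#' @examples
#' p <- model_params(lambda = 2, mode = "basal_gate")
#' p$lambda
#' @export
model_params <- function(...) {
  schema <- .param_schema()
  p <- lapply(schema, `[[`, "default")
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  if (length(over)) {
    bad <- setdiff(names(over), names(schema))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  validate_params(structure(p, class = "iknm_params"))
}

#' Validate a parameter set against the schema
#'
#' Checks presence, type, range and categorical membership of every
#' parameter; errors with an informative message on the first violation.
#'
#' @param p an `iknm_params` object or plain named list.
#' @return the validated `iknm_params` object, invisibly usable.
#' @export
validate_params <- function(p) {
  schema <- .param_schema()
  miss <- setdiff(names(schema), names(p))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  for (nm in names(schema)) {
    s <- schema[[nm]]
    v <- p[[nm]]
    if (isTRUE(s$logical)) {
      if (!is.logical(v) || length(v) != 1L || is.na(v))
        stop(nm, " must be TRUE or FALSE")
      next
    }
    if (!is.null(s$choices)) {
      if (!is.character(v) || length(v) != 1L || !v %in% s$choices)
        stop(nm, " must be one of: ", paste(s$choices, collapse = ", "))
      next
    }
    if (!is.numeric(v) || any(!is.finite(v)))
      stop(nm, " must be finite numeric")
    if (!isTRUE(s$vector) && length(v) != 1L)
      stop(nm, " must be a scalar")
    if (!is.null(s$min) && any(v < s$min))
      stop(nm, " must be >= ", s$min)
    if (isTRUE(s$integer) && any(v != round(v)))
      stop(nm, " must be an integer")
  }
  if (p$t_end <= p$t_start) stop("t_end must exceed t_start")
  if (p$mode == "basal_gate" && p$lambda <= 0)
    stop("lambda must be > 0 in basal_gate mode")
  if (p$S_halfwidth > p$S_mean) stop("S_halfwidth must not exceed S_mean")
  if (p$d_mz >= p$box_height) stop("d_mz must be smaller than box_height")
  structure(unclass(p)[names(schema)], class = "iknm_params")
}

#' @export
print.iknm_params <- function(x, ...) {
  cat("IKNM model parameters (", x$mode, " mode)\n", sep = "")
  schema <- .param_schema()
  for (nm in names(schema)) {
    v <- x[[nm]]
    cat(sprintf("  %-16s %s\n", nm, paste(format(v, digits = 6), collapse = ", ")))
  }
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' The file holds flat `key: value` pairs matching the parameter schema
#' (see [model_params()]); unknown keys or out-of-range values are
#' rejected.
#'
#' @param path file path.
#' @return an `iknm_params` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must contain a key-value mapping")
  do.call(model_params, raw)
}

#' Write a run configuration to a YAML file
#'
#' @param p an `iknm_params` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  p <- validate_params(p)
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}
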