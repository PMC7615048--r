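# Summary statistics computed from trajectories and event logs. Every
# function here is a pure function of the recorded tables; recomputation is
# idempotent and independent of replicate order.

# coerce input to a list of trajectories
#' @keywords internal
.traj_list <- function(x) {
  if (inherits(x, "iknm_ensemble")) return(unclass(x))
  if (inherits(x, "iknm_trajectory")) return(list(x))
  stop("expected an iknm_trajectory or iknm_ensemble")
}

# three-way phase label: M counted with G2 by default (a FUCCI-style
# census cannot distinguish M)
#' @keywords internal
phase3 <- function(phase, M_with_G2 = TRUE) {
  if (M_with_G2) ifelse(phase == "M", "G2", phase) else phase
}

# rebuild polygon matrices from serialized snapshot rows
#' @keywords internal
snap_polygons <- function(rows) {
  vcols <- paste0(rep(c("x", "z"), N_VERTICES),
                  rep(seq_len(N_VERTICES), each = 2L))
  V <- as.matrix(rows[, vcols, drop = FALSE])
  lapply(seq_len(nrow(V)), function(i)
    matrix(V[i, ], ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("x", "z"))))
}

#' @keywords internal
nearest_snapshot_time <- function(traj, t) {
  tt <- unique(traj$snapshots$time)
  tt[which.min(abs(tt - t))]
}

#' Cell-cycle phase fractions over time
#'
#' Per-snapshot fractions of nuclei in G1, S and G2 (M pooled with G2 by
#' default). For an ensemble, fractions are computed per replicate and
#' averaged; `sd_*` columns carry the across-replicate standard deviations.
#'
#' @param x an `iknm_trajectory` or `iknm_ensemble`.
#' @param times snapshot times to evaluate (default: all snapshot times of
#'   the first replicate).
#' @param M_with_G2 count M-phase nuclei with G2.
#' @return data.frame with `time`, `f_G1`, `f_S`, `f_G2`, `n_total` (and
#'   `sd_G1`, `sd_S`, `sd_G2` for ensembles).
#' @export
phase_fractions <- function(x, times = NULL, M_with_G2 = TRUE) {
  trajs <- .traj_list(x)
  if (is.null(times)) times <- unique(trajs[[1L]]$snapshots$time)
  per_rep <- lapply(trajs, function(tr) {
    sn <- tr$snapshots
    t(vapply(times, function(tm) {
      rows <- sn[sn$time == nearest_snapshot_time(tr, tm), , drop = FALSE]
      if (nrow(rows) == 0L) stop("empty snapshot at t = ", tm)
      ph <- phase3(rows$phase, M_with_G2)
      c(f_G1 = mean(ph == "G1"), f_S = mean(ph == "S"),
        f_G2 = mean(ph == "G2"), n_total = nrow(rows))
    }, numeric(4L)))
  })
  arr <- simplify2array(per_rep)   # times x 4 x reps
  out <- data.frame(time = times, apply(arr, c(1L, 2L), mean))
  if (length(trajs) > 1L) {
    sds <- apply(arr[, 1:3, , drop = FALSE], c(1L, 2L), stats::sd)
    colnames(sds) <- c("sd_G1", "sd_S", "sd_G2")
    out <- cbind(out, sds)
  }
  out
}

#' Apical-basal distribution of nuclei by phase
#'
#' Bins nuclei by centroid depth below the local apical surface
#' (`apical_z - cz`) into half-open slices `[k w, (k+1) w)` of width
#' `bin_width` (default half a G1 nucleus diameter) and normalizes each
#' phase's per-bin count by the total number of nuclei, so the fractions
#' over all bins and phases sum to 1.
#'
#' @param x trajectory/ensemble or a data.frame of snapshot rows.
#' @param time snapshot time to use (nearest match; ignored when `x` is a
#'   raw data.frame).
#' @param bin_width slice depth in `G1d`.
#' @param M_with_G2 count M-phase nuclei with G2.
#' @return data.frame `bin_lo`, `bin_hi`, `phase`, `fraction`, `count`,
#'   pooled over replicates for ensembles.
#' @export
ab_distribution <- function(x, time = NULL, bin_width = 0.5, M_with_G2 = TRUE) {
  rows <- if (is.data.frame(x)) x else {
    do.call(rbind, lapply(.traj_list(x), function(tr) {
      tm <- if (is.null(time)) max(tr$snapshots$time) else
        nearest_snapshot_time(tr, time)
      tr$snapshots[tr$snapshots$time == tm, , drop = FALSE]
    }))
  }
  if (nrow(rows) == 0L) stop("empty snapshot")
  depth <- rows$apical_z - rows$cz
  ph <- phase3(rows$phase, M_with_G2)
  k <- pmax(0L, floor(depth / bin_width))
  n_tot <- nrow(rows)
  tab <- as.data.frame(table(bin = k, phase = ph), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L | TRUE, , drop = FALSE]
  data.frame(
    bin_lo = as.numeric(tab$bin) * bin_width,
    bin_hi = (as.numeric(tab$bin) + 1) * bin_width,
    phase = tab$phase,
    fraction = tab$Freq / n_tot,
    count = tab$Freq)
}

#' Crowding indices of nuclei in a snapshot
#'
#' 2D analogue of the voxel-based in vivo crowding measure: each nucleus's
#' bounding rectangle is expanded by `margin_x` laterally and `margin_z`
#' apico-basally, clipped to the box, and the index is the fraction of the
#' available neighborhood area (rectangle minus the focal nucleus) covered
#' by other nuclei. Nuclei whose expanded rectangle crosses a lateral wall
#' are excluded, mirroring the in vivo exclusion of border nuclei.
#'
#' @param x trajectory or ensemble.
#' @param time snapshot time (nearest match).
#' @param margin_x,margin_z rectangle margins in `G1d`; the defaults mirror
#'   the anisotropy of the in vivo 3D box (wider laterally than axially).
#' @return data.frame `time`, `id`, `crowding` in `[0, 1]`, pooled over
#'   replicates.
#' @export
crowding_indices <- function(x, time, margin_x = 0.75, margin_z = 0.25) {
  trajs <- .traj_list(x)
  do.call(rbind, lapply(trajs, function(tr) {
    tm <- nearest_snapshot_time(tr, time)
    rows <- tr$snapshots[tr$snapshots$time == tm, , drop = FALSE]
    fr <- tr$frames[which.min(abs(tr$frames$time - tm)), , drop = FALSE]
    polys <- snap_polygons(rows)
    out <- lapply(seq_len(nrow(rows)), function(i) {
      idx <- crowding_index_one(polys, i, rows$apical_z[i],
                                fr$xL, fr$xR, margin_x, margin_z)
      if (is.na(idx)) return(NULL)
      data.frame(time = tm, id = rows$id[i], crowding = idx)
    })
    do.call(rbind, out)
  }))
}

# crowding of polygon i among polys; NA if the expanded rectangle crosses
# a lateral wall (border exclusion)
#' @keywords internal
crowding_index_one <- function(polys, i, apical_z, xL, xR,
                               margin_x, margin_z) {
  p <- polys[[i]]
  x0 <- min(p[, 1L]) - margin_x; x1 <- max(p[, 1L]) + margin_x
  if (x0 < xL || x1 > xR) return(NA_real_)
  z0 <- max(min(p[, 2L]) - margin_z, 0)
  z1 <- min(max(p[, 2L]) + margin_z, apical_z)
  if (z1 <= z0 || x1 <= x0) stop("empty neighborhood rectangle")
  rect <- cbind(c(x0, x1, x1, x0), c(z0, z0, z1, z1))
  rect_area <- (x1 - x0) * (z1 - z0)
  focal <- overlap_area(p, rect)
  avail <- rect_area - focal
  if (avail <= 0) return(1)
  occ <- 0
  for (j in seq_along(polys)) {
    if (j == i) next
    q <- polys[[j]]
    if (min(q[, 1L]) > x1 || max(q[, 1L]) < x0 ||
        min(q[, 2L]) > z1 || max(q[, 2L]) < z0) next
    occ <- occ + overlap_area(q, rect)
  }
  min(1, occ / avail)
}

# pooled event table with replicate index
#' @keywords internal
.pooled_events <- function(x) {
  trajs <- .traj_list(x)
  do.call(rbind, lapply(seq_along(trajs), function(i) {
    ev <- trajs[[i]]$events
    if (is.null(ev) || nrow(ev) == 0L) return(NULL)
    cbind(ev, rep = i)
  }))
}

#' G2 durations per completed lineage
#'
#' Duration from G2 entry (`SG2` event) to the corresponding `DIVISION` of
#' the same nucleus, assigned to the time of G2 entry. Nuclei that never
#' divide are excluded here (they are the G2-arrested set, see
#' [g2_arrested()]). The returned series aggregates durations in bins of
#' `bin` hours of G2-entry time.
#'
#' @param x trajectory/ensemble or an event data.frame.
#' @param bin bin width in hours for the aggregated series.
#' @return list with `durations` (per-lineage data.frame `id`, `g2_entry`,
#'   `duration`, `rep`) and `series` (`bin_mid`, `mean`, `sd`, `n`).
#' @export
g2_durations <- function(x, bin = 12) {
  ev <- if (is.data.frame(x)) cbind(x, rep = 1L) else .pooled_events(x)
  sg2 <- ev[ev$event == "SG2", , drop = FALSE]
  div <- ev[ev$event == "DIVISION", , drop = FALSE]
  if (nrow(div) > 0L) {
    key_div <- paste(div$rep, div$id)
    key_sg2 <- paste(sg2$rep, sg2$id)
    if (!all(key_div %in% key_sg2))
      stop("orphan DIVISION events without matching SG2")
    m <- match(key_div, key_sg2)
    durations <- data.frame(
      id = div$id, rep = div$rep,
      g2_entry = sg2$time[m],
      duration = div$time - sg2$time[m])
  } else {
    durations <- data.frame(id = integer(0), rep = integer(0),
                            g2_entry = numeric(0), duration = numeric(0))
  }
  if (nrow(durations)) {
    t0 <- min(durations$g2_entry)
    b <- floor((durations$g2_entry - t0) / bin)
    agg <- do.call(rbind, lapply(split(durations, b), function(d) {
      k <- floor((d$g2_entry[1L] - t0) / bin)
      data.frame(bin_mid = t0 + k * bin + bin / 2,
                 mean = mean(d$duration), sd = stats::sd(d$duration),
                 n = nrow(d))
    }))
  } else agg <- data.frame(bin_mid = numeric(0), mean = numeric(0),
                           sd = numeric(0), n = integer(0))
  list(durations = durations, series = agg[order(agg$bin_mid), , drop = FALSE])
}

#' Cumulative G2-arrested nuclei
#'
#' Nuclei that entered G2 (`SG2`) but never divided by `t_end`, cumulated
#' over `bin`-hour intervals of G2-entry time. Together with
#' [g2_durations()] this partitions the set of G2 entries exactly.
#'
#' @param x trajectory/ensemble or event data.frame.
#' @param t_end end of the observation interval (default: latest event
#'   time).
#' @param bin bin width (h).
#' @return data.frame `bin_end`, `arrested_in_bin`, `cumulative` (ensemble
#'   totals across replicates).
#' @export
g2_arrested <- function(x, t_end = NULL, bin = 12) {
  ev <- if (is.data.frame(x)) cbind(x, rep = 1L) else .pooled_events(x)
  if (is.null(ev) || nrow(ev) == 0L)
    return(data.frame(bin_end = numeric(0), arrested_in_bin = integer(0),
                      cumulative = integer(0)))
  if (is.null(t_end)) t_end <- max(ev$time)
  sg2 <- ev[ev$event == "SG2" & ev$time <= t_end, , drop = FALSE]
  div <- ev[ev$event == "DIVISION" & ev$time <= t_end, , drop = FALSE]
  divided <- paste(div$rep, div$id)
  arr <- sg2[!paste(sg2$rep, sg2$id) %in% divided, , drop = FALSE]
  t0 <- min(sg2$time, t_end)
  edges <- seq(t0, t_end + bin, by = bin)
  counts <- vapply(seq_len(length(edges) - 1L), function(k)
    sum(arr$time >= edges[k] & arr$time < edges[k + 1L]), 0L)
  data.frame(bin_end = edges[-1L], arrested_in_bin = counts,
             cumulative = cumsum(counts))
}

#' Terminal pre-mitotic velocity
#'
#' Apical-ward centroid velocity of each dividing nucleus over the
#' `window` hours preceding its division (`G1d`/h), reported against
#' division time, with a degree-3 least-squares polynomial trend and the
#' trend's end/begin ratio (a value below 1 means terminal migration has
#' slowed as the tissue aged).
#'
#' @param x trajectory or ensemble.
#' @param window averaging window before division (h).
#' @return list with `velocities` (`time`, `id`, `rep`, `velocity`),
#'   `trend` (fitted `lm`), and `ratio_end_begin`.
#' @export
terminal_velocity <- function(x, window = 1) {
  trajs <- .traj_list(x)
  cad <- diff(sort(unique(trajs[[1L]]$snapshots$time)))[1L]
  if (is.na(cad) || cad > window / 4 + 1e-9)
    stop(sprintf("snapshot cadence %.3f h too coarse for a %.2f h window (need <= window/4)",
                 cad, window))
  vel <- do.call(rbind, lapply(seq_along(trajs), function(r) {
    tr <- trajs[[r]]
    div <- tr$events[tr$events$event == "DIVISION", , drop = FALSE]
    if (nrow(div) == 0L) return(NULL)
    sn <- tr$snapshots
    out <- lapply(seq_len(nrow(div)), function(k) {
      id <- div$id[k]; td <- div$time[k]
      tr_id <- sn[sn$id == id, , drop = FALSE]
      t1 <- max(tr_id$time[tr_id$time <= td])
      t0_target <- td - window
      if (min(tr_id$time) > t0_target + cad / 2) return(NULL)
      t0 <- tr_id$time[which.min(abs(tr_id$time - t0_target))]
      if (t1 <= t0) return(NULL)
      z1 <- tr_id$cz[tr_id$time == t1][1L]
      z0 <- tr_id$cz[tr_id$time == t0][1L]
      data.frame(time = td, id = id, rep = r,
                 velocity = (z1 - z0) / (t1 - t0))
    })
    do.call(rbind, out)
  }))
  if (is.null(vel) || nrow(vel) < 4L)
    stop("insufficient divisions/snapshot coverage for terminal velocity")
  fit <- stats::lm(velocity ~ poly(time, 3, raw = TRUE), data = vel)
  # begin/end read off the fitted trend at the 5th/95th percentiles of
  # division times: the cubic is unreliable at the extreme endpoints
  tq <- stats::quantile(vel$time, c(0.05, 0.95), names = FALSE)
  pr <- stats::predict(fit, newdata = data.frame(time = tq))
  list(velocities = vel, trend = fit,
       ratio_end_begin = pr[[2L]] / pr[[1L]])
}

#' Tissue thickness and nuclear layering of a snapshot
#'
#' Thickness is the mean apical boundary height; the occupied span is the
#' 2.5-97.5% interquantile range of centroid depths; the layer estimate is
#' `span / diameter + 1`, with the mean nuclear diameter taken from each
#' nucleus's area (centroids of k touching layers span k - 1 diameters, so
#' a single layer scores 1).
#'
#' @param x trajectory/ensemble.
#' @param time snapshot time (nearest match).
#' @return data.frame with one row per replicate: `time`, `thickness`,
#'   `span`, `layers`, `n`.
#' @export
thickness_and_layers <- function(x, time) {
  trajs <- .traj_list(x)
  do.call(rbind, lapply(trajs, function(tr) {
    tm <- nearest_snapshot_time(tr, time)
    rows <- tr$snapshots[tr$snapshots$time == tm, , drop = FALSE]
    if (nrow(rows) == 0L) stop("empty snapshot")
    fr <- tr$frames[which.min(abs(tr$frames$time - tm)), , drop = FALSE]
    depth <- rows$apical_z - rows$cz
    span <- if (nrow(rows) > 1L)
      diff(stats::quantile(depth, c(0.025, 0.975), names = FALSE)) else 0
    diam <- mean(2 * sqrt(rows$area / pi))
    data.frame(time = tm, thickness = fr$h_mean, span = span,
               layers = span / diam + 1, n = nrow(rows))
  }))
}

#' Nuclear shape index
#'
#' 2D analogue of the volume-to-longest-axis ratio: polygon area divided by
#' the maximum pairwise vertex distance (`G1d`). Elongation at fixed area
#' decreases the index.
#'
#' @param p a polygon matrix.
#' @return numeric scalar.
#' @export
shape_index <- function(p) {
  polygon_area(p) / max_extent(p)
}
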