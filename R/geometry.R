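# Exact 2D polygon primitives underlying the mechanics and analysis.
#
# A polygon is an n x 2 numeric matrix of vertices (columns x, z), ordered
# counter-clockwise. Nuclei are always 20-gons; the primitives accept any
# n >= 3 so that intermediate constructions (half-plane clips during
# division, box intersections) can be handled before resampling back to 20
# vertices.

N_VERTICES <- 20L

#' Validate a polygon matrix
#'
#' Checks that `p` is a numeric matrix with two columns, finite entries,
#' at least three vertices, and (optionally) positive signed area.
#'
#' @param p numeric matrix, one vertex per row, columns `x` and `z`.
#' @param n_required if not `NULL`, the exact vertex count demanded
#'   (nuclei use 20 everywhere).
#' @param check_ccw require positive signed area.
#' @return `p`, invisibly, after validation.
#' @keywords internal
validate_polygon <- function(p, n_required = NULL, check_ccw = TRUE) {
  if (!is.matrix(p) || !is.numeric(p) || ncol(p) != 2L)
    stop("polygon must be a numeric matrix with 2 columns (x, z)")
  if (!all(is.finite(p)))
    stop("invalid geometry: non-finite vertex coordinates")
  if (nrow(p) < 3L)
    stop("polygon needs at least 3 vertices")
  if (!is.null(n_required) && nrow(p) != n_required)
    stop("polygon must have exactly ", n_required, " vertices, got ", nrow(p))
  if (check_ccw && polygon_area(p) <= 0)
    stop("polygon must be counter-clockwise (signed area > 0)")
  invisible(p)
}

#' Signed (shoelace) area of a polygon
#'
#' @param p polygon matrix (vertices CCW for positive area).
#' @return Signed area in `G1d^2`; positive for counter-clockwise input.
#' @examples
#' polygon_area(regular_polygon(c(0, 0), area = pi / 4))
#' @export
polygon_area <- function(p) {
  if (!all(is.finite(p))) stop("invalid geometry: non-finite vertex coordinates")
  x <- p[, 1L]; z <- p[, 2L]
  xn <- c(x[-1L], x[1L]); zn <- c(z[-1L], z[1L])
  sum(x * zn - xn * z) / 2
}

#' Area-weighted centroid of a polygon
#'
#' Standard polygon centroid (first moment of area over area). Errors on
#' near-degenerate polygons whose area underflows the moment formula.
#'
#' @inheritParams polygon_area
#' @return length-2 numeric `(x, z)`.
#' @export
polygon_centroid <- function(p) {
  a <- polygon_area(p)
  if (abs(a) < 1e-12)
    stop("degenerate geometry: polygon area ~ 0, centroid undefined")
  x <- p[, 1L]; z <- p[, 2L]
  xn <- c(x[-1L], x[1L]); zn <- c(z[-1L], z[1L])
  cr <- x * zn - xn * z
  c(sum((x + xn) * cr), sum((z + zn) * cr)) / (6 * a)
}

#' Convexity predicate for a polygon
#'
#' TRUE iff every consecutive-edge cross product is `>= -tol * L^2`, where
#' `L` is the mean edge length. The tolerance is relative (scaled by the
#' squared mean edge length) so the predicate is invariant under uniform
#' scaling.
#'
#' @inheritParams polygon_area
#' @param tol relative tolerance (default `1e-8`).
#' @return logical scalar.
#' @export
is_convex <- function(p, tol = 1e-8) {
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  e <- p[nxt, , drop = FALSE] - p
  L <- mean(sqrt(rowSums(e^2)))
  cross <- e[, 1L] * e[nxt, 2L] - e[, 2L] * e[nxt, 1L]
  all(cross >= -tol * L^2)
}

#' Maximum extent (largest pairwise vertex distance)
#'
#' The 2D analogue of a nucleus's longest axis `lmax`.
#'
#' @inheritParams polygon_area
#' @return length in `G1d`.
#' @export
max_extent <- function(p) {
  d <- stats::dist(p)
  max(d)
}

#' Intersection area of two convex polygons
#'
#' Clips `p` against each edge of `q` (Sutherland-Hodgman) and returns the
#' area of the intersection; 0 when disjoint. Both polygons must be convex
#' and counter-clockwise.
#'
#' @param p,q convex polygon matrices (CCW).
#' @return overlap area in `G1d^2` (non-negative).
#' @export
overlap_area <- function(p, q) {
  r <- clip_convex(p, q)
  if (is.null(r) || nrow(r) < 3L) return(0)
  abs(polygon_area(r))
}

# Sutherland-Hodgman clip of polygon p by convex CCW polygon q.
# Returns the clipped vertex matrix or NULL if empty.
#' @keywords internal
clip_convex <- function(p, q) {
  out <- p
  nq <- nrow(q)
  for (i in seq_len(nq)) {
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    a <- q[i, ]
    b <- q[if (i == nq) 1L else i + 1L, ]
    out <- clip_halfplane(out, a, b)
  }
  out
}

# Clip polygon `p` to the half-plane left of directed line a -> b
# (the inside of a CCW polygon's edge).
#' @keywords internal
clip_halfplane <- function(p, a, b) {
  n <- nrow(p)
  if (n == 0L) return(NULL)
  ex <- b[1L] - a[1L]; ez <- b[2L] - a[2L]
  side <- ex * (p[, 2L] - a[2L]) - ez * (p[, 1L] - a[1L])
  keep_all <- all(side >= 0)
  if (keep_all) return(p)
  if (all(side <= 0)) return(NULL)
  out <- matrix(0, nrow = 2L * n, ncol = 2L)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    si <- side[i]; sj <- side[j]
    if (si >= 0) {
      m <- m + 1L
      out[m, ] <- p[i, ]
    }
    if ((si > 0 && sj < 0) || (si < 0 && sj > 0)) {
      t <- si / (si - sj)
      m <- m + 1L
      out[m, ] <- p[i, ] + t * (p[j, ] - p[i, ])
    }
  }
  if (m < 3L) return(NULL)
  out[seq_len(m), , drop = FALSE]
}

#' Regular 20-gon of given area
#'
#' Constructs the rest shape of a nucleus: a regular 20-sided polygon of
#' area `area` centred at `center`, vertices counter-clockwise starting at
#' angle `phase0`.
#'
#' @param center length-2 numeric `(x, z)`.
#' @param area target area (`G1d^2`), must be positive. A spherical G1
#'   nucleus of diameter 1 `G1d` has cross-section area `pi/4`.
#' @param n vertex count (fixed to 20 for nuclei).
#' @param phase0 angular offset of the first vertex (radians).
#' @return an `n x 2` polygon matrix.
#' @export
regular_polygon <- function(center, area, n = N_VERTICES, phase0 = pi / n) {
  if (!is.numeric(area) || length(area) != 1L || !is.finite(area) || area <= 0)
    stop("area must be a positive finite scalar")
  # A = n R^2 sin(2 pi / n) / 2  =>  R
  R <- sqrt(2 * area / (n * sin(2 * pi / n)))
  th <- phase0 + 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = center[1L] + R * cos(th), z = center[2L] + R * sin(th))
}

#' Distance from a point to a closed segment
#'
#' @param pt length-2 numeric.
#' @param a,b segment endpoints (must differ).
#' @return Euclidean distance from `pt` to the segment `[a, b]`.
#' @export
point_segment_distance <- function(pt, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  if (L2 == 0) stop("degenerate segment: a == b")
  t <- sum((pt - a) * ab) / L2
  t <- min(1, max(0, t))
  proj <- a + t * ab
  sqrt(sum((pt - proj)^2))
}

#' Resample a polygon boundary to n vertices by equal arc length
#'
#' Places `n` points at equal arc-length spacing along the boundary of `p`.
#' Convexity is preserved (resampled points lie on the boundary of a convex
#' polygon). Used to bring division halves and convexified shapes back to
#' the fixed 20-vertex representation.
#'
#' @param p polygon matrix (CCW).
#' @param n number of output vertices.
#' @return an `n x 2` polygon matrix.
#' @export
resample_polygon <- function(p, n = N_VERTICES) {
  m <- nrow(p)
  nxt <- c(2:m, 1L)
  seg <- sqrt(rowSums((p[nxt, , drop = FALSE] - p)^2))
  per <- sum(seg)
  if (per <= 0) stop("degenerate geometry: zero-perimeter polygon")
  cum <- c(0, cumsum(seg))
  s <- per * (seq_len(n) - 1L) / n
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > m] <- m
  t <- (s - cum[idx]) / seg[idx]
  t[!is.finite(t)] <- 0
  p[idx, , drop = FALSE] + t * (p[nxt[idx], , drop = FALSE] - p[idx, , drop = FALSE])
}

#' Scale a polygon about its centroid to an exact target area
#'
#' @param p polygon matrix.
#' @param target_area desired area.
#' @return polygon with `polygon_area(p) == target_area` to machine precision.
#' @keywords internal
scale_to_area <- function(p, target_area) {
  a <- polygon_area(p)
  if (a <= 0) stop("degenerate geometry: non-positive area")
  ctr <- polygon_centroid(p)
  s <- sqrt(target_area / a)
  sweep(sweep(p, 2L, ctr, "-") * s, 2L, ctr, "+")
}

# Convexify: replace by convex hull (resampled back to the input vertex
# count) if the convexity predicate fails. Area is restored exactly.
#' @keywords internal
convexify <- function(p, tol = 1e-8) {
  if (is_convex(p, tol)) return(p)
  target <- polygon_area(p)
  h <- grDevices::chull(p)          # clockwise indices
  hull <- p[rev(h), , drop = FALSE] # make CCW
  scale_to_area(resample_polygon(hull, nrow(p)), target)
}
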