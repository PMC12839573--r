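#' Closed planar contours
#'
#' A `contour` is an ordered list of planar vertices forming an implicitly
#' closed simple polyline: vertex `N` connects back to vertex 1. The curve
#' parameter runs over `[0, 1)` with vertex `i` sitting at `t = (i-1)/N`.
#' Vertices are stored as an `N x 2` numeric matrix with columns `x`, `y`;
#' the y axis points up.
#'
#' @param x Numeric vector of x coordinates, or a two-column matrix /
#'   data frame of vertices.
#' @param y Numeric vector of y coordinates (omit when `x` is a matrix).
#' @param name Optional contour name, kept as an attribute.
#' @return An object of class `contour`.
#' @examples
#' sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polyline_length(sq)
#' signed_area(sq)
#' @export
contour <- function(x, y = NULL, name = NULL) {
  v <- if (is.null(y)) {
    m <- as.matrix(x)
    if (ncol(m) != 2L) stop("vertex matrix must have two columns (x, y)")
    m
  } else {
    cbind(x, y)
  }
  storage.mode(v) <- "double"
  dimnames(v) <- list(NULL, c("x", "y"))
  out <- structure(v, class = c("contour", "matrix", "array"))
  if (!is.null(name)) attr(out, "name") <- name
  validate_contour(out)
  out
}

#' Coerce to a contour
#' @param x A `contour`, matrix or data frame of vertices.
#' @return A `contour`.
#' @export
as_contour <- function(x) {
  if (inherits(x, "contour")) return(x)
  contour(x)
}

validate_contour <- function(c) {
  v <- unclass(c)
  if (!is.matrix(v) || ncol(v) != 2L)
    stop("invalid contour: expected an N x 2 vertex matrix")
  if (nrow(v) < 3L)
    stop("invalid contour: fewer than 3 vertices")
  if (anyNA(v) || any(!is.finite(v)))
    stop("invalid contour: non-finite vertex coordinates")
  len <- edge_lengths(v)
  if (any(len == 0))
    stop("invalid contour: consecutive vertices coincide (zero-length edge)")
  invisible(c)
}

# vertex matrix without the contour class (fast internal accessor)
cxy <- function(c) {
  v <- unclass(c)
  attributes(v) <- list(dim = dim(v))
  v
}

new_contour <- function(v, template = NULL) {
  dimnames(v) <- list(NULL, c("x", "y"))
  out <- structure(v, class = c("contour", "matrix", "array"))
  if (!is.null(template) && !is.null(attr(template, "name")))
    attr(out, "name") <- attr(template, "name")
  out
}

# edge vectors v[i+1] - v[i] including the closing edge (N rows)
edge_vectors <- function(v) {
  rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]) - v
}

edge_lengths <- function(v) {
  e <- edge_vectors(v)
  sqrt(e[, 1L]^2 + e[, 2L]^2)
}

#' @export
print.contour <- function(x, ...) {
  nm <- attr(x, "name")
  cat(sprintf("<contour%s: %d vertices, length %.6g, signed area %.6g>\n",
              if (is.null(nm)) "" else paste0(" '", nm, "'"),
              nrow(x), polyline_length(x), signed_area(x)))
  invisible(x)
}

#' @export
plot.contour <- function(x, ..., asp = 1, type = "l", mark_start = TRUE) {
  v <- cxy(x)
  closed <- rbind(v, v[1L, ])
  graphics::plot(closed, asp = asp, type = type, xlab = "x", ylab = "y", ...)
  if (mark_start) graphics::points(v[1L, 1L], v[1L, 2L], pch = 19)
  invisible(x)
}

#' Perimeter of a closed contour
#'
#' Sum of Euclidean edge lengths including the closing edge. A geometric
#' invariant: unchanged by cyclic rolls of the vertex list and by
#' orientation reversal.
#'
#' @param c A [contour].
#' @return Positive scalar length.
#' @export
polyline_length <- function(c) {
  c <- as_contour(c)
  sum(edge_lengths(cxy(c)))
}

#' Signed enclosed area (shoelace formula)
#'
#' Positive for counterclockwise travel, negative for clockwise.
#'
#' @param c A [contour].
#' @return Scalar signed area.
#' @export
signed_area <- function(c) {
  c <- as_contour(c)
  v <- cxy(c)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

#' Center of mass of the contour (boundary centroid)
#'
#' Arc-length-weighted mean of the boundary points, discretized exactly per
#' edge as edge-midpoint times edge length, divided by the total length.
#' Invariant under resampling of the same polyline.
#'
#' @param c A [contour].
#' @return Numeric length-2 point `(x, y)`.
#' @export
contour_centroid <- function(c) {
  c <- as_contour(c)
  v <- cxy(c)
  len <- edge_lengths(v)
  mid <- (v + rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])) / 2
  colSums(mid * len) / sum(len)
}

#' Center of gravity of the enclosed area
#'
#' Centroid of the region enclosed by the contour via the polygon-centroid
#' shoelace formulas; independent of orientation.
#'
#' @param c A [contour].
#' @return Numeric length-2 point `(x, y)`.
#' @export
area_centroid <- function(c) {
  c <- as_contour(c)
  v <- cxy(c)
  a <- signed_area(c)
  if (abs(a) < 1e-12 * max(polyline_length(c)^2, .Machine$double.eps))
    stop("degenerate contour: enclosed area is (near) zero")
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  cx <- sum((x + xn) * cross) / (6 * a)
  cy <- sum((y + yn) * cross) / (6 * a)
  c(cx, cy)
}

#' Discrete signed curvature profile
#'
#' Per-vertex signed curvature: the exterior turning angle at vertex `i`
#' divided by the mean of the two adjacent half-edge lengths. Positive for
#' counterclockwise turning; the profile flips sign globally when the
#' contour's orientation is reversed, and the turning angles sum to `2*pi`
#' for a simple counterclockwise contour.
#'
#' @param c A [contour].
#' @return Numeric vector of length `N` (units 1/length), aligned with the
#'   vertices; the turning angles are attached as attribute `"turning"`.
#' @export
signed_curvature <- function(c) {
  c <- as_contour(c)
  v <- cxy(c)
  e <- edge_vectors(v)
  len <- sqrt(e[, 1L]^2 + e[, 2L]^2)
  heading <- atan2(e[, 2L], e[, 1L])
  n <- nrow(v)
  # turning at vertex i: heading of edge leaving i minus heading of edge
  # arriving at i (edge i-1), wrapped to (-pi, pi]
  prev <- c(n, seq_len(n - 1L))
  turn <- wrap_angle(heading - heading[prev])
  kappa <- turn / ((len[prev] + len) / 2)
  attr(kappa, "turning") <- turn
  kappa
}

# wrap angles to (-pi, pi]
wrap_angle <- function(a) {
  w <- a %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Unwrapped winding-angle function about an interior reference point
#'
#' Angle of the vector from `ref` to the moving contour point, measured from
#' the upward vertical at the start and accumulated continuously along the
#' travel direction, so `w[1] = 0` and the final value is `2*pi` times the
#' winding number (`+2*pi` for a counterclockwise simple contour with an
#' interior reference point).
#'
#' @param c A [contour].
#' @param ref Interior reference point `(x, y)`.
#' @return Numeric vector of `N + 1` radians (vertex grid plus the closing
#'   return to vertex 1).
#' @export
winding_angle <- function(c, ref) {
  c <- as_contour(c)
  if (!point_in_polygon(ref, c))
    stop("reference point is not strictly interior to the contour")
  v <- cxy(c)
  v <- rbind(v, v[1L, , drop = FALSE])
  dx <- v[, 1L] - ref[1L]
  dy <- v[, 2L] - ref[2L]
  raw <- atan2(dy, dx) - pi / 2            # angle from the upward vertical
  steps <- wrap_angle(diff(raw))
  c(0, cumsum(steps))
}

#' Monotone parameter maps on [0, 1]
#'
#' A `param_map` stores values of a non-decreasing map of `[0, 1]` onto
#' itself on the uniform grid `t_j = (j-1)/(M-1)`, with fixed endpoints
#' `0` and `1`. Strictly increasing maps are discrete reparameterizations;
#' weakly monotone maps (plateaus) arise as the `lambda = 0` limit of the
#' curvature-weighted family and belong to the semi-group of generalized
#' reparameterizations.
#'
#' @param values Numeric vector of map values on the uniform grid.
#' @param strict Require strict monotonicity (default `TRUE`).
#' @return An object of class `param_map`.
#' @export
param_map <- function(values, strict = TRUE) {
  values <- as.numeric(values)
  m <- length(values)
  if (m < 2L) stop("param_map needs at least two grid values")
  tol <- 1e-12
  if (abs(values[1L]) > tol || abs(values[m] - 1) > tol)
    stop("param_map must fix the endpoints: values[1] = 0, values[M] = 1")
  values[1L] <- 0; values[m] <- 1
  d <- diff(values)
  if (any(d < -tol)) stop("param_map values must be non-decreasing")
  values <- cummax(values)                 # clamp tiny negative drifts
  if (strict && any(diff(values) <= 0))
    stop("param_map is not strictly increasing (use strict = FALSE for generalized maps)")
  structure(list(values = values, grid = seq(0, 1, length.out = m)),
            class = "param_map")
}

#' @export
print.param_map <- function(x, ...) {
  cat(sprintf("<param_map on %d grid points%s>\n", length(x$values),
              if (any(diff(x$values) == 0)) ", generalized (plateaus)" else ""))
  invisible(x)
}

# leftmost-preimage inversion of a non-decreasing tabulated map:
# for each target u, the smallest s with W(s) >= u, where W is piecewise
# linear through (s, W). Plateau values map to the plateau's left edge.
invert_monotone <- function(s, W, u) {
  n <- length(W)
  eps <- 1e-9 * max(abs(W[n]), 1)
  if (any(u < W[1L] - eps | u > W[n] + eps))
    stop("inversion target outside the map range")
  u <- pmin(pmax(u, W[1L]), W[n])
  j <- findInterval(u, W, left.open = TRUE) + 1L   # first index with W[j] >= u
  j <- pmin(j, n)
  out <- s[j]
  inner <- j > 1L & W[j] > u
  if (any(inner)) {
    ji <- j[inner]
    f <- (u[inner] - W[ji - 1L]) / (W[ji] - W[ji - 1L])
    out[inner] <- s[ji - 1L] + f * (s[ji] - s[ji - 1L])
  }
  out
}

# evaluate the closed polyline at parameters t in [0, 1); vertex i at (i-1)/N.
# parameters landing (within 1e-9 index units) on a vertex return it exactly.
eval_contour <- function(c, tt) {
  v <- cxy(c)
  n <- nrow(v)
  pos <- (tt %% 1) * n
  r <- round(pos)
  snap <- abs(pos - r) < 1e-9
  pos[snap] <- r[snap]
  i0 <- floor(pos) %% n
  f <- pos - floor(pos)
  i1 <- (i0 + 1L) %% n
  p <- v[i0 + 1L, , drop = FALSE] * (1 - f) + v[i1 + 1L, , drop = FALSE] * f
  exact <- f == 0
  if (any(exact)) p[exact, ] <- v[i0[exact] + 1L, , drop = FALSE]
  p
}

#' Resample a contour through a parameter map
#'
#' Realizes `gamma o Phi^{-1}` on samples: returns the contour evaluated at
#' parameters `Phi^{-1}(j / N_out)`, `j = 0, ..., N_out - 1`, using monotone
#' piecewise-linear inversion of the map and piecewise-linear evaluation of
#' the polyline. Plateaus of a generalized map are inverted to their left
#' edge. The identity map with `n_out` equal to the vertex count returns the
#' input vertices exactly.
#'
#' @param c A [contour].
#' @param m A [param_map].
#' @param n_out Number of output vertices (>= 3).
#' @return A [contour] with `n_out` vertices.
#' @export
apply_param_map <- function(c, m, n_out = nrow(c)) {
  c <- as_contour(c)
  if (!inherits(m, "param_map")) stop("m must be a param_map")
  if (n_out < 3L) stop("n_out must be at least 3")
  u <- seq_len(n_out) - 1
  u <- u / n_out
  tt <- invert_monotone(m$grid, m$values, u)
  new_contour(eval_contour(c, tt), template = c)
}

#' Strict point-in-polygon test (even-odd rule)
#'
#' `TRUE` iff the point is strictly interior; points on the boundary are
#' reported not-interior.
#'
#' @param p Point `(x, y)` or an `M x 2` matrix of points.
#' @param c A [contour].
#' @return Logical (vector of length `M` for a matrix input).
#' @export
point_in_polygon <- function(p, c) {
  c <- as_contour(c)
  v <- cxy(c)
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  n <- nrow(v)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  scale <- max(abs(v)) + 1
  btol <- 1e-12 * scale
  vapply(seq_len(nrow(p)), function(k) {
    px <- p[k, 1L]; py <- p[k, 2L]
    # boundary check: distance from point to each segment
    ex <- xn - x; ey <- yn - y
    tt <- pmin(pmax(((px - x) * ex + (py - y) * ey) / (ex^2 + ey^2), 0), 1)
    d2 <- (x + tt * ex - px)^2 + (y + tt * ey - py)^2
    if (min(d2) < btol^2) return(FALSE)
    # even-odd ray casting (ray towards +x)
    crosses <- ((y > py) != (yn > py)) &
      (px < x + (py - y) * (xn - x) / (yn - y))
    sum(crosses) %% 2L == 1L
  }, logical(1L))
}

# cumulative arc length at the N + 1 vertex grid points (0 .. L)
cum_arclength <- function(c) {
  v <- cxy(c)
  c(0, cumsum(edge_lengths(v)))
}
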