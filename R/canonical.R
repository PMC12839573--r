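#' Section parameters for the curvature-weighted clock family
#'
#' Identifies one section `s_{lambda, n}` of the reparameterization quotient:
#' `lam` is the curvature weight (`0` concentrates samples on curved pieces,
#' `Inf` is plain constant speed; `Inf` is a symbolic value, not a large
#' float), `n` the number of clock subdivisions (`0` disables the clock,
#' `n >= 2` cuts the curve into `n` sectors of equal winding angle at the
#' interior reference point), and `points` the output sample count.
#'
#' @param lam Curvature weight, `>= 0` or `Inf`.
#' @param n Clock subdivisions: `0` or an integer `>= 2`.
#' @param points Output sample count `N` (default 1000, must be `>= n`).
#' @return An object of class `section_params`.
#' @examples
#' section_params()                  # constant-speed section
#' section_params(lam = 1, n = 12)   # curvature-weighted clock
#' @export
section_params <- function(lam = Inf, n = 0L, points = 1000L) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
    stop("lam must be a single value >= 0 (Inf allowed)")
  n <- as.integer(n)
  if (is.na(n) || n < 0L || n == 1L)
    stop("n must be 0 (no clock subdivision) or an integer >= 2")
  points <- as.integer(points)
  if (is.na(points) || points < 3L || points < n)
    stop("points must be an integer >= max(3, n)")
  structure(list(lam = lam, n = n, points = points), class = "section_params")
}

#' @export
print.section_params <- function(x, ...) {
  cat(sprintf("<section s_(lambda = %s, n = %d), %d sample points>\n",
              format(x$lam), x$n, x$points))
  invisible(x)
}

#' Constant-speed (arc-length) parameter map
#'
#' The unique orientation-preserving map `psi` with `psi(t)` equal to the
#' cumulative length up to `t` divided by the total length, tabulated on the
#' vertex grid. Resampling through it yields edges of equal length.
#'
#' @param c A [contour].
#' @return A strictly increasing [param_map] on the `N + 1` vertex grid.
#' @export
arclength_map <- function(c) {
  c <- as_contour(c)
  s <- cum_arclength(c)
  param_map(s / s[length(s)])
}

#' Curvature-weighted parameter map
#'
#' The one-parameter family interpolating between sampling proportional to
#' curvature-length (`lam = 0`) and constant speed (`lam = Inf`): the map is
#' the normalized cumulative integral of
#' `(lam * Length(c) + |kappa|) * |gamma'|` along the curve, discretized by
#' the composite trapezoid rule on the vertex grid. `lam = Inf` returns
#' [arclength_map] exactly. `lam = 0` gives the normalized cumulative
#' `|kappa| ds`, which is only weakly monotone: it plateaus over flat
#' pieces, so flat pieces receive no sample points.
#'
#' @param c A [contour].
#' @param lam Curvature weight, `>= 0` or `Inf`.
#' @return A [param_map] (generalized, i.e. weakly monotone, when `lam = 0`).
#' @export
curvature_weighted_map <- function(c, lam) {
  c <- as_contour(c)
  if (identical(lam, Inf)) return(arclength_map(c))
  if (lam < 0) stop("lam must be >= 0")
  W <- cum_weighted_measure(c, lam)
  n1 <- length(W)
  if (W[n1] <= 1e-12)
    stop("degenerate curvature measure: total |kappa| ds is numerically zero")
  param_map(W / W[n1], strict = lam > 0)
}

# cumulative (lam * L + |kappa|) ds on the N + 1 vertex grid, trapezoid rule
cum_weighted_measure <- function(c, lam) {
  v <- cxy(c)
  len <- edge_lengths(v)
  L <- sum(len)
  kap <- abs(signed_curvature(c))
  w <- if (is.infinite(lam)) rep(1, length(kap)) else lam * L + kap
  wn <- c(w, w[1L])                       # closing node = first node
  c(0, cumsum(len * (wn[-length(wn)] + wn[-1L]) / 2))
}

#' Interior reference point for the clock construction
#'
#' Returns the area centroid when it lies strictly inside the contour. For
#' contours whose centroid falls outside (thin crescents and the like) a
#' deterministic fallback is used: triangles with one vertex at the boundary
#' point closest to the centroid and two other vertices on the contour are
#' scanned, and the interior triangle centroid nearest the area centroid is
#' chosen.
#'
#' @param c A [contour].
#' @param max_candidates Upper bound on boundary vertices scanned in the
#'   fallback (subsampled evenly; keeps the search quadratic, not cubic).
#' @return A list of class `reference_point` with fields `point` and
#'   `provenance` (`"area_centroid"` or `"fallback_triangle"`).
#' @export
reference_point <- function(c, max_candidates = 72L) {
  c <- as_contour(c)
  g <- area_centroid(c)
  if (point_in_polygon(g, c))
    return(structure(list(point = g, provenance = "area_centroid"),
                     class = "reference_point"))
  v <- cxy(c)
  n <- nrow(v)
  d2 <- (v[, 1L] - g[1L])^2 + (v[, 2L] - g[2L])^2
  p0 <- v[which.min(d2), ]
  idx <- unique(round(seq(1L, n, length.out = min(n, max_candidates))))
  best <- NULL; bestd <- Inf
  for (i in seq_along(idx)) {
    for (j in seq_along(idx)) {
      if (j <= i) next
      cen <- (p0 + v[idx[i], ] + v[idx[j], ]) / 3
      dd <- sum((cen - g)^2)
      if (dd < bestd && point_in_polygon(cen, c)) {
        best <- cen; bestd <- dd
      }
    }
  }
  if (is.null(best))
    stop("no interior reference point found for this contour")
  structure(list(point = best, provenance = "fallback_triangle"),
            class = "reference_point")
}

#' @export
print.reference_point <- function(x, ...) {
  cat(sprintf("<reference_point (%.6g, %.6g), %s>\n",
              x$point[1L], x$point[2L], x$provenance))
  invisible(x)
}

#' Clock keypoints: equal winding-angle cuts
#'
#' Keypoint `k` (`k = 0, ..., n - 1`) is the smallest arc-length fraction
#' `t` at which the unwrapped winding angle about `ref` first reaches
#' `2*pi*k/n` (first upward crossing, linearly interpolated on the angle
#' grid). Keypoint 0 is the start; the keypoints are strictly increasing and
#' the rays from `ref` to consecutive keypoints subtend equal angles
#' `2*pi/n`. The contour is expected to be counterclockwise with the start
#' already standardized; positions are expressed in the constant-speed
#' (arc-length) parameter.
#'
#' @param c A [contour].
#' @param ref A [reference_point] or interior point `(x, y)`.
#' @param n Number of subdivisions (`>= 2`).
#' @return Numeric vector of `n` parameters in `[0, 1)`.
#' @export
clock_keypoints <- function(c, ref, n) {
  c <- as_contour(c)
  if (inherits(ref, "reference_point")) ref <- ref$point
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  w <- winding_angle(c, ref)
  if (abs(w[length(w)] - 2 * pi) > 1e-6)
    stop("invalid winding: total winding angle is not +2*pi ",
         "(reference not interior, clockwise travel, or non-simple contour)")
  s <- cum_arclength(c)
  tau <- s / s[length(s)]
  targets <- 2 * pi * (seq_len(n) - 1) / n
  out <- numeric(n)
  out[1L] <- 0
  for (k in 2L:n) {
    tg <- targets[k]
    # first segment on which w crosses tg upward
    i <- which(w[-length(w)] < tg & w[-1L] >= tg)[1L]
    if (is.na(i)) stop("invalid winding: target angle never reached")
    f <- (tg - w[i]) / (w[i + 1L] - w[i])
    out[k] <- tau[i] + f * (tau[i + 1L] - tau[i])
  }
  out
}

# distribute N points over n sectors: floor(N/n) each, remainder to the
# first (N mod n) sectors in travel order
sector_counts <- function(N, n) {
  base <- N %/% n
  r <- N %% n
  base + as.integer(seq_len(n) <= r)
}

#' Resample a contour under a curvature-weighted clock section
#'
#' With `n = 0` the global curvature-weighted map for `lam` is applied and
#' `points` samples are placed at equal increments of the weighted measure.
#' With `n >= 2` the curve is first cut at the [clock_keypoints] (equal
#' winding angles at the interior reference point); each sector then
#' receives its allotted share of the `points` samples, placed at equal
#' increments of the sector-restricted curvature-weighted measure
#' (`lam = Inf` means uniform-in-arc-length within the sector). Each
#' keypoint is the first vertex of its sector and vertex 1 of the output is
#' the start point.
#'
#' @param c A [contour], already normalized (counterclockwise, start
#'   standardized).
#' @param params A [section_params].
#' @return A [contour] with exactly `params$points` vertices.
#' @export
canonical_resample <- function(c, params) {
  c <- as_contour(c)
  if (!inherits(params, "section_params")) stop("params must be section_params")
  N <- params$points
  nv <- nrow(c)
  tgrid <- (0:nv) / nv                 # vertex-grid parameter of the nodes
  s <- cum_arclength(c)
  L <- s[length(s)]
  W <- cum_weighted_measure(c, params$lam)
  Wtot <- W[length(W)]
  if (Wtot <= 1e-12) stop("degenerate curvature measure")
  # all inversions return the vertex-grid parameter t: within an edge both s
  # and W are linear in t, so piecewise-linear inversion is exact for the
  # polyline

  if (params$n == 0L) {
    u <- (seq_len(N) - 1) / N * Wtot
    tt <- invert_monotone(tgrid, W, u)
    return(new_contour(eval_contour(c, tt), template = c))
  }

  ref <- reference_point(c)
  kp <- clock_keypoints(c, ref, params$n)          # arc-length fractions
  tcut <- invert_monotone(tgrid, s, kp * L)        # sector bounds, t-parameter
  tcut <- c(tcut, 1)
  Wcut <- stats::approx(tgrid, W, xout = tcut, ties = "ordered")$y
  counts <- sector_counts(N, params$n)
  tt <- numeric(N)
  pos <- 1L
  for (k in seq_len(params$n)) {
    m <- counts[k]
    w0 <- Wcut[k]; w1 <- Wcut[k + 1L]
    if (w1 - w0 <= 1e-15 * Wtot) {
      # degenerate sector mass (fully flat sector at lam = 0): spread uniformly
      tt[pos:(pos + m - 1L)] <- tcut[k] + (seq_len(m) - 1) / m * (tcut[k + 1L] - tcut[k])
    } else {
      u <- w0 + (seq_len(m) - 1) / m * (w1 - w0)
      tt[pos:(pos + m - 1L)] <- invert_monotone(tgrid, W, u)
    }
    # the keypoint itself is the first vertex of the sector
    tt[pos] <- tcut[k]
    pos <- pos + m
  }
  new_contour(eval_contour(c, tt), template = c)
}

#' Project a contour onto a canonical section
#'
#' The idempotent projection `p = s o pi` onto the range of the section:
#' normalizes over the finite-dimensional shape-preserving groups
#' ([normalize_contour]) and then resamples under the curvature-weighted
#' clock section ([canonical_resample]). The output depends only on the
#' oriented shape of the input: reparameterizations, rigid motions,
#' scalings, direction flips and cyclic rolls of the input map to the same
#' canonical representative up to resampling error.
#'
#' @param c A [contour].
#' @param params A [section_params].
#' @param cfg A [norm_config].
#' @return A canonical [contour] with `params$points` vertices; the section
#'   parameters are attached as attribute `"section"`.
#' @examples
#' circ <- contour(cos(2 * pi * (0:199) / 200), sin(2 * pi * (0:199) / 200))
#' p <- project_contour(circ, section_params(lam = 1, n = 4, points = 200))
#' @export
project_contour <- function(c, params = section_params(), cfg = norm_config()) {
  out <- canonical_resample(normalize_contour(c, cfg), params)
  attr(out, "section") <- params
  out
}
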