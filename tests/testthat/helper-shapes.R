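# fixture builders shared across the suite (all generated in code)

# uniform circle polygon, start at the top, counterclockwise
mkcircle <- function(r = 1, n = 200, center = c(0, 0), cw = FALSE, start_top = TRUE) {
  th <- (if (start_top) pi / 2 else 0) + 2 * pi * (0:(n - 1)) / n
  if (cw) th <- rev(th)
  contour(center[1] + r * cos(th), center[2] + r * sin(th))
}

unit_square <- function(cw = FALSE) {
  v <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  if (cw) v <- v[c(1, 4, 3, 2), ]
  contour(v)
}

# L-shaped hexagon with known centroids
l_hexagon <- function() {
  contour(rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2)))
}

# axis-aligned ellipse polygon (uniform in angle), counterclockwise
mkellipse <- function(a = 2, b = 1, n = 400, start_top = FALSE) {
  th <- (if (start_top) pi / 2 else 0) + 2 * pi * (0:(n - 1)) / n
  contour(a * cos(th), b * sin(th))
}

# two semicircles of radius r joined by straight edges of length l, CCW;
# returns the contour plus the index ranges of the flat pieces
mkstadium <- function(r = 0.5, l = 2, n_arc = 200, n_edge = 150) {
  a1 <- seq(-pi / 2, pi / 2, length.out = n_arc)[-n_arc]
  right <- cbind(l / 2 + r * cos(a1), r * sin(a1))
  top <- cbind(seq(l / 2, -l / 2, length.out = n_edge)[-n_edge], rep(r, n_edge - 1))
  a2 <- seq(pi / 2, 3 * pi / 2, length.out = n_arc)[-n_arc]
  left <- cbind(-l / 2 + r * cos(a2), r * sin(a2))
  bot <- cbind(seq(-l / 2, l / 2, length.out = n_edge)[-n_edge], rep(-r, n_edge - 1))
  st <- contour(rbind(right, top, left, bot))
  n1 <- n_arc - 1L; n2 <- n_edge - 1L
  attr(st, "top_idx") <- (n1 + 1L):(n1 + n2)
  attr(st, "bot_idx") <- (2L * n1 + n2 + 1L):(2L * n1 + 2L * n2)
  st
}

# relative L2 discrepancy between two equal-length vertex arrays
rel_l2 <- function(a, b) {
  va <- unclass(a)[, , drop = FALSE]
  vb <- unclass(b)[, , drop = FALSE]
  d <- sqrt(mean(rowSums((va - vb)^2)))
  s <- (sqrt(mean(rowSums(va^2))) + sqrt(mean(rowSums(vb^2)))) / 2
  d / s
}

# O(N^2) polygon simplicity check by pairwise proper segment intersection
is_simple_polygon <- function(c) {
  v <- unclass(c)[, , drop = FALSE]
  n <- nrow(v)
  a <- v
  b <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  cross <- function(o, p, q) (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next  # adjacent edges share a vertex
      d1 <- cross(a[i, ], b[i, ], a[j, ])
      d2 <- cross(a[i, ], b[i, ], b[j, ])
      d3 <- cross(a[j, ], b[j, ], a[i, ])
      d4 <- cross(a[j, ], b[j, ], b[i, ])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(FALSE)
    }
  }
  TRUE
}
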