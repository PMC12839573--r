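#' Specification of a synthetic leaf-like shape class
#'
#' Shapes are smooth radial-Fourier outlines
#' `r(theta) = 1 + sum_k a_k cos(k theta + phi_k)` around the origin,
#' optionally decorated with a peduncle: a narrow Gaussian radial protrusion
#' `l * exp(-((theta - theta0) / w)^2 / 2)` whose area contribution is tiny
#' (well under 2 percent for the defaults), so area-based quantities are
#' peduncle-insensitive while length-based ones are not — the tension the
#' normalization study revolves around. `sum |a_k| < 1` keeps the radius
#' positive, so every realization is star-shaped and simple by construction.
#'
#' @param amplitudes Numeric vector `a_k` of harmonic amplitudes (index =
#'   harmonic number `k`), `sum(|a_k|)` must stay below 0.95.
#' @param phases Phases `phi_k` (radians), recycled to the amplitude length.
#' @param peduncle `NULL` or `list(length =, width =, angle =)`: radial
#'   extent, angular standard deviation (radians) and attachment angle.
#' @param jitter Per-sample standard deviation of the amplitude noise.
#' @param m Number of samples the class contributes to a dataset.
#' @param name Class name.
#' @return An object of class `shape_spec`.
#' @examples
#' sp <- shape_spec(amplitudes = c(0.35, 0, 0.1), name = "ovate")
#' plot(make_shape(sp, seed = 1))
#' @export
shape_spec <- function(amplitudes = numeric(0), phases = 0, peduncle = NULL,
                       jitter = 0.02, m = 10L, name = "shape") {
  if (sum(abs(amplitudes)) >= 0.95)
    stop("sum(|amplitudes|) must be < 0.95 to guarantee a positive radius")
  phases <- rep_len(phases, length(amplitudes))
  if (!is.null(peduncle)) {
    stopifnot(is.list(peduncle),
              all(c("length", "width", "angle") %in% names(peduncle)),
              peduncle$length > 0, peduncle$width > 0)
  }
  structure(list(amplitudes = amplitudes, phases = phases, peduncle = peduncle,
                 jitter = jitter, m = as.integer(m), name = name),
            class = "shape_spec")
}

# radius function of a realized spec (base harmonics + peduncle bump)
spec_radius <- function(theta, amplitudes, phases, peduncle) {
  r <- rep(1, length(theta))
  for (k in seq_along(amplitudes)) {
    if (amplitudes[k] != 0)
      r <- r + amplitudes[k] * cos(k * theta + phases[k])
  }
  if (!is.null(peduncle)) {
    d <- wrap_angle(theta - peduncle$angle)
    r <- r + peduncle$length * exp(-0.5 * (d / peduncle$width)^2)
  }
  r
}

#' Generate one synthetic contour
#'
#' Deterministic per `(spec, seed)`: amplitudes and phases receive seeded
#' Gaussian jitter, then the outline is sampled counterclockwise starting at
#' the top (`theta = pi/2`), first densely in angle (four-fold oversampling)
#' and then resampled to `n` constant-speed vertices — emulating the roughly
#' arc-uniform spacing of a pixel boundary tracer and keeping narrow
#' features such as peduncles resolved. Jittered amplitudes are rescaled if
#' they would push `sum |a_k|` past 0.95, so the radius stays positive and
#' the contour simple.
#'
#' @param spec A [shape_spec].
#' @param seed Integer seed.
#' @param n Number of vertices (default 1200).
#' @return A counterclockwise [contour].
#' @export
make_shape <- function(spec, seed = 1L, n = 1200L) {
  stopifnot(inherits(spec, "shape_spec"))
  n <- as.integer(n)
  amp <- spec$amplitudes
  ph <- spec$phases
  if (length(amp) > 0 && spec$jitter > 0) {
    jit <- with_private_seed(derive_seed(seed, 1L), {
      list(a = stats::rnorm(length(amp), 0, spec$jitter),
           p = stats::rnorm(length(amp), 0, spec$jitter))
    })
    amp <- amp + jit$a
    ph <- ph + jit$p
    tot <- sum(abs(amp))
    if (tot >= 0.95) amp <- amp * (0.9 / tot)
  }
  n_dense <- 4L * n
  theta <- pi / 2 + 2 * pi * (seq_len(n_dense) - 1) / n_dense
  r <- spec_radius(theta, amp, ph, spec$peduncle)
  dense <- contour(r * cos(theta), r * sin(theta), name = spec$name)
  out <- apply_param_map(dense, arclength_map(dense), n_out = n)
  attr(out, "realized") <- list(amplitudes = amp, phases = ph,
                                peduncle = spec$peduncle)
  out
}

#' Thin crescent contour (exterior-centroid fixture)
#'
#' An annular-arc polygon: outer radius arc swept counterclockwise over
#' `span` radians, closed by the inner arc. For a wide, thin crescent the
#' area centroid falls in the hole, outside the band — the case that forces
#' [reference_point] onto its interior fallback.
#'
#' @param r_outer,r_inner Outer and inner radii.
#' @param span Angular extent in radians (default 5.2, about 300 degrees).
#' @param n Total vertex count.
#' @return A counterclockwise [contour].
#' @export
make_crescent <- function(r_outer = 1, r_inner = 0.82, span = 5.2, n = 600L) {
  stopifnot(r_inner > 0, r_outer > r_inner, span > 0, span < 2 * pi)
  half <- n %/% 2L
  a0 <- pi / 2 - span / 2
  ang <- seq(a0, a0 + span, length.out = half)
  outer <- cbind(r_outer * cos(ang), r_outer * sin(ang))
  inner <- cbind(r_inner * cos(rev(ang)), r_inner * sin(rev(ang)))
  contour(rbind(outer, inner), name = "crescent")
}

#' Seeded random monotone reparameterization
#'
#' A smooth strictly increasing map of `[0, 1]` onto itself fixing the
#' endpoints: `Phi(t) = t + sum_k b_k sin(2 pi k t + phi_k) / (2 pi k)` with
#' the low-frequency coefficients `b_k` drawn from the seed and scaled so
#' that `Phi' >= 1 - strength > 0`.
#'
#' @param m Number of grid points for the tabulated map.
#' @param seed Integer seed.
#' @param strength Total relative slope modulation in `(0, 1)` (default 0.5).
#' @return A strictly increasing [param_map].
#' @export
random_reparam_map <- function(m = 1001L, seed = 1L, strength = 0.5) {
  stopifnot(strength > 0, strength < 1)
  coef <- with_private_seed(derive_seed(seed, 2L), {
    list(b = stats::runif(3L, -1, 1), p = stats::runif(3L, 0, 2 * pi))
  })
  b <- coef$b * strength / sum(abs(coef$b))
  tt <- seq(0, 1, length.out = m)
  vals <- tt
  for (k in 1:3) vals <- vals + b[k] * (sin(2 * pi * k * tt + coef$p[k]) -
                                          sin(coef$p[k])) / (2 * pi * k)
  vals[m] <- 1
  param_map(vals)
}

#' Apply seeded nuisance transforms to a contour
#'
#' Draws, from named substreams of one seed, a uniform rotation, a
#' translation, a log-uniform scale in `[1/2, 2]`, an optional direction
#' flip (probability 1/2), a cyclic roll of the starting vertex, and a
#' random monotone reparameterization, and applies them. This is the group
#' of nuisances that [project_contour] is designed to quotient out;
#' `project(nuisance(c))` agrees with `project(c)` up to resampling error.
#' Using substreams means adding a transform later never perturbs the draws
#' of existing ones.
#'
#' @param c A [contour].
#' @param seed Integer seed.
#' @param flip,roll,reparam Logicals enabling the non-similarity nuisances.
#' @return A transformed [contour] with the same vertex count.
#' @export
nuisance_transform <- function(c, seed = 1L, flip = TRUE, roll = TRUE,
                               reparam = TRUE) {
  c <- as_contour(c)
  n <- nrow(c)
  draws <- with_private_seed(derive_seed(seed, 3L), {
    list(theta = stats::runif(1L, 0, 2 * pi),
         shift = stats::runif(2L, -2, 2),
         scale = exp(stats::runif(1L, log(0.5), log(2))),
         do_flip = stats::runif(1L) < 0.5,
         roll_to = sample.int(n, 1L))
  })
  if (roll && draws$roll_to > 1L) c <- roll_contour(c, draws$roll_to)
  if (flip && draws$do_flip) {
    v <- cxy(c)
    c <- new_contour(v[c(1L, n:2L), , drop = FALSE], template = c)
  }
  if (reparam) {
    c <- apply_param_map(c, random_reparam_map(n + 1L, seed = seed), n_out = n)
  }
  v <- rotate_about(cxy(c), draws$theta) * draws$scale
  v <- sweep(v, 2L, draws$shift, FUN = "+")
  new_contour(v, template = c)
}

#' Generate a labeled synthetic dataset
#'
#' Concatenates `m` seeded samples per class spec, each optionally hit by
#' [nuisance_transform] with its own derived seed. Deterministic for a given
#' `(specs, seed, n)`.
#'
#' @param specs List of [shape_spec] objects (at least 2 for a labeled set).
#' @param seed Integer seed.
#' @param n Vertices per contour.
#' @param nuisance Apply per-sample nuisance transforms (default `TRUE`).
#' @return A [shape_set].
#' @export
make_dataset <- function(specs, seed = 1L, n = 1200L, nuisance = TRUE) {
  if (inherits(specs, "shape_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 2L)
  contours <- list()
  labels <- integer(0)
  sample_id <- 0L
  for (cl in seq_along(specs)) {
    for (j in seq_len(specs[[cl]]$m)) {
      sample_id <- sample_id + 1L
      sh <- make_shape(specs[[cl]], seed = derive_seed(seed, 100L + sample_id), n = n)
      if (nuisance)
        sh <- nuisance_transform(sh, seed = derive_seed(seed, 10000L + sample_id))
      contours[[sample_id]] <- sh
      labels[sample_id] <- cl
    }
  }
  shape_set(contours, labels,
            class_names = vapply(specs, `[[`, character(1L), "name"))
}

#' Stratified train/test split
#'
#' Disjoint stratified subsets covering all samples: a seeded draw of
#' `round(train_frac * m_k)` training samples per class, the rest to test.
#'
#' @param ds A [shape_set].
#' @param train_frac Training fraction per class (default 2/3).
#' @param seed Integer seed.
#' @return List with [shape_set] fields `train`, `test` and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
split_shape_set <- function(ds, train_frac = 2 / 3, seed = 1L) {
  stopifnot(inherits(ds, "shape_set"))
  train_idx <- with_private_seed(derive_seed(seed, 4L), {
    unlist(lapply(seq_len(max(ds$labels)), function(cl) {
      idx <- which(ds$labels == cl)
      sort(sample(idx, max(1L, round(train_frac * length(idx)))))
    }), use.names = FALSE)
  })
  test_idx <- setdiff(seq_along(ds$contours), train_idx)
  list(train = subset_shape_set(ds, train_idx),
       test = subset_shape_set(ds, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Default five-class synthetic leaf gallery
#'
#' Five contrasting outline families: an ovate blade, a three-lobed and a
#' five-lobed outline, an ovate blade with a peduncle, and an elongated
#' blade. The families deliberately avoid first-harmonic (`k = 1`) content —
#' to first order that mode is a centroid shift, not a shape change — and
#' each has one landmark (the apex, or the peduncle end for the peduncle
#' class) distinctly farthest from the area centroid, with a margin of at
#' least 0.15 base-radius units over the runner-up, as real leaf outlines
#' do. This keeps the farthest-point start rule stable under the default
#' amplitude jitter and under resampling.
#'
#' @param m Samples per class.
#' @param jitter Per-sample amplitude jitter.
#' @return List of five [shape_spec] objects.
#' @export
leaf_gallery <- function(m = 10L, jitter = 0.02) {
  list(
    # vertical elongation + apex sharpening: tip r = 1.28, base 1.08, sides 0.82
    shape_spec(amplitudes = c(0, 0.18, 0.10), phases = c(0, pi, pi / 2),
               m = m, jitter = jitter, name = "ovate"),
    # three lobes, top lobe reinforced by the elongation: 1.32 vs 1.17
    shape_spec(amplitudes = c(0, 0.10, 0.22), phases = c(0, pi, pi / 2),
               m = m, jitter = jitter, name = "three-lobed"),
    # five lobes, top lobe reinforced: 1.28 vs 1.10
    shape_spec(amplitudes = c(0, 0.10, 0, 0, 0.18),
               phases = c(0, pi, 0, 0, -pi / 2),
               m = m, jitter = jitter, name = "five-lobed"),
    # the peduncle end (r ~ 1.42) is the farthest landmark here, as for a
    # long-petioled leaf; it is sharp, so the start rule is very stable
    shape_spec(amplitudes = c(0, 0.15, 0.08), phases = c(0, pi, pi / 2),
               peduncle = list(length = 0.35, width = 0.04, angle = -pi / 2),
               m = m, jitter = jitter, name = "ovate-peduncle"),
    # strong elongation: tip 1.38, base 1.18, sides 0.72
    shape_spec(amplitudes = c(0, 0.28, 0.10), phases = c(0, pi, pi / 2),
               m = m, jitter = jitter, name = "elongated")
  )
}

#' Fraction of canonical sample points lying on the peduncle
#'
#' Diagnostic for the clock construction: counts the output vertices of a
#' canonical representative that fall inside the peduncle wedge, as a
#' fraction of all vertices. The wedge is located geometrically in the
#' canonical frame: the peduncle end of a [leaf_gallery]-style shape is the
#' vertex farthest from the interior reference point; membership is then
#' "within 3 angular standard deviations of that direction and radially
#' beyond the base outline" (base radius estimated from the vertices just
#' outside the wedge).
#'
#' @param proj A canonical [contour] produced by [project_contour] from a
#'   peduncled [make_shape] output.
#' @param width Angular standard deviation of the peduncle (the generating
#'   `peduncle$width`).
#' @return Fraction in `[0, 1]`.
#' @export
peduncle_fraction <- function(proj, width) {
  ref <- reference_point(proj)$point
  v <- cxy(proj)
  dx <- v[, 1L] - ref[1L]; dy <- v[, 2L] - ref[2L]
  theta <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  theta0 <- theta[which.max(r)]
  off <- abs(wrap_angle(theta - theta0))
  in_wedge <- off < 3 * width
  shoulder <- off >= 3 * width & off < 12 * width
  base_r <- max(r[shoulder])
  mean(in_wedge & r > 1.02 * base_r)
}
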