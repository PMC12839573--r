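test_that("arclength map is the normalized cumulative speed", {
  circ <- mkcircle(1, 500)
  m <- arclength_map(circ)
  expect_lt(max(abs(m$values - m$grid)), 1e-9)       # uniform sampling: identity
  # circle sampled at angles 2 pi t^2: psi(t) recovers ~ t^2
  n <- 800
  tt <- (0:(n - 1)) / n
  warped <- contour(cos(2 * pi * tt^2), sin(2 * pi * tt^2))
  m2 <- arclength_map(warped)
  expect_lt(max(abs(m2$values - m2$grid^2)), 1e-3)
  # constant-speed postcondition: equal edges after resampling
  sh <- make_shape(leaf_gallery(m = 1)[[2]], seed = 6, n = 1000)
  out <- apply_param_map(sh, arclength_map(sh), 1000)
  len <- sqrt(rowSums((unclass(out)[c(2:1000, 1), ] - unclass(out)[, ])^2))
  expect_lt(diff(range(len)) / mean(len), 1e-6)
})

test_that("curvature-weighted maps interpolate between curvature and arc length", {
  circ <- mkcircle(1, 400)
  for (lam in c(0, 0.5, 3, Inf)) {
    m <- curvature_weighted_map(circ, lam)
    expect_lt(max(abs(m$values - m$grid)), 1e-6)     # constant kappa and speed
  }
  sh <- make_shape(leaf_gallery(m = 1)[[1]], seed = 12, n = 800)
  psi <- arclength_map(sh)$values
  expect_lt(max(abs(curvature_weighted_map(sh, 1e9)$values - psi)), 1e-6)
  # sup gap is non-increasing in lambda and vanishes in the limit
  sup <- vapply(c(1, 10, 100, 1e4, 1e6),
                function(l) max(abs(curvature_weighted_map(sh, l)$values - psi)),
                numeric(1))
  expect_true(all(diff(sup) <= 1e-15))
  expect_lt(sup[5], 1e-4)
  expect_error(curvature_weighted_map(sh, -1), ">= 0")
})

test_that("lambda = 0 plateaus exactly over the flat pieces of a stadium", {
  st <- mkstadium()
  m0 <- curvature_weighted_map(st, 0)
  v <- m0$values
  # independent brute-force cumulative |kappa| ds oracle (explicit loops)
  vv <- unclass(st)[, ]
  n <- nrow(vv)
  turn <- numeric(n); len <- numeric(n)
  for (i in seq_len(n)) {
    ip <- if (i == n) 1L else i + 1L
    im <- if (i == 1L) n else i - 1L
    e1 <- vv[i, ] - vv[im, ]; e2 <- vv[ip, ] - vv[i, ]
    a <- atan2(e1[1] * e2[2] - e1[2] * e2[1], sum(e1 * e2))
    turn[i] <- abs(a)
    len[i] <- sqrt(sum(e2^2))
  }
  kap <- turn / ((c(len[n], len[-n]) + len) / 2)
  kn <- c(kap, kap[1])
  oracle <- c(0, cumsum(len * (kn[-length(kn)] + kn[-1]) / 2))
  oracle <- oracle / oracle[length(oracle)]
  expect_equal(v, oracle, tolerance = 1e-12)
  # flat interiors are exact plateaus
  top <- attr(st, "top_idx"); bot <- attr(st, "bot_idx")
  expect_equal(diff(range(v[top[-1]])), 0)
  expect_equal(diff(range(v[bot[-1]])), 0)
  # each semicircle carries half the total turning: plateau heights 0.5 apart
  expect_equal(v[bot[2]] - v[top[2]], 0.5, tolerance = 1e-9)
})

test_that("reference point is the centroid or a deterministic interior fallback", {
  conv <- mkcircle(2, 100, center = c(1, 1))
  rp <- reference_point(conv)
  expect_identical(rp$provenance, "area_centroid")
  expect_equal(rp$point, c(1, 1), tolerance = 1e-9)
  cr <- make_crescent()
  expect_false(point_in_polygon(area_centroid(cr), cr))
  rp2 <- reference_point(cr)
  expect_identical(rp2$provenance, "fallback_triangle")
  expect_true(point_in_polygon(rp2$point, cr))
  expect_identical(reference_point(cr)$point, rp2$point)   # deterministic
})

test_that("clock keypoints subtend equal winding angles at the reference point", {
  circ <- mkcircle(1, 1000)
  kp <- clock_keypoints(circ, c(0, 0), 4)
  expect_equal(kp, c(0, 0.25, 0.5, 0.75), tolerance = 1e-6)
  # star-shaped gallery outlines: consecutive angular gaps are all 2 pi / n
  cfg <- norm_config()
  for (cl in c(1, 2, 5)) {
    sh <- normalize_contour(make_shape(leaf_gallery(m = 1)[[cl]], seed = cl, n = 2000),
                            cfg)
    ref <- reference_point(sh)
    n <- 12
    kp <- clock_keypoints(sh, ref, n)
    expect_true(all(diff(kp) > 0))
    # keypoints are arc-length fractions; convert to the vertex-grid parameter
    s <- canonshape:::cum_arclength(sh)
    nv <- nrow(sh)
    tt <- canonshape:::invert_monotone((0:nv) / nv, s, kp * s[nv + 1])
    pts <- canonshape:::eval_contour(sh, tt)
    ang <- atan2(pts[, 2] - ref$point[2], pts[, 1] - ref$point[1])
    gaps <- diff(c(ang, ang[1]))
    gaps <- (gaps + 2 * pi) %% (2 * pi)
    expect_lt(max(abs(gaps - 2 * pi / n)), 1e-4)
  }
  # 2:1 ellipse against a dense angle-scan oracle
  ell <- mkellipse(2, 1, 500, start_top = TRUE)
  kp_e <- clock_keypoints(ell, c(0, 0), 4)
  fine <- seq(0, 1, length.out = 200001)
  dense <- canonshape:::eval_contour(ell, fine)
  ang_d <- atan2(dense[, 2], dense[, 1]) - pi / 2
  w_d <- c(0, cumsum(atan2(sin(diff(ang_d)), cos(diff(ang_d)))))
  s_d <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  s_d <- s_d / max(s_d)
  oracle <- vapply(2 * pi * (0:3) / 4, function(tg) {
    i <- which(w_d >= tg)[1]
    s_d[i]
  }, numeric(1))
  expect_equal(kp_e, oracle, tolerance = 1e-4)
  expect_error(clock_keypoints(mkcircle(1, 100, cw = TRUE), c(0, 0), 4),
               "invalid winding")
})

test_that("canonical resampling maps circles to uniform polygons for every section", {
  circ <- mkcircle(1, 800)
  target <- unclass(mkcircle(1, 200))[, ]
  for (lam in c(0, 0.5, 2, 1000, Inf)) {
    for (n in c(0, 4, 10, 20)) {
      out <- canonical_resample(circ, section_params(lam, n, points = 200))
      expect_lt(max(abs(unclass(out)[, ] - target)), 1e-4)
    }
  }
  # constant-speed section gives equal edge lengths on any shape
  sh <- make_shape(leaf_gallery(m = 1)[[3]], seed = 7, n = 1000)
  out <- canonical_resample(normalize_contour(sh), section_params(points = 500))
  len <- sqrt(rowSums((unclass(out)[c(2:500, 1), ] - unclass(out)[, ])^2))
  expect_lt(diff(range(len)) / mean(len), 1e-3)
  expect_error(canonical_resample(sh, section_params(Inf, 0, points = 2)),
               "points")
})

test_that("more clock subdivisions drain sample points from the peduncle", {
  cfg <- norm_config()
  sh <- make_shape(leaf_gallery(m = 1)[[4]], seed = 21)
  fr <- vapply(c(12, 24, 36), function(n) {
    peduncle_fraction(project_contour(sh, section_params(Inf, n, 1000), cfg),
                      width = 0.04)
  }, numeric(1))
  expect_true(all(diff(fr) < 0))
  fr0 <- peduncle_fraction(project_contour(sh, section_params(Inf, 0, 1000), cfg),
                           width = 0.04)
  expect_gt(fr0, fr[1])     # constant speed loads the peduncle most
})

test_that("projection is idempotent and invariant over the nuisance group", {
  cfg <- norm_config()
  specs <- leaf_gallery(m = 1)
  p <- section_params(lam = Inf, n = 12, points = 1000)
  for (seed in 1:10) {
    sh <- make_shape(specs[[(seed %% 5) + 1]], seed = 60 + seed)
    pr <- project_contour(sh, p, cfg)
    expect_lt(rel_l2(pr, project_contour(pr, p, cfg)), 1e-2)
    tr <- nuisance_transform(sh, seed = seed)
    expect_lt(rel_l2(pr, project_contour(tr, p, cfg)), 1e-2)
  }
  # an already-projected circle re-projects to the identical vertex array
  circ <- mkcircle(1, 400)
  pc <- project_contour(circ, section_params(points = 400), cfg)
  pc2 <- project_contour(pc, section_params(points = 400), cfg)
  expect_lt(max(abs(unclass(pc2)[, ] - unclass(pc)[, ])), 1e-9)
})

test_that("section parameters validate their domain", {
  expect_error(section_params(lam = -0.1), ">= 0")
  expect_error(section_params(n = 1), "n must be 0")
  expect_error(section_params(n = 12, points = 10), "points")
  p <- section_params(lam = 0, n = 0, points = 100)
  expect_identical(p$n, 0L)
})
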