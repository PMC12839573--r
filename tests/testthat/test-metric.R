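test_that("section distance is the discrete L2 norm and a true metric", {
  a <- mkcircle(1, 300)
  expect_identical(section_distance(a, a), 0)
  # concentric circles with a common start: distance is the radius difference
  expect_equal(section_distance(mkcircle(1, 300), mkcircle(2.4, 300)), 1.4,
               tolerance = 1e-9)
  expect_error(section_distance(mkcircle(1, 100), mkcircle(1, 101)),
               "same number of vertices")
  # metric axioms on seeded random canonical triples
  cfg <- norm_config()
  p <- section_params(points = 300)
  specs <- leaf_gallery(m = 1)
  for (seed in 1:12) {
    set.seed(seed)
    tri <- lapply(sample(5, 3, replace = TRUE), function(cl) {
      project_contour(make_shape(specs[[cl]], seed = seed * 7 + cl, n = 500), p, cfg)
    })
    dab <- section_distance(tri[[1]], tri[[2]])
    dba <- section_distance(tri[[2]], tri[[1]])
    dbc <- section_distance(tri[[2]], tri[[3]])
    dac <- section_distance(tri[[1]], tri[[3]])
    expect_identical(dab, dba)                       # symmetry, exact
    expect_lte(dac, dab + dbc + 1e-12)               # triangle inequality
    expect_gte(dab, 0)
  }
  # non-degeneracy: zero iff identical vertex arrays
  b <- mkcircle(1, 300)
  v <- unclass(b)[, ]; v[5, 1] <- v[5, 1] + 1e-9
  expect_gt(section_distance(a, contour(v)), 0)
})

test_that("distance matrix is exact on concentric circles and symmetric", {
  ds <- shape_set(list(mkcircle(1, 100), mkcircle(2, 100), mkcircle(4, 100)),
                  c(1, 2, 3))
  D <- distance_matrix(ds)
  expect_equal(D, rbind(c(0, 1, 3), c(1, 0, 2), c(3, 2, 0)), tolerance = 1e-12)
  expect_identical(D, t(D))
  single <- shape_set(list(mkcircle(1, 50)), 1)
  expect_identical(distance_matrix(single), matrix(0, 1, 1))
})

test_that("class centroids are vertex-wise means", {
  ds <- shape_set(list(mkcircle(1, 200), mkcircle(1.1, 200), mkcircle(3, 200)),
                  c(1, 1, 2))
  cen <- class_centroids(ds)
  expect_equal(unclass(cen[[1]])[, ], unclass(mkcircle(1.05, 200))[, ],
               tolerance = 1e-12)
  expect_equal(unclass(cen[[2]])[, ], unclass(mkcircle(3, 200))[, ])   # singleton
  same <- shape_set(list(mkcircle(2, 100), mkcircle(2, 100)), c(1, 1))
  expect_equal(unclass(class_centroids(same)[[1]])[, ],
               unclass(mkcircle(2, 100))[, ])
})

test_that("Dunn and Davies-Bouldin match the hand-derived circle example", {
  ds <- shape_set(list(mkcircle(1, 200), mkcircle(1.1, 200),
                       mkcircle(2, 200), mkcircle(2.2, 200)), c(1, 1, 2, 2))
  # inter = |2.1 - 1.05| = 1.05, max intra = 0.2, Dunn = 5.25
  expect_equal(dunn_index(ds), 5.25, tolerance = 1e-12)
  # delta_bar = (0.05, 0.1), DB = 0.15 / 1.05 = 1/7
  expect_equal(davies_bouldin_index(ds), 1 / 7, tolerance = 1e-12)
  ep <- extreme_pairs(ds)
  expect_identical(ep$intra_pair, c(3L, 4L))
  expect_equal(ep$intra_distance, 0.2, tolerance = 1e-12)
  expect_identical(ep$inter_pair, c(2L, 3L))
  expect_equal(ep$inter_distance, 0.9, tolerance = 1e-12)
  # scale invariance of both ratios
  ds2 <- shape_set(lapply(ds$contours, function(c) contour(3 * unclass(c)[, ])),
                   ds$labels)
  expect_equal(dunn_index(ds2), dunn_index(ds), tolerance = 1e-12)
  expect_equal(davies_bouldin_index(ds2), davies_bouldin_index(ds),
               tolerance = 1e-12)
  # identical class centroids: Dunn 0, DB undefined
  deg <- shape_set(list(mkcircle(1, 50), mkcircle(3, 50),
                        mkcircle(1, 50), mkcircle(3, 50)), c(1, 1, 2, 2))
  expect_equal(dunn_index(deg), 0)
  expect_error(davies_bouldin_index(deg), "coincident")
  # all-singleton classes: Dunn undefined rather than infinite
  sing <- shape_set(list(mkcircle(1, 50), mkcircle(2, 50)), c(1, 2))
  expect_error(dunn_index(sing), "singleton")
  expect_equal(davies_bouldin_index(sing), 0)     # both spreads are zero
})

test_that("indices agree with an independent brute-force implementation", {
  brute_dunn <- function(ds) {
    k <- max(ds$labels)
    cen <- list()
    for (cl in 1:k) {
      idx <- which(ds$labels == cl)
      acc <- 0
      for (i in idx) acc <- acc + unclass(ds$contours[[i]])[, ]
      cen[[cl]] <- acc / length(idx)
    }
    d2 <- function(x, y) sqrt(mean(rowSums((x - y)^2)))
    inter <- Inf
    for (k1 in 1:(k - 1)) for (k2 in (k1 + 1):k)
      inter <- min(inter, d2(cen[[k1]], cen[[k2]]))
    intra <- 0
    for (cl in 1:k) {
      idx <- which(ds$labels == cl)
      for (i in idx) for (j in idx)
        intra <- max(intra, d2(unclass(ds$contours[[i]])[, ],
                               unclass(ds$contours[[j]])[, ]))
    }
    inter / intra
  }
  brute_db <- function(ds) {
    k <- max(ds$labels)
    cen <- list(); delta <- numeric(k)
    d2 <- function(x, y) sqrt(mean(rowSums((x - y)^2)))
    for (cl in 1:k) {
      idx <- which(ds$labels == cl)
      acc <- 0
      for (i in idx) acc <- acc + unclass(ds$contours[[i]])[, ]
      cen[[cl]] <- acc / length(idx)
      delta[cl] <- mean(vapply(idx, function(i)
        d2(unclass(ds$contours[[i]])[, ], cen[[cl]]), numeric(1)))
    }
    mean(vapply(1:k, function(i) {
      max(vapply(setdiff(1:k, i), function(j)
        (delta[i] + delta[j]) / d2(cen[[i]], cen[[j]]), numeric(1)))
    }, numeric(1)))
  }
  cfg <- norm_config()
  p <- section_params(points = 200)
  for (seed in 1:10) {
    ds <- project_set(make_dataset(leaf_gallery(m = 3), seed = seed, n = 400),
                      p, cfg)
    expect_equal(dunn_index(ds), brute_dunn(ds), tolerance = 1e-12)
    expect_equal(davies_bouldin_index(ds), brute_db(ds), tolerance = 1e-12)
  }
})

test_that("label shuffling degrades the Dunn index of a separated set", {
  cfg <- norm_config()
  ds <- project_set(make_dataset(leaf_gallery(m = 4), seed = 3, n = 400),
                    section_params(points = 200), cfg)
  d_true <- dunn_index(ds)
  set.seed(11)
  shuffled <- ds
  shuffled$labels <- sample(ds$labels)
  expect_lt(dunn_index(shuffled), d_true)
})

test_that("interpolation walks the straight segment between representatives", {
  a <- mkcircle(1, 150); b <- mkcircle(3, 150)
  path <- interpolate_contours(a, b, 5)
  expect_identical(unclass(path[[1]])[, ], unclass(a)[, ])
  expect_identical(unclass(path[[5]])[, ], unclass(b)[, ])
  expect_equal(section_distance(path[[3]], mkcircle(2, 150)), 0, tolerance = 1e-12)
  dab <- section_distance(a, b)
  for (j in 1:5) {
    expect_equal(section_distance(a, path[[j]]), (j - 1) / 4 * dab,
                 tolerance = 1e-12)
  }
  expect_error(interpolate_contours(a, b, 1), "steps")
  expect_error(interpolate_contours(a, mkcircle(1, 100), 3), "same number")
})

test_that("the validity report bundles all diagnostics consistently", {
  ds <- shape_set(list(mkcircle(1, 100), mkcircle(1.1, 100),
                       mkcircle(2, 100), mkcircle(2.2, 100)), c(1, 1, 2, 2),
                  class_names = c("small", "large"))
  rep <- validity_report(ds)
  expect_s3_class(rep, "validity_report")
  expect_equal(rep$dunn, 5.25, tolerance = 1e-12)
  expect_equal(rep$davies_bouldin, 1 / 7, tolerance = 1e-12)
  expect_identical(dim(rep$D_inter), c(2L, 2L))
  expect_identical(rep$D_inter, t(rep$D_inter))
  expect_equal(diag(rep$D_inter), c(0, 0))
  expect_equal(rep$delta_bar, c(0.05, 0.1), tolerance = 1e-12)
  expect_output(print(rep), "Dunn")
})
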