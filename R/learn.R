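# run expr with a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# derived sub-seed for a named stream: deterministic, stays below 2^31
derive_seed <- function(seed, id) {
  (as.numeric(seed) * 31 + id * 1009) %% 2147483647
}

#' Learn a canonical section by cluster-validity grid search
#'
#' Fits the section parameters `(lambda, n)` of the curvature-weighted clock
#' family to a labeled set of contours: for every grid cell the set is
#' projected under `s_{lambda, n}`, the chosen cluster-validity index (Dunn,
#' maximized, or Davies-Bouldin, minimized) is computed on `folds` seeded
#' stratified training subsamples, and the fold-averaged values are
#' tabulated. The optimum defines the learned shape metric. The whole
#' procedure is a pure function of `(ds, grids, index, folds, train_frac,
#' seed, cfg, points)`: the same seed reproduces the grid bit-for-bit.
#'
#' @param ds A [shape_set] of raw (unprojected) contours.
#' @param lam_grid Curvature weights to scan (may include `0` and `Inf`).
#' @param n_grid Clock subdivision counts to scan (may include `0`).
#' @param index `"dunn"` (maximized) or `"davies_bouldin"` (minimized).
#' @param folds Number of repeated stratified subsamples (`>= 1`).
#' @param train_frac Fraction of each class drawn into a fold's training
#'   partition (default 2/3, mirroring a 50-train / 25-test per-class split).
#' @param seed Integer seed for the fold draws.
#' @param cfg A [norm_config] used for normalization (fixed across cells).
#' @param points Output sample count per contour.
#' @return An object of class `section_fit` with the fold-averaged value
#'   matrix (`rows = n_grid`, `columns = lam_grid`), the winning cell, and
#'   the projected training set under the winning section. Cells whose index
#'   was undefined on any fold are `NA` and excluded from the optimum.
#' @seealso [predict.section_fit], [knn_evaluate], [validity_report]
#' @export
fit_section <- function(ds,
                        lam_grid = c(0.5, 1, 2, 5, 10, 100, 1000, 2000, Inf),
                        n_grid = c(0, 2, 3, 4, 5, 7, 9, 10, 20),
                        index = c("dunn", "davies_bouldin"),
                        folds = 30L,
                        train_frac = 2 / 3,
                        seed = 1L,
                        cfg = norm_config(),
                        points = 1000L) {
  stopifnot(inherits(ds, "shape_set"))
  index <- match.arg(index)
  folds <- as.integer(folds)
  if (folds < 1L) stop("folds must be >= 1")
  if (length(lam_grid) == 0L || length(n_grid) == 0L) stop("empty grid")
  if (train_frac <= 0 || train_frac > 1) stop("train_frac must be in (0, 1]")

  # normalization does not depend on (lambda, n): do it once
  normalized <- ds
  normalized$contours <- lapply(ds$contours, normalize_contour, cfg = cfg)

  # fold membership drawn once, reused across all grid cells
  fold_idx <- with_private_seed(seed, {
    lapply(seq_len(folds), function(f) {
      unlist(lapply(seq_len(max(ds$labels)), function(cl) {
        idx <- which(ds$labels == cl)
        ntr <- max(1L, floor(train_frac * length(idx)))
        sort(sample(idx, ntr))
      }), use.names = FALSE)
    })
  })

  index_fun <- switch(index, dunn = dunn_index, davies_bouldin = davies_bouldin_index)
  values <- matrix(NA_real_, length(n_grid), length(lam_grid),
                   dimnames = list(n = format(n_grid), lambda = format(lam_grid)))
  for (a in seq_along(n_grid)) {
    for (b in seq_along(lam_grid)) {
      params <- section_params(lam = lam_grid[b], n = n_grid[a], points = points)
      proj <- normalized
      proj$contours <- lapply(normalized$contours, canonical_resample, params = params)
      attr(proj, "section") <- params
      vals <- vapply(fold_idx, function(idx) {
        tryCatch(index_fun(subset_shape_set(proj, idx)),
                 error = function(e) NA_real_)
      }, numeric(1L))
      if (!anyNA(vals)) values[a, b] <- mean(vals)
    }
  }
  if (all(is.na(values)))
    stop("validity index undefined on every grid cell")
  flat <- if (index == "dunn") values else -values
  best <- which(flat == max(flat, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  best_params <- section_params(lam = lam_grid[best[2L]], n = n_grid[best[1L]],
                                points = points)
  train_proj <- normalized
  train_proj$contours <- lapply(normalized$contours, canonical_resample,
                                params = best_params)
  attr(train_proj, "section") <- best_params

  structure(list(values = values,
                 lam_grid = lam_grid, n_grid = n_grid,
                 index = index, folds = folds, train_frac = train_frac,
                 seed = seed, cfg = cfg, points = points,
                 best = best_params,
                 best_value = values[best[1L], best[2L]],
                 train = train_proj),
            class = "section_fit")
}

#' @export
print.section_fit <- function(x, ...) {
  cat(sprintf("Canonical-section fit (%s index, %d folds, seed %d)\n",
              x$index, x$folds, x$seed))
  cat(sprintf("  grid: %d x %d (n x lambda), %d training contours\n",
              length(x$n_grid), length(x$lam_grid), length(x$train$contours)))
  cat(sprintf("  best section: lambda = %s, n = %d  (%s = %.6g)\n",
              format(x$best$lam), x$best$n, x$index, x$best_value))
  invisible(x)
}

#' @export
summary.section_fit <- function(object, ...) {
  print(object)
  cat("\nFold-averaged index values (rows n, columns lambda):\n")
  print(round(object$values, 4))
  invisible(object)
}

#' @export
coef.section_fit <- function(object, ...) {
  c(lambda = object$best$lam, n = object$best$n)
}

#' @export
plot.section_fit <- function(x, ...) {
  z <- x$values
  graphics::image(x = seq_along(x$lam_grid), y = seq_along(x$n_grid), z = t(z),
                  axes = FALSE, xlab = "lambda", ylab = "n",
                  main = sprintf("%s index over the section grid", x$index), ...)
  graphics::axis(1, at = seq_along(x$lam_grid), labels = format(x$lam_grid))
  graphics::axis(2, at = seq_along(x$n_grid), labels = format(x$n_grid))
  graphics::box()
  best <- coef(x)
  graphics::points(match(best["lambda"], x$lam_grid), match(best["n"], x$n_grid),
                   pch = 4, cex = 2, lwd = 2)
  invisible(x)
}

# k-nearest-neighbour vote over a query-by-train distance matrix
knn_vote <- function(D, train_labels, k) {
  apply(D, 1L, function(drow) {
    ord <- order(drow)
    nn <- ord[seq_len(k)]
    votes <- table(train_labels[nn])
    top <- as.integer(names(votes)[votes == max(votes)])
    if (length(top) == 1L) return(top)
    # ties: smallest mean distance to the query, then smallest label
    md <- vapply(top, function(l) mean(drow[nn[train_labels[nn] == l]]), numeric(1L))
    top <- top[md == min(md)]
    min(top)
  })
}

#' Classify new contours with the learned section metric
#'
#' Projects the query contours under the fitted section and assigns each the
#' majority label of its `k` nearest training samples in section distance.
#'
#' @param object A [fit_section] result.
#' @param newdata A [shape_set] or list of contours (raw, unprojected).
#' @param k Number of neighbours (default 5).
#' @param ... Unused.
#' @return Integer vector of predicted class labels.
#' @export
predict.section_fit <- function(object, newdata, k = 5L, ...) {
  contours <- if (inherits(newdata, "shape_set")) newdata$contours
              else if (inherits(newdata, "contour")) list(newdata)
              else newdata
  proj <- lapply(contours, project_contour, params = object$best, cfg = object$cfg)
  train <- object$train$contours
  if (k > length(train)) stop("k exceeds the number of training samples")
  D <- matrix(0, length(proj), length(train))
  for (i in seq_along(proj)) {
    D[i, ] <- vapply(train, section_distance, numeric(1L), a = proj[[i]])
  }
  knn_vote(D, object$train$labels, as.integer(k))
}

#' k-nearest-neighbour accuracy under the section distance
#'
#' Majority vote over the `k` nearest training samples by [section_distance]
#' (ties: smallest mean distance, then smallest label); returns the fraction
#' of correctly classified test samples. Both sets must already be projected
#' under the same section.
#'
#' @param train,test Projected [shape_set] objects with equal vertex counts.
#' @param k Number of neighbours (default 5).
#' @return Accuracy in `[0, 1]`.
#' @export
knn_evaluate <- function(train, test, k = 5L) {
  stopifnot(inherits(train, "shape_set"), inherits(test, "shape_set"))
  k <- as.integer(k)
  if (k > length(train$contours)) stop("k exceeds the number of training samples")
  D <- matrix(0, length(test$contours), length(train$contours))
  for (i in seq_along(test$contours)) {
    D[i, ] <- vapply(train$contours, section_distance, numeric(1L),
                     a = test$contours[[i]])
  }
  pred <- knn_vote(D, train$labels, k)
  mean(pred == test$labels)
}

#' Orientation-bias diagnostic
#'
#' For each class, the circular distribution of tip directions: the angle of
#' the vector from the area centroid to the start vertex, measured from the
#' upward vertical. A class whose samples were photographed or scanned in a
#' consistent pose has a resultant length near 1; genuinely unoriented
#' classes have small resultant lengths. Many classes above the flag
#' threshold indicate that orientation leaks class information (an alignment
#' bias), which orientation normalization would then erase.
#'
#' @param ds A [shape_set] (raw contours; tip = start vertex).
#' @param flag_threshold Resultant length above which a class is flagged as
#'   aligned (default 0.7).
#' @return A data frame of class `orientation_bias` with per-class circular
#'   mean angle (radians), resultant length, sample count and `biased` flag.
#' @export
orientation_bias_report <- function(ds, flag_threshold = 0.7) {
  stopifnot(inherits(ds, "shape_set"))
  angles <- vapply(ds$contours, function(c) {
    g <- area_centroid(c)
    d <- cxy(c)[1L, ] - g
    atan2(d[1L], d[2L])      # angle from the upward vertical, clockwise-positive
  }, numeric(1L))
  k <- max(ds$labels)
  rows <- lapply(seq_len(k), function(cl) {
    a <- angles[ds$labels == cl]
    z <- mean(exp(1i * a))
    data.frame(class = cl,
               name = if (is.null(ds$class_names)) paste0("class ", cl)
                      else ds$class_names[cl],
               n = length(a),
               mean_angle = Arg(z),
               resultant = Mod(z))
  })
  out <- do.call(rbind, rows)
  out$biased <- out$resultant > flag_threshold
  class(out) <- c("orientation_bias", "data.frame")
  attr(out, "angles") <- angles
  out
}
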