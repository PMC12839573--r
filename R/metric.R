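#' Labeled sets of contours
#'
#' Container pairing contours with integer class labels `1..K` (and optional
#' class names): the substrate for validity indices, metric learning and
#' classification. Use [project_set] to replace every contour by its
#' canonical representative before computing distances.
#'
#' @param contours List of [contour] objects.
#' @param labels Integer class labels, one per contour, or a factor.
#' @param class_names Optional character vector of class names (length =
#'   number of classes).
#' @return An object of class `shape_set`.
#' @export
shape_set <- function(contours, labels, class_names = NULL) {
  if (!is.list(contours) || length(contours) == 0L)
    stop("contours must be a non-empty list")
  contours <- lapply(contours, as_contour)
  if (is.factor(labels)) {
    if (is.null(class_names)) class_names <- levels(labels)
    labels <- as.integer(labels)
  }
  labels <- as.integer(labels)
  if (length(labels) != length(contours))
    stop("labels must match contours in length")
  if (any(is.na(labels)) || any(labels < 1L))
    stop("labels must be positive integers")
  k <- max(labels)
  if (!all(seq_len(k) %in% labels))
    stop("every class 1..K must be non-empty")
  if (!is.null(class_names) && length(class_names) != k)
    stop("class_names must have one entry per class")
  structure(list(contours = contours, labels = labels,
                 class_names = class_names),
            class = "shape_set")
}

#' @export
print.shape_set <- function(x, ...) {
  k <- max(x$labels)
  sec <- attr(x, "section")
  cat(sprintf("<shape_set: %d contours, %d classes%s>\n",
              length(x$contours), k,
              if (is.null(sec)) ""
              else sprintf(", projected under s_(lambda = %s, n = %d)",
                           format(sec$lam), sec$n)))
  tab <- tabulate(x$labels, k)
  nm <- if (is.null(x$class_names)) paste0("class ", seq_len(k)) else x$class_names
  cat(paste0("  ", nm, ": ", tab, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
length.shape_set <- function(x) length(x$contours)

subset_shape_set <- function(ds, idx) {
  out <- structure(list(contours = ds$contours[idx],
                        labels = ds$labels[idx],
                        class_names = ds$class_names),
                   class = "shape_set")
  attr(out, "section") <- attr(ds, "section")
  out
}

#' Project every contour of a set onto a canonical section
#'
#' @param ds A [shape_set].
#' @param params A [section_params].
#' @param cfg A [norm_config].
#' @return A [shape_set] of canonical representatives (all sharing
#'   `params$points` vertices), with the section recorded as an attribute.
#' @export
project_set <- function(ds, params = section_params(), cfg = norm_config()) {
  stopifnot(inherits(ds, "shape_set"))
  out <- ds
  out$contours <- lapply(ds$contours, project_contour, params = params, cfg = cfg)
  attr(out, "section") <- params
  out
}

#' Section-based L2 distance between canonical representatives
#'
#' The discrete `L2(S1)` norm of the pointwise difference,
#' `sqrt(mean(|a_j - b_j|^2))`, with the uniform `1/N` quadrature weight
#' (canonical representatives are uniform in the section's parameter). It is
#' a true metric on canonical representatives: symmetric, zero exactly for
#' equal vertex arrays, and it satisfies the triangle inequality. For two
#' concentric uniformly-sampled circles with a common start it equals the
#' difference of the radii.
#'
#' @param a,b [contour] objects with the same number of vertices.
#' @return Non-negative scalar distance.
#' @export
section_distance <- function(a, b) {
  va <- cxy(as_contour(a)); vb <- cxy(as_contour(b))
  if (nrow(va) != nrow(vb))
    stop("contours must share the same number of vertices")
  d <- va - vb
  sqrt(mean(d[, 1L]^2 + d[, 2L]^2))
}

#' Pairwise section-distance matrix
#'
#' @param ds A projected [shape_set].
#' @return A symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(ds) {
  stopifnot(inherits(ds, "shape_set"))
  m <- length(ds$contours)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- section_distance(ds$contours[[i]], ds$contours[[j]])
    }
  }
  D
}

#' Per-class mean shapes
#'
#' Vertex-wise arithmetic mean of the canonical representatives of each
#' class ("the average of the positions of the points along the contours").
#'
#' @param ds A projected [shape_set].
#' @return A list of `K` [contour] objects.
#' @export
class_centroids <- function(ds) {
  stopifnot(inherits(ds, "shape_set"))
  k <- max(ds$labels)
  lapply(seq_len(k), function(cl) {
    idx <- which(ds$labels == cl)
    if (length(idx) == 0L) stop("empty class ", cl)
    acc <- Reduce(`+`, lapply(ds$contours[idx], cxy)) / length(idx)
    new_contour(acc)
  })
}

# internal: centroid-to-centroid distances, intraclass diameters, mean
# spreads; shared by the indices and the validity report
validity_parts <- function(ds, D = NULL) {
  k <- max(ds$labels)
  cen <- class_centroids(ds)
  Dinter <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j > i) Dinter[i, j] <- Dinter[j, i] <- section_distance(cen[[i]], cen[[j]])
  }
  if (is.null(D)) D <- distance_matrix(ds)
  Dintra <- vapply(seq_len(k), function(cl) {
    idx <- which(ds$labels == cl)
    if (length(idx) < 2L) return(0)
    max(D[idx, idx])
  }, numeric(1L))
  delta_bar <- vapply(seq_len(k), function(cl) {
    idx <- which(ds$labels == cl)
    mean(vapply(idx, function(i) section_distance(ds$contours[[i]], cen[[cl]]),
                numeric(1L)))
  }, numeric(1L))
  list(k = k, centroids = cen, D = D, Dinter = Dinter,
       Dintra = Dintra, delta_bar = delta_bar)
}

#' Dunn index of a labeled shape set
#'
#' Ratio of the minimal interclass distance (measured between class
#' centroids) to the maximal intraclass diameter (maximum pairwise distance
#' within a class). Higher values characterize dense, well-separated
#' clusters. Note the interclass term is centroid-to-centroid, not
#' single-linkage as in the classical Dunn index.
#'
#' @param ds A projected [shape_set] with `K >= 2` classes, at least one of
#'   which has two or more elements.
#' @param parts Optional precomputed result of the internal distance pass
#'   (used by [fit_section] to avoid recomputation).
#' @return Non-negative scalar; higher is better.
#' @export
dunn_index <- function(ds, parts = NULL) {
  if (is.null(parts)) parts <- validity_parts(ds)
  if (parts$k < 2L) stop("Dunn index needs at least two classes")
  dmax <- max(parts$Dintra)
  if (dmax <= 0)
    stop("undefined Dunn index: all classes are singletons (zero diameter)")
  min(parts$Dinter[upper.tri(parts$Dinter)]) / dmax
}

#' Davies-Bouldin index of a labeled shape set
#'
#' Mean over classes of the worst ratio between the summed within-class
#' spreads (mean distance of class members to their centroid) and the
#' distance between the two class centroids. Lower values indicate a better
#' clustering.
#'
#' @inheritParams dunn_index
#' @return Non-negative scalar; lower is better.
#' @export
davies_bouldin_index <- function(ds, parts = NULL) {
  if (is.null(parts)) parts <- validity_parts(ds)
  k <- parts$k
  if (k < 2L) stop("Davies-Bouldin index needs at least two classes")
  if (any(parts$Dinter[upper.tri(parts$Dinter)] <= 0))
    stop("undefined Davies-Bouldin index: coincident class centroids")
  db <- vapply(seq_len(k), function(i) {
    others <- setdiff(seq_len(k), i)
    max((parts$delta_bar[others] + parts$delta_bar[i]) / parts$Dinter[others, i])
  }, numeric(1L))
  mean(db)
}

#' Extreme sample pairs
#'
#' The pair of same-class samples at maximal distance and the pair of
#' different-class samples at minimal distance: the two pairs that drive the
#' Dunn index and are useful for spotting outliers and label
#' inconsistencies. Ties are broken by lexicographic index order `(i, j)`,
#' `i < j`.
#'
#' @param ds A projected [shape_set].
#' @return List with integer index pairs `intra_pair`, `inter_pair` and
#'   their distances.
#' @export
extreme_pairs <- function(ds) {
  stopifnot(inherits(ds, "shape_set"))
  D <- distance_matrix(ds)
  m <- length(ds$contours)
  same <- outer(ds$labels, ds$labels, `==`)
  up <- upper.tri(D)
  best_intra <- NULL; dmax <- -Inf
  best_inter <- NULL; dmin <- Inf
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (same[i, j]) {
        if (D[i, j] > dmax) { dmax <- D[i, j]; best_intra <- c(i, j) }
      } else {
        if (D[i, j] < dmin) { dmin <- D[i, j]; best_inter <- c(i, j) }
      }
    }
  }
  list(intra_pair = best_intra, intra_distance = if (is.finite(dmax)) dmax else NA_real_,
       inter_pair = best_inter, inter_distance = if (is.finite(dmin)) dmin else NA_real_)
}

#' Cluster-validity report
#'
#' Bundles the per-class centroids, the centroid-to-centroid distance
#' matrix, intraclass diameters, mean spreads, Dunn and Davies-Bouldin
#' indices and the extreme sample pairs for a projected labeled set.
#'
#' @param ds A projected [shape_set].
#' @return An object of class `validity_report`.
#' @export
validity_report <- function(ds) {
  parts <- validity_parts(ds)
  ep <- extreme_pairs(ds)
  structure(list(centroids = parts$centroids,
                 D_inter = parts$Dinter,
                 D_intra = parts$Dintra,
                 delta_bar = parts$delta_bar,
                 dunn = tryCatch(dunn_index(ds, parts), error = function(e) NA_real_),
                 davies_bouldin = tryCatch(davies_bouldin_index(ds, parts),
                                           error = function(e) NA_real_),
                 extreme_pairs = ep,
                 class_names = ds$class_names),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("<validity_report>\n")
  cat(sprintf("  classes:        %d\n", length(x$D_intra)))
  cat(sprintf("  Dunn index:     %.6g (higher is better)\n", x$dunn))
  cat(sprintf("  Davies-Bouldin: %.6g (lower is better)\n", x$davies_bouldin))
  ep <- x$extreme_pairs
  cat(sprintf("  widest same-class pair:      (%d, %d) at %.6g\n",
              ep$intra_pair[1L], ep$intra_pair[2L], ep$intra_distance))
  cat(sprintf("  closest different-class pair: (%d, %d) at %.6g\n",
              ep$inter_pair[1L], ep$inter_pair[2L], ep$inter_distance))
  invisible(x)
}

#' Linear interpolation between canonical representatives
#'
#' Convex combinations `(1 - u) a + u b` at `u = 0, 1/(steps-1), ..., 1`.
#' Because canonical representatives are registered point-to-point by the
#' section, the straight segment in `L2` is an optimal deformation between
#' the two shapes; endpoints reproduce the inputs exactly.
#'
#' @param a,b Canonical [contour] representatives with equal vertex counts.
#' @param steps Number of interpolation steps (`>= 2`).
#' @return List of `steps` [contour] objects.
#' @export
interpolate_contours <- function(a, b, steps = 5L) {
  a <- as_contour(a); b <- as_contour(b)
  if (nrow(a) != nrow(b)) stop("contours must share the same number of vertices")
  steps <- as.integer(steps)
  if (steps < 2L) stop("steps must be >= 2")
  va <- cxy(a); vb <- cxy(b)
  lapply(seq_len(steps), function(j) {
    u <- (j - 1) / (steps - 1)
    if (u == 0) return(a)
    if (u == 1) return(b)
    new_contour((1 - u) * va + u * vb)
  })
}
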