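#' Read a contour from CSV or JSON
#'
#' CSV: two columns `x,y`, one vertex per row, no closing duplicate row,
#' header optional. JSON: an object
#' `{"vertices": [[x, y], ...], "label": optional, "name": optional}`.
#' Parse errors report the offending line.
#'
#' @param path File path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return A [contour]; a JSON `label` is attached as attribute `"label"`.
#' @export
read_contour <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(path)
    if (is.null(obj$vertices)) stop("JSON contour lacks a 'vertices' field: ", path)
    out <- contour(matrix(as.numeric(obj$vertices), ncol = 2L),
                   name = obj$name %||% NULL)
    if (!is.null(obj$label)) attr(out, "label") <- as.integer(obj$label)
    return(out)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty contour file: ", path)
  first <- strsplit(lines[1L], ",")[[1L]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first))))
  start <- if (has_header) 2L else 1L
  if (length(lines) < start + 2L)
    stop("contour file has fewer than 3 vertices: ", path)
  rows <- lapply(seq(start, length(lines)), function(i) {
    f <- strsplit(lines[i], ",")[[1L]]
    vals <- suppressWarnings(as.numeric(trimws(f)))
    if (length(vals) != 2L || anyNA(vals))
      stop(sprintf("malformed contour row at line %d of %s: '%s'", i, path, lines[i]))
    vals
  })
  v <- do.call(rbind, rows)
  dup <- which(rowSums((v - rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]))^2) == 0)
  if (length(dup) > 0L)
    stop(sprintf("duplicate consecutive vertex at line %d of %s",
                 dup[1L] + start, path))
  contour(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a contour to CSV or JSON
#'
#' Coordinates are serialized with 17 significant digits, so a write/read
#' round trip reproduces the vertices bit-exactly.
#'
#' @param c A [contour].
#' @param path Output path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @param label Optional integer label (JSON only).
#' @return `path`, invisibly.
#' @export
write_contour <- function(c, path, format = c("auto", "csv", "json"), label = NULL) {
  c <- as_contour(c)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  v <- cxy(c)
  num <- function(z) sprintf("%.17g", z)
  if (format == "csv") {
    writeLines(c("x,y", paste(num(v[, 1L]), num(v[, 2L]), sep = ",")), path)
  } else {
    rows <- paste0("[", num(v[, 1L]), ",", num(v[, 2L]), "]")
    fields <- c(sprintf("\"vertices\":[%s]", paste(rows, collapse = ",")))
    if (!is.null(label)) fields <- c(fields, sprintf("\"label\":%d", as.integer(label)))
    nm <- attr(c, "name")
    if (!is.null(nm)) fields <- c(fields, sprintf("\"name\":\"%s\"", nm))
    writeLines(paste0("{", paste(fields, collapse = ","), "}"), path)
  }
  invisible(path)
}

#' Write a distance matrix as CSV
#'
#' Square matrix with a header of sample ids.
#'
#' @param D Symmetric distance matrix.
#' @param path Output path.
#' @param ids Optional sample ids (default `s1..sm`).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(D)))
  dimnames(D) <- list(ids, ids)
  utils::write.csv(D, path, quote = FALSE)
  invisible(path)
}

#' Serialize a validity report to JSON
#'
#' @param report A [validity_report].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validity_report <- function(report, path) {
  stopifnot(inherits(report, "validity_report"))
  obj <- list(dunn = report$dunn,
              davies_bouldin = report$davies_bouldin,
              D_inter = report$D_inter,
              D_intra = report$D_intra,
              delta_bar = report$delta_bar,
              extreme_pairs = report$extreme_pairs,
              class_names = report$class_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a section-fit grid as CSV
#'
#' Table layout: one row per clock subdivision count `n`, one column per
#' curvature weight `lambda`.
#'
#' @param fit A [fit_section] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(fit, path) {
  stopifnot(inherits(fit, "section_fit"))
  m <- fit$values
  dimnames(m) <- list(format(fit$n_grid, trim = TRUE),
                      format(fit$lam_grid, trim = TRUE))
  utils::write.csv(m, path, quote = FALSE)
  invisible(path)
}

#' Extract the boundary contour of a binary mask
#'
#' Traces the 0.5 iso-level of the mask with a marching-squares-style
#' sub-pixel contour tracer ([grDevices::contourLines]), after `smooth`
#' passes of a 3x3 box blur that suppress the half-pixel staircase a binary
#' grid otherwise imprints on the iso-contour (staircase artifacts inflate
#' the perimeter and pollute curvature weighting). Image rows increase
#' downward and are converted to y-up world coordinates, so "largest
#' vertical component" matches the physical top of the object. The largest
#' closed iso-contour is returned, oriented counterclockwise.
#'
#' @param mask Numeric or logical matrix (rows = image rows top to bottom);
#'   foreground is `> 0.5`.
#' @param target_vertices Optional count: if given, the traced boundary is
#'   resampled to this many constant-speed vertices.
#' @param smooth Number of 3x3 box-blur passes before tracing (default 2;
#'   use 0 for the raw marching-squares polygon).
#' @return A counterclockwise [contour].
#' @export
extract_boundary <- function(mask, target_vertices = NULL, smooth = 2L) {
  m <- as.matrix(mask) * 1
  if (!any(m > 0.5)) stop("boundary extraction failed: empty mask")
  # pad with background so boundary components touching the frame stay
  # closed, with room for the blur to spread
  margin <- as.integer(smooth) + 1L
  pad <- matrix(0, nrow(m) + 2L * margin, ncol(m) + 2L * margin)
  pad[margin + seq_len(nrow(m)), margin + seq_len(ncol(m))] <- m
  for (i in seq_len(smooth)) pad <- box_blur3(pad)
  # world coords: x = column index, y = (flipped) row index
  z <- t(pad[nrow(pad):1L, , drop = FALSE])
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (length(cl) == 0L) stop("boundary extraction failed: no iso-contour at 0.5")
  closed <- Filter(function(p) {
    length(p$x) > 3L && abs(p$x[1L] - p$x[length(p$x)]) < 1e-9 &&
      abs(p$y[1L] - p$y[length(p$y)]) < 1e-9
  }, cl)
  if (length(closed) == 0L) stop("boundary extraction failed: no closed iso-contour")
  per <- vapply(closed, function(p) {
    sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
  }, numeric(1L))
  best <- closed[[which.max(per)]]
  k <- length(best$x)
  # drop the closing duplicate and undo the padding offset
  v <- cbind(best$x[-k], best$y[-k]) - margin
  keep <- c(TRUE, rowSums(diff(v)^2) > 1e-18)
  v <- v[keep, , drop = FALSE]
  out <- contour(v)
  out <- standardize_direction(out)
  if (!is.null(target_vertices))
    out <- apply_param_map(out, arclength_map(out), n_out = as.integer(target_vertices))
  out
}

# one pass of a 3x3 box blur (zero boundary)
box_blur3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2L:(nr + 1L), 2L:(nc + 1L)] <- m
  (p[1L:nr, 1L:nc] + p[1L:nr, 2L:(nc + 1L)] + p[1L:nr, 3L:(nc + 2L)] +
     p[2L:(nr + 1L), 1L:nc] + p[2L:(nr + 1L), 2L:(nc + 1L)] + p[2L:(nr + 1L), 3L:(nc + 2L)] +
     p[3L:(nr + 2L), 1L:nc] + p[3L:(nr + 2L), 2L:(nc + 1L)] + p[3L:(nr + 2L), 3L:(nc + 2L)]) / 9
}
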