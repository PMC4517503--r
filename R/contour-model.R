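#' Slice geometry of a short-axis image stack
#'
#' Physical geometry shared by all contours of one case: in-plane pixel size,
#' slice thickness and inter-slice (center-to-center) distance, image matrix
#' size and number of short-axis slices. Slice index 0 is the most apical
#' contoured slice. Contour coordinates are physical millimetres with the
#' center of pixel (0, 0) at (dx/2, dy/2), so volumes are independent of the
#' acquisition matrix.
#'
#' @param pixel_size_mm numeric length-2 `(dx, dy)` in mm, or a scalar for
#'   square pixels.
#' @param slice_thickness_mm slice thickness in mm.
#' @param slice_spacing_mm center-to-center inter-slice distance in mm. May be
#'   smaller than the thickness (overlapping) or larger (gapped).
#' @param n_rows,n_cols image matrix size in pixels.
#' @param n_slices number of short-axis slice positions.
#' @return an object of class `slice_geometry`.
#' @export
slice_geometry <- function(pixel_size_mm, slice_thickness_mm, slice_spacing_mm,
                           n_rows, n_cols, n_slices) {
  if (length(pixel_size_mm) == 1L) pixel_size_mm <- rep(pixel_size_mm, 2L)
  stopifnot(
    length(pixel_size_mm) == 2L, all(pixel_size_mm > 0),
    slice_thickness_mm > 0, slice_spacing_mm > 0,
    n_rows >= 1, n_cols >= 1, n_slices >= 1
  )
  structure(
    list(
      pixel_size_mm = as.numeric(pixel_size_mm),
      slice_thickness_mm = as.numeric(slice_thickness_mm),
      slice_spacing_mm = as.numeric(slice_spacing_mm),
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      n_slices = as.integer(n_slices)
    ),
    class = "slice_geometry"
  )
}

#' A single closed LV contour
#'
#' One closed planar polygon for one surface (`"endo"` or `"epi"`) on one
#' slice at one frame (`"ED"` or `"ES"`), in physical mm coordinates. The
#' polygon is implicitly closed (last vertex joins the first), must be simple
#' (non-self-intersecting) with nonzero area, and is normalized to
#' counter-clockwise orientation on construction.
#'
#' @param points numeric matrix with columns `(x_mm, y_mm)` and at least 3
#'   rows.
#' @param surface `"endo"` or `"epi"`.
#' @param frame `"ED"` or `"ES"`.
#' @param slice_index integer slice index (0 = most apical).
#' @param check if `TRUE` (default) verify simplicity; the O(n^2) segment
#'   test is skipped for internally generated star-shaped polygons.
#' @return an object of class `lv_contour`.
#' @export
lv_contour <- function(points, surface = c("endo", "epi"),
                       frame = c("ED", "ES"), slice_index = 0L,
                       check = TRUE) {
  surface <- match.arg(surface)
  frame <- match.arg(frame)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L || nrow(points) < 3L) {
    stop("contour needs a two-column point matrix with >= 3 vertices ",
         "(frame ", frame, ", slice ", slice_index, ", ", surface, ")")
  }
  # drop a duplicated closing vertex
  n <- nrow(points)
  if (all(points[1L, ] == points[n, ])) points <- points[-n, , drop = FALSE]
  a <- signed_area(points)
  if (abs(a) < .Machine$double.eps) {
    stop("degenerate contour with zero area (frame ", frame,
         ", slice ", slice_index, ", ", surface, ")")
  }
  if (a < 0) points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  if (check && !is_simple_polygon(points)) {
    stop("self-intersecting contour (frame ", frame, ", slice ", slice_index,
         ", ", surface, ")")
  }
  structure(
    list(points = points, surface = surface, frame = frame,
         slice_index = as.integer(slice_index)),
    class = "lv_contour"
  )
}

# Shoelace signed area; positive for counter-clockwise vertex order.
signed_area <- function(points) {
  x <- points[, 1L]; y <- points[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

is_simple_polygon <- function(points) {
  n <- nrow(points)
  if (n < 4L) return(TRUE)
  x <- points[, 1L]; y <- points[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    # adjacent segments share a vertex; skip the wrap-around neighbour of 1
    if (i == 1L) js <- js[js != n]
    if (!length(js)) next
    if (any(segments_cross(x[i], y[i], x2[i], y2[i],
                           x[js], y[js], x2[js], y2[js]))) {
      return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Absolute polygon area in mm^2
#'
#' Shoelace area of a contour (or a raw two-column vertex matrix). This is the
#' polygon area backend used for reader contours; consensus areas come from
#' the supersampled raster by default.
#'
#' @param contour an [lv_contour] or a numeric matrix of vertices.
#' @return area in mm^2.
#' @export
polygon_area_mm2 <- function(contour) {
  pts <- if (inherits(contour, "lv_contour")) contour$points else as.matrix(contour)
  abs(signed_area(pts))
}

polygon_centroid <- function(contour) {
  pts <- if (inherits(contour, "lv_contour")) contour$points else as.matrix(contour)
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Collection of contours for one case from one source
#'
#' All contours drawn for one case by one source (a reader, the simulated
#' truth, or the consensus), keyed by (frame, slice, surface), together with
#' the slice geometry. Any key may be absent: readers are free to skip slices.
#'
#' @param case_id case identifier.
#' @param source_id source label (reader id, `"truth"`, or `"consensus"`).
#' @param geometry a [slice_geometry].
#' @param contours list of [lv_contour]s (names assigned automatically).
#' @return an object of class `contour_set`.
#' @export
contour_set <- function(case_id, source_id, geometry, contours = list()) {
  stopifnot(inherits(geometry, "slice_geometry"))
  set <- structure(
    list(case_id = as.character(case_id), source_id = as.character(source_id),
         geometry = geometry, contours = list()),
    class = "contour_set"
  )
  for (ct in contours) set <- set_contour(set, ct)
  set
}

contour_key <- function(frame, slice_index, surface) {
  paste(frame, slice_index, surface, sep = "|")
}

#' Insert or replace one contour in a set
#' @param set a [contour_set].
#' @param contour an [lv_contour].
#' @return the updated set.
#' @export
set_contour <- function(set, contour) {
  stopifnot(inherits(set, "contour_set"), inherits(contour, "lv_contour"))
  g <- set$geometry
  pts <- contour$points
  if (any(pts[, 1L] < 0) || any(pts[, 2L] < 0) ||
      any(pts[, 1L] > g$n_cols * g$pixel_size_mm[1L]) ||
      any(pts[, 2L] > g$n_rows * g$pixel_size_mm[2L])) {
    stop("contour outside image bounds (case ", set$case_id, ", source ",
         set$source_id, ", frame ", contour$frame, ", slice ",
         contour$slice_index, ", ", contour$surface, ")")
  }
  key <- contour_key(contour$frame, contour$slice_index, contour$surface)
  set$contours[[key]] <- contour
  # nesting: endo strictly smaller than epi on the same ED slice
  other <- if (contour$surface == "endo") "epi" else "endo"
  okey <- contour_key(contour$frame, contour$slice_index, other)
  if (!is.null(set$contours[[okey]])) {
    endo <- if (contour$surface == "endo") contour else set$contours[[okey]]
    epi <- if (contour$surface == "epi") contour else set$contours[[okey]]
    if (polygon_area_mm2(endo) >= polygon_area_mm2(epi)) {
      stop("endocardial area not smaller than epicardial area (case ",
           set$case_id, ", source ", set$source_id, ", frame ",
           contour$frame, ", slice ", contour$slice_index, ")")
    }
  }
  set
}

#' Retrieve one contour (or NULL) from a set
#' @param set a [contour_set].
#' @inheritParams lv_contour
#' @return an [lv_contour] or `NULL` when absent.
#' @export
get_contour <- function(set, frame, slice_index, surface) {
  set$contours[[contour_key(frame, slice_index, surface)]]
}

#' Keys present in a contour set
#' @param set a [contour_set].
#' @return data.frame with columns frame, slice_index, surface, key.
#' @export
contour_keys <- function(set) {
  keys <- names(set$contours)
  if (!length(keys)) {
    return(data.frame(frame = character(), slice_index = integer(),
                      surface = character(), key = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  data.frame(frame = parts[, 1L], slice_index = as.integer(parts[, 2L]),
             surface = parts[, 3L], key = keys, stringsAsFactors = FALSE)
}

#' @export
print.contour_set <- function(x, ...) {
  cat("<contour_set> case", x$case_id, "source", x$source_id, "-",
      length(x$contours), "contours,", x$geometry$n_slices, "slices\n")
  invisible(x)
}

#' @export
print.slice_geometry <- function(x, ...) {
  cat(sprintf("<slice_geometry> %dx%d px @ %.2fx%.2f mm, %d slices, SLT %.1f / SLD %.1f mm\n",
              x$n_rows, x$n_cols, x$pixel_size_mm[1L], x$pixel_size_mm[2L],
              x$n_slices, x$slice_thickness_mm, x$slice_spacing_mm))
  invisible(x)
}
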