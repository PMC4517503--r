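#' Rasterize a contour to a supersampled binary mask
#'
#' Converts a contour polygon to a binary decision map on a grid supersampled
#' by `factor` relative to the image pixel grid (default 4, i.e. 16 sub-cells
#' per pixel). A cell is 1 iff its center lies inside the polygon under the
#' even-odd rule; centers that fall exactly on the boundary are resolved by a
#' half-open scanline convention (entering edge in, exiting edge out), so the
#' test is deterministic and tie-free.
#'
#' The mask is stored on a rectangular window of the full supersampled grid
#' (by default the whole image) recorded in supersampled-cell offsets, so
#' fusion can work on a tight region of interest without materializing the
#' full grid.
#'
#' @param contour an [lv_contour].
#' @param geometry a [slice_geometry].
#' @param factor supersampling factor (integer >= 1, default 4).
#' @param window optional `list(row0, col0, nrow, ncol)` in supersampled cell
#'   units (0-based offsets); default covers the full image.
#' @return an object of class `lv_mask` with fields `grid` (integer matrix),
#'   `row0`, `col0`, `factor`, `cell_dx`, `cell_dy`, `cell_area_mm2`, and the
#'   contour's frame/slice/surface.
#' @export
rasterize_contour <- function(contour, geometry, factor = 4L, window = NULL) {
  stopifnot(inherits(contour, "lv_contour"), inherits(geometry, "slice_geometry"),
            factor >= 1)
  factor <- as.integer(factor)
  g <- geometry
  pts <- contour$points
  if (any(pts[, 1L] < 0) || any(pts[, 2L] < 0) ||
      any(pts[, 1L] > g$n_cols * g$pixel_size_mm[1L]) ||
      any(pts[, 2L] > g$n_rows * g$pixel_size_mm[2L])) {
    stop("contour outside image bounds (frame ", contour$frame, ", slice ",
         contour$slice_index, ", ", contour$surface, ")")
  }
  cdx <- g$pixel_size_mm[1L] / factor
  cdy <- g$pixel_size_mm[2L] / factor
  if (is.null(window)) {
    window <- list(row0 = 0L, col0 = 0L,
                   nrow = g$n_rows * factor, ncol = g$n_cols * factor)
  }
  xc <- (window$col0 + seq_len(window$ncol) - 0.5) * cdx
  yc <- (window$row0 + seq_len(window$nrow) - 0.5) * cdy
  grid <- .raster_polygon(pts[, 1L], pts[, 2L], xc, yc)
  structure(
    list(grid = grid, row0 = as.integer(window$row0), col0 = as.integer(window$col0),
         factor = factor, cell_dx = cdx, cell_dy = cdy,
         cell_area_mm2 = cdx * cdy,
         frame = contour$frame, slice_index = contour$slice_index,
         surface = contour$surface),
    class = "lv_mask"
  )
}

#' Area of a binary mask in mm^2
#' @param mask an `lv_mask`.
#' @return number of set cells times the cell area.
#' @export
mask_area_mm2 <- function(mask) {
  stopifnot(inherits(mask, "lv_mask"))
  sum(mask$grid) * mask$cell_area_mm2
}

# Tight common window (supersampled cells) around a list of contours,
# expanded by margin_mm and clipped to the image grid.
window_for_contours <- function(contours, geometry, factor, margin_mm = 0) {
  pts <- do.call(rbind, lapply(contours, function(ct) ct$points))
  cdx <- geometry$pixel_size_mm[1L] / factor
  cdy <- geometry$pixel_size_mm[2L] / factor
  col_lo <- floor((min(pts[, 1L]) - margin_mm) / cdx) - 2L
  col_hi <- ceiling((max(pts[, 1L]) + margin_mm) / cdx) + 2L
  row_lo <- floor((min(pts[, 2L]) - margin_mm) / cdy) - 2L
  row_hi <- ceiling((max(pts[, 2L]) + margin_mm) / cdy) + 2L
  col_lo <- max(0L, as.integer(col_lo))
  row_lo <- max(0L, as.integer(row_lo))
  col_hi <- min(geometry$n_cols * factor, as.integer(col_hi))
  row_hi <- min(geometry$n_rows * factor, as.integer(row_hi))
  list(row0 = row_lo, col0 = col_lo,
       nrow = row_hi - row_lo, ncol = col_hi - col_lo)
}

# Binary dilation by a square structuring element of half-width (rx, ry)
# cells, via separable running-max passes with logarithmic step doubling
# (dilating an interval of half-width c by a shift of s <= c + 1 yields a
# contiguous interval of half-width c + s).
dilate_binary <- function(mat, rx, ry) {
  shift_rows <- function(m, k) {
    n <- nrow(m)
    if (k > 0) rbind(m[-seq_len(k), , drop = FALSE], matrix(0, k, ncol(m)))
    else rbind(matrix(0, -k, ncol(m)), m[seq_len(n + k), , drop = FALSE])
  }
  shift_cols <- function(m, k) {
    n <- ncol(m)
    if (k > 0) cbind(m[, -seq_len(k), drop = FALSE], matrix(0, nrow(m), k))
    else cbind(matrix(0, nrow(m), -k), m[, seq_len(n + k), drop = FALSE])
  }
  out <- mat
  c <- 0L
  while (c < ry) {
    s <- min(ry - c, c + 1L)
    out <- pmax(out, shift_rows(out, s), shift_rows(out, -s))
    c <- c + s
  }
  c <- 0L
  while (c < rx) {
    s <- min(rx - c, c + 1L)
    out <- pmax(out, shift_cols(out, s), shift_cols(out, -s))
    c <- c + s
  }
  out
}

#' Extract the consensus contour from a probability map
#'
#' Traces the 0.5 (or `threshold`) level set of a probability map with
#' marching-squares style linear interpolation ([grDevices::contourLines()])
#' on the zero-padded map, keeps the largest-area closed contour (the boundary
#' of the largest connected component for the single-blob maps produced by
#' label fusion), and returns it as a counter-clockwise polygon in mm.
#' An empty thresholded set yields `NULL` ("no contour"), not an error.
#'
#' @param prob a probability grid: an `lv_mask`-like object whose `grid` holds
#'   values in \\[0, 1\\] (e.g. the `W` field of [staple_fuse()]'s result), or
#'   a plain matrix combined with `geometry` and `factor`.
#' @param geometry,factor used when `prob` is a plain matrix (window assumed
#'   to start at cell (0, 0) unless `row0`/`col0` are given).
#' @param threshold level at which the boundary is traced (default 0.5).
#' @param frame,slice_index,surface metadata for the returned contour
#'   (defaulting to `prob`'s own when present).
#' @return an [lv_contour] or `NULL`.
#' @export
extract_contour <- function(prob, geometry = NULL, factor = 4L, threshold = 0.5,
                            frame = NULL, slice_index = NULL, surface = NULL) {
  if (inherits(prob, "lv_mask") || is.list(prob)) {
    grid <- prob$grid
    cdx <- prob$cell_dx; cdy <- prob$cell_dy
    row0 <- prob$row0 %||% 0L; col0 <- prob$col0 %||% 0L
    frame <- frame %||% prob$frame
    slice_index <- slice_index %||% prob$slice_index
    surface <- surface %||% prob$surface
  } else {
    stopifnot(inherits(geometry, "slice_geometry"))
    grid <- prob
    cdx <- geometry$pixel_size_mm[1L] / factor
    cdy <- geometry$pixel_size_mm[2L] / factor
    row0 <- 0L; col0 <- 0L
  }
  stopifnot(min(grid) >= 0, max(grid) <= 1)
  if (!any(grid >= threshold)) return(NULL)
  padded <- matrix(0, nrow(grid) + 2L, ncol(grid) + 2L)
  padded[2:(nrow(grid) + 1L), 2:(ncol(grid) + 1L)] <- grid
  xc <- (col0 + seq_len(ncol(padded)) - 1.5) * cdx
  yc <- (row0 + seq_len(nrow(padded)) - 1.5) * cdy
  # contourLines wants z[i, j] at (x[i], y[j]); our grid is rows = y
  lines <- grDevices::contourLines(x = xc, y = yc, z = t(padded),
                                   levels = threshold)
  if (!length(lines)) return(NULL)
  areas <- vapply(lines, function(l) abs(signed_area(cbind(l$x, l$y))), 0)
  best <- lines[[which.max(areas)]]
  lv_contour(cbind(best$x, best$y),
             surface = surface %||% "endo", frame = frame %||% "ED",
             slice_index = slice_index %||% 0L, check = FALSE)
}
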