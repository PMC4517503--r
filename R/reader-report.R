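#' Minimum distance from a point to a closed contour
#'
#' Segment-wise (not vertex-only) Euclidean distance from one or more points
#' to the closed polyline of a contour.
#'
#' @param point numeric length-2 `(x, y)` or an n x 2 matrix of points.
#' @param contour an [lv_contour] (or vertex matrix).
#' @return distance(s) in mm.
#' @export
point_to_contour_distance <- function(point, contour) {
  pts <- if (inherits(contour, "lv_contour")) contour$points else
    as.matrix(contour)
  q <- if (is.matrix(point)) point else matrix(point, ncol = 2L)
  .dist_to_polyline(q[, 1L], q[, 2L], pts[, 1L], pts[, 2L])
}

# Outermost intersection distance of rays from `origin` along `angles` with a
# closed polygon; NA when a ray never crosses the boundary.
ray_crossing_radius <- function(origin, angles, contour) {
  pts <- if (inherits(contour, "lv_contour")) contour$points else
    as.matrix(contour)
  n <- nrow(pts)
  ax <- pts[, 1L]; ay <- pts[, 2L]
  bx <- c(ax[-1L], ax[1L]); by <- c(ay[-1L], ay[1L])
  ex <- bx - ax; ey <- by - ay
  vapply(angles, function(th) {
    ux <- cos(th); uy <- sin(th)
    denom <- ux * ey - uy * ex
    ok <- abs(denom) > 1e-12
    t <- ((ax - origin[1L]) * ey - (ay - origin[2L]) * ex) / denom
    s <- ((ax - origin[1L]) * uy - (ay - origin[2L]) * ux) / denom
    hit <- ok & s >= 0 & s < 1 & t > 0
    if (!any(hit)) return(NA_real_)
    max(t[hit])
  }, 0)
}

#' Per-slice discrepancy report of one reader against the consensus
#'
#' For every (frame, slice, surface) shared by the reader and the consensus:
#' the distance of each reader contour point to the consensus contour, flags
#' for points farther than `threshold_mm` (default 3 mm), the cross-reader
#' radial band (min/max boundary radius over all readers, sampled on
#' `n_directions` equally spaced rays from the consensus centroid), and the
#' mean/max/SD distance summary. Keys the reader contoured but for which no
#' consensus exists (e.g. slices failing the most-readers rule) are skipped
#' and listed.
#'
#' @param reader a reader's [contour_set].
#' @param consensus the consensus [contour_set].
#' @param all_readers list of every reader's [contour_set] (for the band);
#'   defaults to just `reader`.
#' @param threshold_mm flag distance threshold (default 3).
#' @param n_directions rays for the band (default 72, i.e. 5 degree steps).
#' @return object of class `discrepancy_report`: list with `slices` (named
#'   list of per-key records: `key`, `frame`, `slice_index`, `surface`,
#'   `distances_mm`, `flagged` (indices), `band` (data.frame angle_rad,
#'   band_min_mm, band_max_mm), `summary` (mean/max/sd)), `skipped_keys`,
#'   `reader_id`, `threshold_mm`.
#' @export
discrepancy_report <- function(reader, consensus, all_readers = NULL,
                               threshold_mm = 3.0, n_directions = 72L) {
  stopifnot(inherits(reader, "contour_set"), inherits(consensus, "contour_set"))
  if (is.null(all_readers)) all_readers <- list(reader)
  rk <- contour_keys(reader)
  shared <- rk$key[rk$key %in% contour_keys(consensus)$key]
  skipped <- setdiff(rk$key, shared)
  angles <- 2 * pi * (seq_len(n_directions) - 1L) / n_directions
  slices <- list()
  for (key in shared) {
    rc <- reader$contours[[key]]
    cc <- consensus$contours[[key]]
    d <- point_to_contour_distance(rc$points, cc)
    cen <- polygon_centroid(cc)
    radii <- vapply(all_readers, function(s) {
      ct <- s$contours[[key]]
      if (is.null(ct)) return(rep(NA_real_, n_directions))
      ray_crossing_radius(cen, angles, ct)
    }, numeric(n_directions))
    radii <- matrix(radii, nrow = n_directions)
    band <- data.frame(
      angle_rad = angles,
      band_min_mm = apply(radii, 1L, function(v) suppressWarnings(min(v, na.rm = TRUE))),
      band_max_mm = apply(radii, 1L, function(v) suppressWarnings(max(v, na.rm = TRUE)))
    )
    band$band_min_mm[!is.finite(band$band_min_mm)] <- NA_real_
    band$band_max_mm[!is.finite(band$band_max_mm)] <- NA_real_
    slices[[key]] <- list(
      key = key, frame = rc$frame, slice_index = rc$slice_index,
      surface = rc$surface, distances_mm = d,
      flagged = which(d > threshold_mm), band = band,
      summary = c(mean = mean(d), max = max(d), sd = stats::sd(d))
    )
  }
  structure(
    list(slices = slices, skipped_keys = skipped,
         reader_id = reader$source_id, threshold_mm = threshold_mm),
    class = "discrepancy_report"
  )
}

#' Discrepancy report as a flat per-point table
#' @param report a [discrepancy_report()].
#' @return data.frame: key, frame, slice_index, surface, point_index,
#'   distance_mm, flagged.
#' @export
discrepancy_table <- function(report) {
  stopifnot(inherits(report, "discrepancy_report"))
  if (!length(report$slices)) {
    return(data.frame(key = character(), frame = character(),
                      slice_index = integer(), surface = character(),
                      point_index = integer(), distance_mm = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(report$slices, function(s) {
    n <- length(s$distances_mm)
    data.frame(key = s$key, frame = s$frame, slice_index = s$slice_index,
               surface = s$surface, point_index = seq_len(n) - 1L,
               distance_mm = s$distances_mm,
               flagged = seq_len(n) %in% s$flagged,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Render a reader discrepancy report
#'
#' Draws, per shared slice key, the consensus contour, the reader contour,
#' the cross-reader band (region between the minimum and maximum reader
#' boundary along each ray) and markers on reader points farther than the
#' flag threshold from the consensus; writes a multi-page PDF and a CSV of
#' the underlying per-point distances so the numbers are testable without
#' pixel comparison. An empty report yields a valid CSV and no figure pages.
#'
#' @param report a [discrepancy_report()].
#' @param path output path prefix; writes `<path>.pdf` and `<path>.csv`.
#' @param reader the reader's [contour_set] (for drawing its contours).
#' @param consensus the consensus [contour_set].
#' @return invisibly, a list with `pdf` and `csv` paths (pdf `NULL` when no
#'   pages were drawn).
#' @export
render_report <- function(report, path, reader, consensus) {
  stopifnot(inherits(report, "discrepancy_report"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory '", dir, "' does not exist")
  csv <- paste0(path, ".csv")
  utils::write.csv(discrepancy_table(report), csv, row.names = FALSE)
  if (!length(report$slices)) {
    return(invisible(list(pdf = NULL, csv = csv)))
  }
  pdf_path <- paste0(path, ".pdf")
  grDevices::pdf(pdf_path, width = 6, height = 6)
  on.exit(grDevices::dev.off())
  for (s in report$slices) {
    cc <- consensus$contours[[s$key]]
    rc <- reader$contours[[s$key]]
    cen <- polygon_centroid(cc)
    band <- s$band[stats::complete.cases(s$band), , drop = FALSE]
    layers <- list()
    if (nrow(band)) {
      outer_pts <- data.frame(
        x = cen[1L] + band$band_max_mm * cos(band$angle_rad),
        y = cen[2L] + band$band_max_mm * sin(band$angle_rad))
      inner_pts <- data.frame(
        x = cen[1L] + band$band_min_mm * cos(rev(band$angle_rad)),
        y = cen[2L] + band$band_min_mm * sin(rev(band$angle_rad)))
      band_poly <- rbind(outer_pts, inner_pts)
      layers <- c(layers, list(ggplot2::geom_polygon(
        data = band_poly, ggplot2::aes(x = .data$x, y = .data$y),
        fill = "magenta", alpha = 0.25)))
    }
    cons_df <- as.data.frame(rbind(cc$points, cc$points[1L, ]))
    names(cons_df) <- c("x", "y")
    read_df <- as.data.frame(rbind(rc$points, rc$points[1L, ]))
    names(read_df) <- c("x", "y")
    p <- ggplot2::ggplot() +
      layers +
      ggplot2::geom_path(data = cons_df, ggplot2::aes(x = .data$x, y = .data$y),
                         color = "red", linewidth = 0.8) +
      ggplot2::geom_path(data = read_df, ggplot2::aes(x = .data$x, y = .data$y),
                         color = "darkgreen", linewidth = 0.6)
    if (length(s$flagged)) {
      flag_df <- as.data.frame(rc$points[s$flagged, , drop = FALSE])
      names(flag_df) <- c("x", "y")
      p <- p + ggplot2::geom_point(data = flag_df,
                                   ggplot2::aes(x = .data$x, y = .data$y),
                                   shape = 17, color = "black", size = 2)
    }
    p <- p + ggplot2::coord_fixed() +
      ggplot2::labs(
        title = sprintf("Reader %s vs consensus - %s slice %d (%s)",
                        report$reader_id, s$frame, s$slice_index, s$surface),
        subtitle = sprintf("distance mean %.2f / max %.2f / sd %.2f mm; %d point(s) > %.1f mm",
                           s$summary[["mean"]], s$summary[["max"]],
                           s$summary[["sd"]], length(s$flagged),
                           report$threshold_mm),
        x = "x (mm)", y = "y (mm)") +
      ggplot2::theme_minimal()
    print(p)
  }
  invisible(list(pdf = pdf_path, csv = csv))
}
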