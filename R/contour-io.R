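#' Read a contour exchange file
#'
#' The exchange format is a UTF-8, LF-terminated CSV with one record per
#' contour point:
#'
#' ```
#' case_id,source_id,frame,slice_index,surface,point_index,x_mm,y_mm
#' ```
#'
#' preceded by `#`-prefixed header lines carrying the slice geometry, e.g.
#' `# geometry: dx=1.25 dy=1.25 slt=8 sld=8 nrow=176 ncol=176 nslices=12`.
#' Writers emit vertices in counter-clockwise order; readers re-normalize
#' orientation regardless. One file holds all contours of one case from one
#' source.
#'
#' @param path path to an exchange file written by [write_contour_set()].
#' @return a [contour_set].
#' @export
read_contour_set <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  gline <- grep("^# geometry:", lines, value = TRUE)
  if (length(gline) != 1L) {
    stop("malformed contour file '", path, "': expected exactly one ",
         "'# geometry:' header line, found ", length(gline))
  }
  kv <- regmatches(gline, gregexpr("[a-z]+=[0-9.eE+-]+", gline))[[1L]]
  vals <- as.numeric(sub("^[a-z]+=", "", kv))
  names(vals) <- sub("=.*$", "", kv)
  need <- c("dx", "dy", "slt", "sld", "nrow", "ncol", "nslices")
  if (!all(need %in% names(vals))) {
    stop("malformed geometry header in '", path, "': missing ",
         paste(setdiff(need, names(vals)), collapse = ", "))
  }
  geom <- slice_geometry(c(vals[["dx"]], vals[["dy"]]), vals[["slt"]],
                         vals[["sld"]], vals[["nrow"]], vals[["ncol"]],
                         vals[["nslices"]])
  body <- lines[!startsWith(lines, "#")]
  header <- "case_id,source_id,frame,slice_index,surface,point_index,x_mm,y_mm"
  if (!length(body) || body[1L] != header) {
    stop("malformed contour file '", path, "' at line ",
         which(!startsWith(lines, "#"))[1L], ": expected header '", header, "'")
  }
  sline <- grep("^# set:", lines, value = TRUE)
  set_case <- set_source <- NULL
  if (length(sline) == 1L) {
    set_case <- sub(".*case_id=([^ ]+).*", "\\1", sline)
    set_source <- sub(".*source_id=([^ ]+).*", "\\1", sline)
  }
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    # legal: a consensus file where every slice failed the most-readers rule
    return(contour_set(set_case %||% "unknown", set_source %||% "unknown", geom))
  }
  bad <- which(!df$frame %in% c("ED", "ES") | !df$surface %in% c("endo", "epi") |
                 !is.finite(df$x_mm) | !is.finite(df$y_mm))
  if (length(bad)) {
    stop("malformed record in '", path, "' at data line ", bad[1L],
         ": frame/surface/coordinates invalid")
  }
  case_id <- df$case_id[1L]
  source_id <- df$source_id[1L]
  if (any(df$case_id != case_id) || any(df$source_id != source_id)) {
    stop("contour file '", path, "' mixes cases or sources")
  }
  set <- contour_set(case_id, source_id, geom)
  for (grp in split(df, contour_key(df$frame, df$slice_index, df$surface))) {
    grp <- grp[order(grp$point_index), , drop = FALSE]
    ct <- lv_contour(cbind(grp$x_mm, grp$y_mm), surface = grp$surface[1L],
                     frame = grp$frame[1L], slice_index = grp$slice_index[1L])
    set <- set_contour(set, ct)
  }
  set
}

#' Write a contour exchange file
#'
#' @param set a [contour_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_contour_set()] for the format.
#' @export
write_contour_set <- function(set, path) {
  stopifnot(inherits(set, "contour_set"))
  g <- set$geometry
  con <- file(path, open = "wb")  # binary mode forces LF on every platform
  on.exit(close(con))
  writeLines(sprintf("# set: case_id=%s source_id=%s", set$case_id,
                     set$source_id), con, useBytes = TRUE)
  writeLines(sprintf(
    "# geometry: dx=%.10g dy=%.10g slt=%.10g sld=%.10g nrow=%d ncol=%d nslices=%d",
    g$pixel_size_mm[1L], g$pixel_size_mm[2L], g$slice_thickness_mm,
    g$slice_spacing_mm, g$n_rows, g$n_cols, g$n_slices), con, useBytes = TRUE)
  writeLines("case_id,source_id,frame,slice_index,surface,point_index,x_mm,y_mm",
             con, useBytes = TRUE)
  keys <- contour_keys(set)
  if (nrow(keys)) {
    keys <- keys[order(keys$frame, keys$slice_index, keys$surface), , drop = FALSE]
    for (key in keys$key) {
      ct <- set$contours[[key]]
      n <- nrow(ct$points)
      writeLines(sprintf("%s,%s,%s,%d,%s,%d,%.10g,%.10g",
                         set$case_id, set$source_id, ct$frame, ct$slice_index,
                         ct$surface, seq_len(n) - 1L,
                         ct$points[, 1L], ct$points[, 2L]), con, useBytes = TRUE)
    }
  }
  invisible(path)
}
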