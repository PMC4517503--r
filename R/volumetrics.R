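#' Slice-summation stack volume
#'
#' Simpson-style slice summation: each contoured slice contributes its 2D
#' cavity area times the inter-slice (center-to-center) distance. Missing
#' slices contribute nothing — no interpolation or partial-slice correction —
#' so omitted end slices surface as volume bias, which is exactly the
#' phenomenon the agreement statistics measure.
#'
#' @param set a [contour_set].
#' @param frame `"ED"` or `"ES"`.
#' @param surface `"endo"` or `"epi"`.
#' @param backend `"polygon"` (shoelace area of the stored polygon, default)
#'   or `"mask"` (area of the supersampled raster; uses a contour's
#'   `mask_area_mm2` attribute when present, e.g. on consensus contours).
#' @param factor supersampling factor for the mask backend.
#' @return volume in ml.
#' @export
stack_volume_ml <- function(set, frame, surface,
                            backend = c("polygon", "mask"), factor = 4L) {
  backend <- match.arg(backend)
  stopifnot(inherits(set, "contour_set"))
  keys <- contour_keys(set)
  sel <- keys[keys$frame == frame & keys$surface == surface, , drop = FALSE]
  if (!nrow(sel)) {
    stop("no contours for (", frame, ", ", surface, ") in case ",
         set$case_id, " source ", set$source_id)
  }
  areas <- vapply(sel$key, function(k) {
    ct <- set$contours[[k]]
    if (backend == "polygon") return(polygon_area_mm2(ct))
    ma <- attr(ct, "mask_area_mm2")
    if (!is.null(ma)) return(ma)
    mask_area_mm2(rasterize_contour(ct, set$geometry, factor = factor,
                                    window = window_for_contours(
                                      list(ct), set$geometry, factor)))
  }, 0)
  sum(areas) * set$geometry$slice_spacing_mm / 1000
}

#' Left-ventricular myocardial mass
#'
#' Myocardial volume (epicardial volume at ED minus EDV) converted to grams
#' at myocardial density 1.05 g/ml.
#'
#' @param epi_volume_ml epicardial stack volume at ED, ml.
#' @param edv_ml end-diastolic (endocardial) volume, ml.
#' @return mass in g.
#' @export
lv_mass_g <- function(epi_volume_ml, edv_ml) {
  if (any(epi_volume_ml < edv_ml)) {
    stop("epicardial volume smaller than EDV: endo/epi nesting violated upstream")
  }
  (epi_volume_ml - edv_ml) * 1.05
}

#' Ejection fraction
#' @param edv_ml end-diastolic volume (> 0), ml.
#' @param esv_ml end-systolic volume, ml.
#' @return `100 * (EDV - ESV) / EDV`, percent.
#' @export
ejection_fraction_pct <- function(edv_ml, esv_ml) {
  stopifnot(all(edv_ml > 0))
  100 * (edv_ml - esv_ml) / edv_ml
}

#' Select the end-systolic frame
#'
#' ES is the frame with the smallest endocardial cavity area in a
#' mid-ventricular slice; ties resolve to the earliest frame.
#'
#' @param mid_slice_areas_mm2 per-frame mid-ventricular endocardial areas;
#'   must be complete (an `NA` means the mid slice was not contoured in that
#'   frame and is an error).
#' @return 0-based frame index.
#' @export
select_es_frame <- function(mid_slice_areas_mm2) {
  stopifnot(length(mid_slice_areas_mm2) >= 2L)
  if (anyNA(mid_slice_areas_mm2)) {
    stop("mid-slice area missing in frame(s) ",
         paste(which(is.na(mid_slice_areas_mm2)) - 1L, collapse = ", "))
  }
  which.min(mid_slice_areas_mm2) - 1L
}

#' LV functional parameters from one contour set
#'
#' EDV and ESV by endocardial slice summation, LVM from the ED epicardial
#' stack (mass defined at ED), EF from EDV and ESV.
#'
#' @param set a [contour_set] holding ED endo, ED epi and ES endo contours on
#'   at least one slice each.
#' @inheritParams stack_volume_ml
#' @return object of class `lv_function`: list with `case_id`, `source_id`,
#'   `EDV_ml`, `ESV_ml`, `LVM_g`, `EF_pct`.
#' @export
compute_lv_function <- function(set, backend = c("polygon", "mask"),
                                factor = 4L) {
  backend <- match.arg(backend)
  keys <- contour_keys(set)
  need <- list(c("ED", "endo"), c("ED", "epi"), c("ES", "endo"))
  missing <- Filter(function(k) {
    !any(keys$frame == k[1L] & keys$surface == k[2L])
  }, need)
  if (length(missing)) {
    stop("case ", set$case_id, " source ", set$source_id,
         ": missing contours for ",
         paste(vapply(missing, paste, "", collapse = "/"), collapse = ", "))
  }
  edv <- stack_volume_ml(set, "ED", "endo", backend, factor)
  esv <- stack_volume_ml(set, "ES", "endo", backend, factor)
  epi <- stack_volume_ml(set, "ED", "epi", backend, factor)
  structure(
    list(case_id = set$case_id, source_id = set$source_id,
         EDV_ml = edv, ESV_ml = esv, LVM_g = lv_mass_g(epi, edv),
         EF_pct = ejection_fraction_pct(edv, esv)),
    class = "lv_function"
  )
}

#' @export
print.lv_function <- function(x, ...) {
  cat(sprintf("<lv_function> case %s / %s: EDV %.1f ml, ESV %.1f ml, LVM %.1f g, EF %.1f%%\n",
              x$case_id, x$source_id, x$EDV_ml, x$ESV_ml, x$LVM_g, x$EF_pct))
  invisible(x)
}

#' @export
as.data.frame.lv_function <- function(x, ...) {
  data.frame(case_id = x$case_id, source_id = x$source_id, EDV_ml = x$EDV_ml,
             ESV_ml = x$ESV_ml, LVM_g = x$LVM_g, EF_pct = x$EF_pct,
             stringsAsFactors = FALSE)
}
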