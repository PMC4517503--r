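# Geometric fixtures shared across tests. All coordinates in mm.

circle_points <- function(r, cx = 0, cy = 0, n = 64L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

square_points <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}

test_geometry <- function(pixel = 1.25, slt = 8, sld = slt, npix = 80L,
                          n_slices = 10L) {
  slice_geometry(pixel, slt, sld, npix, npix, n_slices)
}

# lv_mask wrapper around a raw grid, for mask-level STAPLE tests
raw_mask <- function(grid, cell = 1) {
  structure(
    list(grid = grid, row0 = 0L, col0 = 0L, factor = 1L,
         cell_dx = cell, cell_dy = cell, cell_area_mm2 = cell^2,
         frame = "ED", slice_index = 0L, surface = "endo"),
    class = "lv_mask"
  )
}

# Simulated raters corrupting a binary truth cell-wise with known
# sensitivity/specificity; returns the cells x readers decision matrix.
corrupt_decisions <- function(truth, n_readers, sens, spec) {
  n <- length(truth)
  vapply(seq_len(n_readers), function(j) {
    ifelse(truth == 1L,
           stats::rbinom(n, 1L, sens),
           stats::rbinom(n, 1L, 1 - spec))
  }, numeric(n))
}

# Stack of circular (128-gon) slices with radius given by radius_fun(z),
# z the slice-center depth; used for cylinder/hemisphere volume oracles.
stack_of_circles <- function(radius_fun, geometry, frame = "ED",
                             surface = "endo", cx = 50, cy = 50, n = 128L) {
  set <- contour_set("fix", "reader", geometry)
  for (i in seq_len(geometry$n_slices)) {
    z <- (i - 0.5) * geometry$slice_spacing_mm
    r <- radius_fun(z)
    if (is.na(r) || r <= 0) next
    set <- set_contour(set, lv_contour(circle_points(r, cx, cy, n),
                                       surface, frame, i - 1L, check = FALSE))
  }
  set
}

zero_profiles <- function(n = 7L) {
  lapply(seq_len(n), function(i) reader_profile(paste0("R", i)))
}
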