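test_that("point-to-contour distance is segment-wise and exact on fixtures", {
  sq <- lv_contour(square_points(-0.5, -0.5, 1), "endo", "ED", 0,
                   check = FALSE)
  expect_equal(as.numeric(point_to_contour_distance(c(5, 0), sq)), 4.5)
  expect_equal(as.numeric(point_to_contour_distance(c(0.5, 0), sq)), 0)
  # mid-edge query: nearest vertex is sqrt(0.5) away but the edge is 0.5
  expect_equal(as.numeric(point_to_contour_distance(c(0, 0), sq)), 0.5)
  circ <- lv_contour(circle_points(20, 0, 0, 64L), "endo", "ED", 0)
  d <- as.numeric(point_to_contour_distance(c(0, 0), circ))
  expect_gte(d, 20 * cos(pi / 64) - 1e-9)
  expect_lte(d, 20)
})

test_that("a reader identical to the consensus has zero discrepancy", {
  geom <- test_geometry()
  cons <- contour_set("c", "consensus", geom, list(
    lv_contour(circle_points(20, 50, 50), "endo", "ED", 0),
    lv_contour(circle_points(27, 50, 50), "epi", "ED", 0)))
  reader <- cons
  reader$source_id <- "R1"
  rep <- discrepancy_report(reader, cons)
  expect_length(rep$slices, 2L)
  for (s in rep$slices) {
    expect_equal(max(s$distances_mm), 0)
    expect_length(s$flagged, 0L)
    expect_equal(unname(s$summary), c(0, 0, 0))
  }
  expect_length(rep$skipped_keys, 0L)
})

test_that("a uniform 4 mm offset flags every point at the 3 mm threshold", {
  geom <- test_geometry()
  cons <- contour_set("c", "consensus", geom, list(
    lv_contour(circle_points(20, 50, 50, 128L), "endo", "ED", 0)))
  reader <- contour_set("c", "R1", geom, list(
    lv_contour(circle_points(24, 50, 50, 128L), "endo", "ED", 0)))
  rep <- discrepancy_report(reader, cons, threshold_mm = 3)
  s <- rep$slices[[1L]]
  expect_length(s$flagged, 128L)
  expect_lt(abs(s$summary[["mean"]] - 4), 0.05)
  # flag count is monotone non-increasing in the threshold
  counts <- vapply(c(1, 3, 4.2), function(thr) {
    length(discrepancy_report(reader, cons,
                              threshold_mm = thr)$slices[[1L]]$flagged)
  }, 0)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[3], 0)
})

test_that("the cross-reader band spans the reader radii", {
  geom <- test_geometry()
  radii <- seq(18, 22, length.out = 7)
  readers <- lapply(seq_along(radii), function(i) {
    contour_set("c", paste0("R", i), geom, list(
      lv_contour(circle_points(radii[i], 50, 50, 128L), "endo", "ED", 0)))
  })
  cons <- contour_set("c", "consensus", geom, list(
    lv_contour(circle_points(20, 50, 50, 128L), "endo", "ED", 0)))
  rep <- discrepancy_report(readers[[1L]], cons, all_readers = readers)
  band <- rep$slices[[1L]]$band
  expect_true(all(abs(band$band_min_mm - 18) < 0.1))
  expect_true(all(abs(band$band_max_mm - 22) < 0.1))
})

test_that("distances are invariant under rigid motion of both contours", {
  geom <- slice_geometry(1, 8, 8, 300, 300, 1)
  rot <- function(pts, a, t) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    sweep(pts %*% t(R), 2, t, `+`)
  }
  base_r <- circle_points(21, 0, 0, 64L)
  base_c <- circle_points(19.5, 1, 0, 64L)
  d0 <- point_to_contour_distance(base_r, lv_contour(base_c, "endo", "ED", 0))
  a <- 0.7; tr <- c(140, 150)
  d1 <- point_to_contour_distance(
    rot(base_r, a, tr), lv_contour(rot(base_c, a, tr), "endo", "ED", 0))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("keys without consensus are skipped and listed", {
  geom <- test_geometry()
  reader <- contour_set("c", "R1", geom, list(
    lv_contour(circle_points(20, 50, 50), "endo", "ED", 0),
    lv_contour(circle_points(20, 50, 50), "endo", "ED", 1)))
  cons <- contour_set("c", "consensus", geom, list(
    lv_contour(circle_points(20, 50, 50), "endo", "ED", 0)))
  rep <- discrepancy_report(reader, cons)
  expect_length(rep$slices, 1L)
  expect_equal(rep$skipped_keys, "ED|1|endo")
})

test_that("summary statistics are internally consistent", {
  geom <- test_geometry()
  cons <- contour_set("c", "consensus", geom, list(
    lv_contour(circle_points(20, 50, 50), "endo", "ED", 0)))
  reader <- contour_set("c", "R1", geom, list(
    lv_contour(circle_points(21.5, 49, 50, 48L), "endo", "ED", 0)))
  s <- discrepancy_report(reader, cons)$slices[[1L]]
  expect_gte(s$summary[["max"]], s$summary[["mean"]])
  expect_gte(s$summary[["mean"]], 0)
  expect_gt(s$summary[["sd"]], 0)
})

test_that("rendered reports emit a figure and a CSV matching the data", {
  geom <- test_geometry()
  cons <- contour_set("c", "consensus", geom, list(
    lv_contour(circle_points(20, 50, 50), "endo", "ED", 0)))
  reader <- contour_set("c", "R1", geom, list(
    lv_contour(circle_points(24, 50, 50), "endo", "ED", 0)))
  rep <- discrepancy_report(reader, cons, all_readers = list(reader))
  out <- file.path(tempdir(), "rep_one")
  paths <- render_report(rep, out, reader, cons)
  expect_true(file.exists(paths$pdf))
  expect_true(file.exists(paths$csv))
  csv <- read.csv(paths$csv)
  expect_equal(nrow(csv), 64L)
  expect_equal(csv$distance_mm, unname(rep$slices[[1L]]$distances_mm),
               tolerance = 1e-9)
  expect_true(all(csv$flagged))
  # empty report: valid CSV, no figure
  empty <- discrepancy_report(contour_set("c", "R2", geom),
                              contour_set("c", "consensus", geom))
  paths2 <- render_report(empty, file.path(tempdir(), "rep_empty"),
                          contour_set("c", "R2", geom),
                          contour_set("c", "consensus", geom))
  expect_null(paths2$pdf)
  expect_true(file.exists(paths2$csv))
  expect_equal(nrow(read.csv(paths2$csv)), 0L)
  expect_error(render_report(rep, "/nonexistent-dir/zzz/rep", reader, cons),
               "unwritable")
})
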