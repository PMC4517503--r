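test_that("shoelace areas match closed forms", {
  expect_equal(polygon_area_mm2(square_points(0, 0, 1)), 1.0)
  expect_equal(polygon_area_mm2(cbind(c(0, 4, 0), c(0, 0, 3))), 6.0)
  # regular 64-gon, radius 10: area = n r^2 sin(2 pi / n) / 2
  poly <- circle_points(10, n = 64L)
  exact <- 0.5 * 64 * 100 * sin(2 * pi / 64)
  expect_equal(polygon_area_mm2(poly), exact, tolerance = 1e-12)
  expect_lt(abs(polygon_area_mm2(poly) - pi * 100) / (pi * 100), 0.002)
})

test_that("clockwise input is normalized to counter-clockwise, area preserved", {
  ccw <- square_points(2, 2, 3)
  cw <- ccw[rev(seq_len(nrow(ccw))), ]
  expect_lt(lvconsensus:::signed_area(cw), 0)
  ct <- lv_contour(cw, "endo", "ED", 0)
  expect_gt(lvconsensus:::signed_area(ct$points), 0)
  expect_equal(polygon_area_mm2(ct), 9.0)
})

test_that("contour validation rejects degenerate and crossing polygons", {
  expect_error(lv_contour(cbind(c(0, 1), c(0, 1)), "endo", "ED", 3),
               "3 vertices")
  # asymmetric bow-tie: nonzero shoelace area but crossing diagonals
  bow <- cbind(c(0, 4, 0, 2), c(0, 0, 3, 3))
  expect_error(lv_contour(bow, "epi", "ES", 5), "self-intersecting")
  expect_error(lv_contour(cbind(c(0, 1, 2), c(0, 0, 0)), "endo", "ED", 0),
               "zero area")
})

test_that("contour sets enforce bounds and endo/epi nesting", {
  geom <- test_geometry()
  set <- contour_set("c1", "R1", geom)
  expect_error(set_contour(set, lv_contour(square_points(95, 95, 20),
                                           "endo", "ED", 0)),
               "outside image bounds")
  set <- set_contour(set, lv_contour(circle_points(20, 50, 50), "epi", "ED", 2))
  expect_error(set_contour(set, lv_contour(circle_points(25, 50, 50),
                                           "endo", "ED", 2)),
               "not smaller")
  set <- set_contour(set, lv_contour(circle_points(14, 50, 50), "endo", "ED", 2))
  expect_equal(nrow(contour_keys(set)), 2L)
})

test_that("exchange files round-trip exactly", {
  geom <- test_geometry()
  set <- contour_set("caseA", "R3", geom, list(
    lv_contour(square_points(30, 30, 10), "endo", "ED", 0),
    lv_contour(circle_points(22, 50, 50, 48), "epi", "ED", 1),
    lv_contour(circle_points(12, 50, 50, 48), "endo", "ES", 1)
  ))
  path <- tempfile(fileext = ".csv")
  write_contour_set(set, path)
  back <- read_contour_set(path)
  expect_equal(back$case_id, "caseA")
  expect_equal(back$source_id, "R3")
  expect_equal(back$geometry, set$geometry)
  expect_equal(names(back$contours), names(set$contours))
  for (k in names(set$contours)) {
    expect_equal(back$contours[[k]]$points, set$contours[[k]]$points,
                 tolerance = 1e-9)
  }
  # a single-square file read directly holds exactly one 4-point contour
  one <- contour_set("caseB", "R1", geom,
                     list(lv_contour(square_points(10, 10, 5), "endo", "ED", 0)))
  p2 <- tempfile(fileext = ".csv")
  write_contour_set(one, p2)
  r2 <- read_contour_set(p2)
  expect_length(r2$contours, 1L)
  expect_equal(nrow(r2$contours[[1L]]$points), 4L)
})

test_that("files listing clockwise points load counter-clockwise with same area", {
  path <- tempfile(fileext = ".csv")
  cw <- square_points(10, 10, 4)[4:1, ]
  writeLines(c(
    "# geometry: dx=1 dy=1 slt=8 sld=8 nrow=40 ncol=40 nslices=3",
    "case_id,source_id,frame,slice_index,surface,point_index,x_mm,y_mm",
    sprintf("cX,R9,ED,1,endo,%d,%g,%g", 0:3, cw[, 1], cw[, 2])
  ), path)
  set <- read_contour_set(path)
  ct <- get_contour(set, "ED", 1, "endo")
  expect_gt(lvconsensus:::signed_area(ct$points), 0)
  expect_equal(polygon_area_mm2(ct), 16.0)
})

test_that("malformed exchange files fail with located errors", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("case_id,source_id", "a,b"), p)
  expect_error(read_contour_set(p), "geometry")
  writeLines(c("# geometry: dx=1 dy=1 slt=8 sld=8 nrow=40 ncol=40 nslices=3",
               "x,y", "1,2"), p)
  expect_error(read_contour_set(p), "expected header")
  writeLines(c("# geometry: dx=1 dy=1 slt=8 sld=8 nrow=40 ncol=40 nslices=3",
               "case_id,source_id,frame,slice_index,surface,point_index,x_mm,y_mm",
               "c1,R1,ED,0,endo,0,1,1", "c1,R1,ED,0,endo,1,2,1"), p)
  expect_error(read_contour_set(p), "3 vertices|slice 0")
})

test_that("rasterization covers an axis-aligned square exactly", {
  geom <- slice_geometry(1, 8, 8, 20, 20, 1)
  ct <- lv_contour(square_points(5, 5, 10), "endo", "ED", 0)
  m <- rasterize_contour(ct, geom, factor = 4L)
  expect_equal(mask_area_mm2(m), 100.0)
  # half-open convention at integer cell centers: [0.5, 3.5) spans 3 cells
  g1 <- slice_geometry(1, 8, 8, 10, 10, 1)
  sq <- lv_contour(square_points(0.5, 0.5, 3), "endo", "ED", 0)
  m1 <- rasterize_contour(sq, g1, factor = 1L)
  expect_equal(sum(m1$grid), 9)
})

test_that("rasterized circle area converges to the analytic area", {
  geom <- test_geometry(pixel = 1.25)
  ct <- lv_contour(circle_points(20, 50, 50, 256L), "endo", "ED", 0)
  a4 <- mask_area_mm2(rasterize_contour(ct, geom, factor = 4L))
  expect_lt(abs(a4 - pi * 400) / (pi * 400), 0.005)
  a1 <- mask_area_mm2(rasterize_contour(ct, geom, factor = 1L))
  poly <- polygon_area_mm2(ct)
  expect_lt(abs(a4 - poly), abs(a1 - poly))
})

test_that("rasterize rejects out-of-bounds contours", {
  geom <- slice_geometry(1, 8, 8, 20, 20, 1)
  ct <- lv_contour(square_points(15, 15, 10), "endo", "ED", 0, check = FALSE)
  expect_error(rasterize_contour(ct, geom), "outside image bounds")
})

test_that("extract_contour inverts rasterize up to discretization", {
  geom <- test_geometry(pixel = 1.25)
  for (r in c(10, 20, 28)) {
    ct <- lv_contour(circle_points(r, 50, 50, 128L), "endo", "ED", 0)
    m <- rasterize_contour(ct, geom, factor = 4L)
    back <- extract_contour(m)
    expect_lt(abs(polygon_area_mm2(back) - polygon_area_mm2(ct)) /
                polygon_area_mm2(ct), 0.02)
  }
})

test_that("extract_contour handles empty maps and keeps the largest blob", {
  geom <- slice_geometry(1, 8, 8, 30, 30, 1)
  expect_null(extract_contour(matrix(0, 30, 30), geom, factor = 1L))
  grid <- matrix(0, 30, 30)
  grid[5:14, 5:14] <- 1   # 100-cell blob
  grid[25, 25:27] <- 1    # 3-cell blob
  ct <- extract_contour(grid, geom, factor = 1L)
  area <- polygon_area_mm2(ct)
  expect_gt(area, 50)
  expect_lt(area, 150)
  expect_true(all(ct$points[, 1L] < 20))  # big blob only
  expect_true(all(ct$points[, 2L] < 20))
})
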