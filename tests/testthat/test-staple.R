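test_that("majority vote counts marks per cell", {
  grids <- lapply(1:7, function(i) {
    g <- matrix(0L, 4, 4)
    if (i <= 4) g[2, 2] <- 1L
    g[3, 3] <- 1L
    g
  })
  vote <- majority_vote(lapply(grids, raw_mask))
  expect_equal(vote$grid[2, 2], 4 / 7)
  expect_equal(vote$grid[3, 3], 1)
  expect_equal(vote$grid[1, 1], 0)
  same <- lapply(1:7, function(i) raw_mask(grids[[1L]]))
  expect_equal(majority_vote(same)$grid, grids[[1L]] + 0)
  bad <- raw_mask(matrix(0L, 3, 3))
  expect_error(majority_vote(list(raw_mask(grids[[1]]), bad)), "identical")
})

test_that("thresholded vote equals cell-wise majority for odd reader counts", {
  # every possible 7-reader pattern for one cell
  patterns <- as.matrix(expand.grid(rep(list(0:1), 7)))
  masks <- lapply(1:7, function(j) raw_mask(matrix(patterns[, j], 16, 8)))
  vote <- majority_vote(masks)$grid
  majority <- matrix(rowSums(patterns) >= 4, 16, 8)
  expect_equal(vote >= 0.5, majority)
})

test_that("expectation step matches the closed-form consensus probability", {
  # all 7 readers mark the cell, p = q = 0.9, prior 0.5
  D <- matrix(1, 1, 7)
  got <- staple_e_step(D, rep(0.9, 7), rep(0.9, 7), 0.5)
  expect_equal(got$W, 0.9^7 / (0.9^7 + 0.1^7), tolerance = 1e-12)
  # uninformative readers leave the prior untouched
  D2 <- matrix(c(1, 0, 1, 0, 1, 0), 2, 3)
  got2 <- staple_e_step(D2, rep(0.5, 3), rep(0.5, 3), 0.3)
  expect_equal(got2$W, rep(0.3, 2), tolerance = 1e-12)
  # nobody marks the cell, symmetric rates: posterior drops below the prior
  D3 <- matrix(0, 1, 5)
  got3 <- staple_e_step(D3, rep(0.8, 5), rep(0.8, 5), 0.4)
  expect_lt(got3$W, 0.4)
})

test_that("maximization step is the weighted proportion estimator", {
  W <- c(1, 1, 0, 0)
  D <- cbind(c(1, 1, 0, 0), c(1, 0, 0, 0))
  mm <- staple_m_step(D, W)
  expect_equal(mm$p, c(1, 0.5))
  expect_equal(mm$q, c(1, 1))
  # independent two-loop summation oracle on a random instance
  set.seed(42)
  D2 <- matrix(rbinom(200, 1, 0.4), 50, 4)
  W2 <- runif(50)
  mm2 <- staple_m_step(D2, W2)
  p_ref <- q_ref <- numeric(4)
  for (j in 1:4) {
    num_p <- num_q <- 0
    for (i in 1:50) {
      num_p <- num_p + W2[i] * D2[i, j]
      num_q <- num_q + (1 - W2[i]) * (1 - D2[i, j])
    }
    p_ref[j] <- num_p / sum(W2)
    q_ref[j] <- num_q / sum(1 - W2)
  }
  expect_equal(mm2$p, p_ref, tolerance = 1e-12)
  expect_equal(mm2$q, q_ref, tolerance = 1e-12)
})

test_that("identical readers produce a degenerate perfect fusion", {
  geom <- test_geometry()
  ct <- lv_contour(circle_points(18, 50, 50), "endo", "ED", 1)
  win <- lvconsensus:::window_for_contours(list(ct), geom, 4L, 7)
  masks <- lapply(1:7, function(i) rasterize_contour(ct, geom, 4L, win))
  res <- staple_fuse(masks)
  expect_equal(unname(res$p), rep(1, 7))
  expect_equal(unname(res$q), rep(1, 7))
  expect_equal(res$W$grid >= 0.5, masks[[1L]]$grid == 1)
  expect_true(all(diff(res$trace) >= -1e-9))
})

test_that("EM log-likelihood is non-decreasing and the fixed point is stable", {
  set.seed(7)
  for (rep in 1:5) {
    truth <- rbinom(800, 1, 0.45)
    D <- corrupt_decisions(truth, 5, sens = runif(1, 0.7, 0.95),
                           spec = runif(1, 0.7, 0.95))
    fit <- staple_fuse_matrix(D)
    expect_true(all(diff(fit$trace) >= -1e-9))
    expect_true(fit$converged)
    # one more M/E cycle barely moves the converged map
    mm <- staple_m_step(D, fit$W)
    ee <- staple_e_step(D, mm$p, mm$q, fit$prior)
    expect_lt(mean(abs(ee$W - fit$W)), staple_params()$convergence_tol)
  }
})

test_that("reader permutation permutes (p, q) and leaves the consensus alone", {
  set.seed(11)
  truth <- rbinom(600, 1, 0.4)
  D <- corrupt_decisions(truth, 6, 0.9, 0.85)
  perm <- c(4, 1, 6, 2, 5, 3)
  f1 <- staple_fuse_matrix(D)
  f2 <- staple_fuse_matrix(D[, perm])
  expect_equal(unname(f2$p), unname(f1$p[perm]), tolerance = 1e-9)
  expect_equal(unname(f2$q), unname(f1$q[perm]), tolerance = 1e-9)
  expect_equal(f2$W, f1$W, tolerance = 1e-9)
})

test_that("unequal reader reliability separates STAPLE from majority voting", {
  set.seed(3)
  truth <- matrix(0L, 60, 60)
  truth[16:45, 16:45] <- 1L
  tv <- as.vector(truth)
  D <- cbind(corrupt_decisions(tv, 3, 0.99, 0.99),
             corrupt_decisions(tv, 4, 0.70, 0.70))
  fit <- staple_fuse_matrix(D)
  staple_lab <- fit$W >= 0.5
  vote_lab <- rowMeans(D) >= 0.5
  expect_gt(sum(staple_lab != vote_lab), 0)
  expect_lt(sum(staple_lab != tv), sum(vote_lab != tv))
  # the unreliable readers are identified as such
  expect_gt(min(fit$p[1:3]), max(fit$p[4:7]))
})

test_that("six consistent readers outvote one grossly offset reader", {
  geom <- test_geometry()
  ct <- lv_contour(circle_points(20, 48, 50), "endo", "ED", 1)
  outlier <- lv_contour(circle_points(20, 63, 50), "endo", "ED", 1)
  win <- lvconsensus:::window_for_contours(list(ct, outlier), geom, 4L, 7)
  masks <- c(lapply(1:6, function(i) rasterize_contour(ct, geom, 4L, win)),
             list(rasterize_contour(outlier, geom, 4L, win)))
  res <- staple_fuse(masks)
  expect_equal(res$W$grid >= 0.5, masks[[1L]]$grid == 1)
  expect_equal(which.min(res$p), 7L)
  expect_lt(res$p[7], 0.7)
  expect_gt(min(res$p[1:6]), 0.99)
})

test_that("the most-readers rule gates slice consensus", {
  geom <- test_geometry()
  cts <- lapply(1:3, function(i) {
    lv_contour(circle_points(20 + 0.2 * i, 50, 50), "endo", "ED", 2)
  })
  expect_null(consensus_for_slice(cts, geom))
  cts4 <- lapply(1:4, function(i) lv_contour(circle_points(20, 50, 50),
                                             "endo", "ED", 2))
  fused <- consensus_for_slice(cts4, geom)
  expect_false(is.null(fused$contour))
  expect_lt(abs(polygon_area_mm2(fused$contour) -
                  polygon_area_mm2(cts4[[1L]])) /
              polygon_area_mm2(cts4[[1L]]), 0.02)
})

test_that("symmetric reader spread fuses to the central contour", {
  geom <- test_geometry()
  radii <- seq(18, 22, length.out = 7)
  cts <- lapply(radii, function(r) lv_contour(circle_points(r, 50, 50, 128L),
                                              "endo", "ED", 3))
  fused <- consensus_for_slice(cts, geom)
  r_hat <- sqrt(polygon_area_mm2(fused$contour) / pi)
  expect_lt(abs(r_hat - 20), 0.5)
})

test_that("consensus_contour_set fuses per key and lists skipped slices", {
  ph <- generate_phantom("healthy", seed = 21)
  rsets <- lapply(zero_profiles(5), function(p) simulate_reader(ph, p, seed = 2))
  names(rsets) <- paste0("R", 1:5)
  # leave only 3 readers on one slice
  key <- lvconsensus:::contour_key("ES", 0, "endo")
  for (id in c("R1", "R2")) rsets[[id]]$contours[[key]] <- NULL
  out <- consensus_contour_set(rsets, min_readers = 4L)
  expect_equal(nrow(out$skipped), 1L)
  expect_equal(out$skipped$frame, "ES")
  expect_equal(out$skipped$slice_index, 0L)
  expect_equal(out$skipped$n_readers, 3L)
  expect_null(get_contour(out$consensus, "ES", 0, "endo"))
  n_keys <- nrow(contour_keys(rsets[[3L]]))
  expect_equal(nrow(out$diagnostics), n_keys - 1L)
  expect_true(all(out$diagnostics$converged))
})
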