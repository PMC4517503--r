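#' STAPLE fusion parameters
#'
#' Controls for the expectation-maximization label fusion. The foreground
#' prior is a scalar, fixed at the mean of the initial voting map over the
#' region of interest (`prior_mode = "voting_mean"`) or at a user value. EM
#' runs only inside the ROI — the union of the reader masks dilated by
#' `roi_margin_mm` — because an unbounded background drives every specificity
#' to 1 and washes out the reader weighting; cells outside the ROI get
#' consensus probability 0.
#'
#' @param prior_mode `"voting_mean"` or a fixed scalar in (0, 1).
#' @param convergence_tol EM stops when the mean absolute change in the
#'   consensus probability map drops below this (default 1e-6).
#' @param max_iter maximum EM iterations (default 100).
#' @param roi_margin_mm dilation margin around the union of reader masks
#'   defining the computation region (default 5 mm).
#' @return an object of class `staple_params`.
#' @export
staple_params <- function(prior_mode = "voting_mean", convergence_tol = 1e-6,
                          max_iter = 100L, roi_margin_mm = 5) {
  if (is.numeric(prior_mode)) {
    stopifnot(prior_mode > 0, prior_mode < 1)
  } else {
    stopifnot(identical(prior_mode, "voting_mean"))
  }
  stopifnot(convergence_tol > 0, max_iter >= 1, roi_margin_mm >= 0)
  structure(
    list(prior_mode = prior_mode, convergence_tol = convergence_tol,
         max_iter = as.integer(max_iter), roi_margin_mm = roi_margin_mm),
    class = "staple_params"
  )
}

STAPLE_EPS <- 1e-6

#' Majority-vote probability map
#'
#' Per-cell fraction of readers marking the cell foreground; the voting
#' baseline and the EM initializer.
#'
#' @param masks list of `lv_mask` objects on identical windows.
#' @return an `lv_mask`-like object whose `grid` holds vote fractions.
#' @export
majority_vote <- function(masks) {
  stopifnot(length(masks) >= 1L)
  ref <- masks[[1L]]
  for (m in masks[-1L]) {
    if (!identical(dim(m$grid), dim(ref$grid)) || m$row0 != ref$row0 ||
        m$col0 != ref$col0 || m$factor != ref$factor) {
      stop("majority_vote: masks are not on identical grids")
    }
  }
  vote <- Reduce(`+`, lapply(masks, `[[`, "grid")) / length(masks)
  out <- ref
  out$grid <- vote
  class(out) <- c("lv_probmap", "lv_mask")
  out
}

#' STAPLE expectation step
#'
#' Given reader decisions and current sensitivities/specificities, computes
#' the per-cell consensus probability
#' \deqn{W_i = \frac{a_i}{a_i + b_i}, \quad
#'   a_i = \pi \prod_j p_j^{D_{ij}} (1-p_j)^{1-D_{ij}}, \quad
#'   b_i = (1-\pi) \prod_j (1-q_j)^{D_{ij}} q_j^{1-D_{ij}}}
#' with products accumulated in log space. Degenerate rates are clamped to
#' \\[1e-6, 1 - 1e-6\\].
#'
#' @param D integer/numeric matrix of reader decisions, cells x readers.
#' @param p,q per-reader sensitivity and specificity vectors.
#' @param prior scalar foreground prior in (0, 1).
#' @return list with `W` (per-cell consensus probability) and `loglik`
#'   (the observed-data log-likelihood at (p, q, prior)).
#' @export
staple_e_step <- function(D, p, q, prior) {
  stopifnot(is.matrix(D), length(p) == ncol(D), length(q) == ncol(D),
            prior > 0, prior < 1)
  p <- pmin(pmax(p, STAPLE_EPS), 1 - STAPLE_EPS)
  q <- pmin(pmax(q, STAPLE_EPS), 1 - STAPLE_EPS)
  # one GEMM for both log-products over readers
  coef <- cbind(log(p) - log1p(-p), log1p(-q) - log(q))
  lp <- D %*% coef
  loga <- log(prior) + sum(log1p(-p)) + lp[, 1L]
  logb <- log1p(-prior) + sum(log(q)) + lp[, 2L]
  d <- logb - loga
  W <- 1 / (1 + exp(d))
  # log(a + b) = max + log1p(exp(-|d|))
  lse <- pmax(loga, logb) + log1p(exp(-abs(d)))
  list(W = W, loglik = sum(lse))
}

#' STAPLE maximization step
#'
#' Updates each reader's sensitivity as the consensus-weighted proportion of
#' consensus-foreground cells the reader marked, and specificity as the
#' weighted proportion of consensus-background cells the reader left
#' unmarked:
#' \deqn{p_j = \frac{\sum_i W_i D_{ij}}{\sum_i W_i}, \qquad
#'   q_j = \frac{\sum_i (1-W_i)(1-D_{ij})}{\sum_i (1-W_i)}}
#'
#' @param D decision matrix, cells x readers.
#' @param W per-cell consensus probability.
#' @return list with vectors `p` and `q`. A zero denominator (all-foreground
#'   or all-background consensus) yields 1 with a warning.
#' @export
staple_m_step <- function(D, W) {
  stopifnot(is.matrix(D), length(W) == nrow(D), all(W >= 0), all(W <= 1))
  sw <- sum(W)
  sv <- sum(1 - W)
  if (sw <= 0 || sv <= 0) {
    warning("degenerate consensus map: all-", if (sw <= 0) "background" else
              "foreground", "; affected rates set to 1")
  }
  dw <- as.vector(crossprod(D, W))
  # sum_i (1 - D_ij)(1 - W_i) = N - colSums(D) - sum(W) + (D^T W)_j
  p <- if (sw > 0) dw / sw else rep(1, ncol(D))
  q <- if (sv > 0) (nrow(D) - colSums(D) - sw + dw) / sv else rep(1, ncol(D))
  list(p = p, q = q)
}

#' STAPLE fusion of a decision matrix
#'
#' Core EM loop on a raw decision matrix (cells x readers): initialize the
#' consensus probability at the majority vote, fix the prior, then alternate
#' maximization and expectation steps until the mean absolute change in the
#' consensus map falls below `convergence_tol` or `max_iter` is reached.
#'
#' @param D decision matrix, cells x readers (columns may be named with
#'   reader ids).
#' @param params a [staple_params].
#' @return list of class `staple_fit`: `W` (vector), `p`, `q`, `prior`,
#'   `n_iter`, `converged`, `trace` (per-iteration log-likelihood,
#'   non-decreasing up to numerical tolerance).
#' @export
staple_fuse_matrix <- function(D, params = staple_params()) {
  stopifnot(is.matrix(D), ncol(D) >= 2L)
  storage.mode(D) <- "double"
  W <- rowMeans(D)
  prior <- if (is.numeric(params$prior_mode)) params$prior_mode else mean(W)
  prior <- min(max(prior, STAPLE_EPS), 1 - STAPLE_EPS)
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  p <- q <- rep(NA_real_, ncol(D))
  for (it in seq_len(params$max_iter)) {
    mm <- staple_m_step(D, W)
    p <- mm$p; q <- mm$q
    ee <- staple_e_step(D, p, q, prior)
    trace <- c(trace, ee$loglik)
    delta <- mean(abs(ee$W - W))
    W <- ee$W
    n_iter <- it
    if (delta < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(W = W, p = stats::setNames(p, colnames(D)),
         q = stats::setNames(q, colnames(D)), prior = prior,
         n_iter = n_iter, converged = converged, trace = trace),
    class = "staple_fit"
  )
}

#' STAPLE fusion of reader masks
#'
#' Fuses supersampled reader masks for one (frame, slice, surface) into a
#' consensus probability map with per-reader sensitivity/specificity. The EM
#' runs on the region of interest (union of reader masks dilated by
#' `roi_margin_mm`); cells outside the ROI are assigned probability 0.
#'
#' @param masks list of `lv_mask` objects on identical windows, optionally
#'   named by reader id.
#' @param params a [staple_params].
#' @return an object of class `staple_result`: `W` (probability map as an
#'   `lv_mask`-like object), `p`, `q`, `prior`, `n_iter`, `converged`,
#'   `trace`, `roi_n_cells`, and `consensus_contour` (`NULL` until extracted).
#' @export
staple_fuse <- function(masks, params = staple_params()) {
  stopifnot(length(masks) >= 2L)
  ref <- majority_vote(masks)  # also validates grid identity
  rx <- as.integer(ceiling(params$roi_margin_mm / ref$cell_dx))
  ry <- as.integer(ceiling(params$roi_margin_mm / ref$cell_dy))
  roi <- dilate_binary((ref$grid > 0) * 1L, rx, ry) > 0
  D <- vapply(masks, function(m) as.double(m$grid[roi]),
              numeric(sum(roi)))
  colnames(D) <- names(masks)
  fit <- staple_fuse_matrix(D, params)
  Wgrid <- matrix(0, nrow(ref$grid), ncol(ref$grid))
  Wgrid[roi] <- fit$W
  Wmap <- ref
  Wmap$grid <- Wgrid
  structure(
    list(W = Wmap, p = fit$p, q = fit$q, prior = fit$prior,
         n_iter = fit$n_iter, converged = fit$converged, trace = fit$trace,
         roi_n_cells = sum(roi), consensus_contour = NULL),
    class = "staple_result"
  )
}

#' @export
print.staple_result <- function(x, ...) {
  cat(sprintf("<staple_result> %d ROI cells, %d readers, %d iterations (%s)\n",
              x$roi_n_cells, length(x$p), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat("  p:", paste(sprintf("%.3f", x$p), collapse = " "), "\n")
  cat("  q:", paste(sprintf("%.3f", x$q), collapse = " "), "\n")
  invisible(x)
}

#' Consensus contour for one slice key
#'
#' Applies the most-readers rule: a consensus is generated only when at least
#' `min_readers` readers (default 4) contoured the (frame, slice, surface);
#' otherwise an explicit "no consensus" result is returned. When enough
#' readers are present, their contours are rasterized on a common window,
#' fused by STAPLE, and the consensus contour is traced from the probability
#' map at threshold 0.5.
#'
#' @param contours list of [lv_contour]s from different readers, all on the
#'   same (frame, slice, surface); names are reader ids.
#' @param geometry the case's [slice_geometry].
#' @param params a [staple_params].
#' @param min_readers minimum number of contouring readers (default 4).
#' @param factor supersampling factor (default 4).
#' @return `NULL` when fewer than `min_readers` contours are supplied;
#'   otherwise a list with `contour` (the consensus [lv_contour], carrying a
#'   `mask_area_mm2` attribute = thresholded-map area) and `staple` (the
#'   [staple_fuse()] result with `consensus_contour` filled in).
#' @export
consensus_for_slice <- function(contours, geometry, params = staple_params(),
                                min_readers = 4L, factor = 4L) {
  if (length(contours) < min_readers) return(NULL)
  key <- contours[[1L]]
  same <- vapply(contours, function(ct) {
    ct$frame == key$frame && ct$slice_index == key$slice_index &&
      ct$surface == key$surface
  }, logical(1L))
  if (!all(same)) stop("consensus_for_slice: contours span multiple slice keys")
  win <- window_for_contours(contours, geometry, factor,
                             margin_mm = params$roi_margin_mm + 2)
  masks <- lapply(contours, rasterize_contour, geometry = geometry,
                  factor = factor, window = win)
  res <- staple_fuse(masks, params)
  ct <- extract_contour(res$W, threshold = 0.5, frame = key$frame,
                        slice_index = key$slice_index, surface = key$surface)
  if (!is.null(ct)) {
    attr(ct, "mask_area_mm2") <- sum(res$W$grid >= 0.5) * res$W$cell_area_mm2
  }
  res$consensus_contour <- ct
  list(contour = ct, staple = res)
}

#' Fuse all slices of a case into a consensus contour set
#'
#' Runs [consensus_for_slice()] over every (frame, slice, surface) key that
#' any reader contoured, applying the `min_readers` rule per key, and
#' assembles the consensus [contour_set] plus per-slice fusion diagnostics.
#'
#' @param reader_sets list of [contour_set]s for one case, one per reader.
#' @param params a [staple_params].
#' @param min_readers minimum readers per slice key (default 4).
#' @param factor supersampling factor (default 4).
#' @return list with `consensus` (a [contour_set], `source_id = "consensus"`),
#'   `diagnostics` (data.frame: case, frame, slice, surface, n_readers,
#'   n_iter, converged, prior, and `p_<reader>` / `q_<reader>` columns), and
#'   `skipped` (data.frame of keys with fewer than `min_readers` readers).
#' @export
consensus_contour_set <- function(reader_sets, params = staple_params(),
                                  min_readers = 4L, factor = 4L) {
  stopifnot(length(reader_sets) >= 2L)
  case_id <- reader_sets[[1L]]$case_id
  stopifnot(all(vapply(reader_sets, `[[`, "", "case_id") == case_id))
  geometry <- reader_sets[[1L]]$geometry
  reader_ids <- vapply(reader_sets, `[[`, "", "source_id")
  names(reader_sets) <- reader_ids
  all_keys <- unique(do.call(rbind, lapply(reader_sets, contour_keys)))
  all_keys <- all_keys[order(all_keys$frame, all_keys$slice_index,
                             all_keys$surface), , drop = FALSE]
  consensus <- contour_set(case_id, "consensus", geometry)
  diag_rows <- list()
  skipped <- list()
  for (r in seq_len(nrow(all_keys))) {
    k <- all_keys[r, ]
    cts <- list()
    for (id in reader_ids) {
      ct <- get_contour(reader_sets[[id]], k$frame, k$slice_index, k$surface)
      if (!is.null(ct)) cts[[id]] <- ct
    }
    fused <- consensus_for_slice(cts, geometry, params, min_readers, factor)
    if (is.null(fused)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        case_id = case_id, frame = k$frame, slice_index = k$slice_index,
        surface = k$surface, n_readers = length(cts), stringsAsFactors = FALSE)
      next
    }
    if (!is.null(fused$contour)) consensus <- set_contour(consensus, fused$contour)
    row <- data.frame(case_id = case_id, frame = k$frame,
                      slice_index = k$slice_index, surface = k$surface,
                      n_readers = length(cts), n_iter = fused$staple$n_iter,
                      converged = fused$staple$converged,
                      prior = fused$staple$prior, stringsAsFactors = FALSE)
    for (id in reader_ids) {
      row[[paste0("p_", id)]] <- unname(fused$staple$p[id])
      row[[paste0("q_", id)]] <- unname(fused$staple$q[id])
    }
    diag_rows[[length(diag_rows) + 1L]] <- row
  }
  list(
    consensus = consensus,
    diagnostics = if (length(diag_rows)) do.call(rbind, diag_rows) else NULL,
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(case_id = character(), frame = character(),
                 slice_index = integer(), surface = character(),
                 n_readers = integer(), stringsAsFactors = FALSE)
  )
}
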