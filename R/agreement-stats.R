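#' Reader x case matrix of one functional index
#'
#' Holds the values F_i(k) of one LV functional index (EDV, ESV, LVM or EF)
#' for every reader i and case k, plus the consensus row F_C(k). Complete
#' coverage is required: every reader must have analyzed every case.
#'
#' @param values numeric R x N matrix (readers x cases), with dimnames taken
#'   as reader/case labels when present.
#' @param consensus numeric length-N consensus values.
#' @param index index name, e.g. `"EDV_ml"`.
#' @return an object of class `function_matrix`.
#' @export
function_matrix <- function(values, consensus, index = "F") {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 2L, ncol(values) >= 1L,
            length(consensus) == ncol(values))
  if (anyNA(values) || anyNA(consensus)) {
    stop("function_matrix requires complete reader x case coverage (index ",
         index, ")")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("R", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("case", seq_len(ncol(values)))
  }
  structure(
    list(values = values, consensus = as.numeric(consensus), index = index,
         readers = rownames(values), cases = colnames(values)),
    class = "function_matrix"
  )
}

#' Inter-reader RMSE for one reader
#'
#' Agreement between reader i and all other readers:
#' \deqn{E_i = \sqrt{\sum_{j \ne i} \sum_k \frac{(F_i(k) - F_j(k))^2}{N (R - 1)}}}
#'
#' @param M a [function_matrix].
#' @param i reader index or label.
#' @return E_i, in the index's units.
#' @export
reader_rmse <- function(M, i) {
  stopifnot(inherits(M, "function_matrix"))
  V <- M$values
  if (is.character(i)) i <- match(i, M$readers)
  stopifnot(!is.na(i), i >= 1, i <= nrow(V))
  if (nrow(V) < 2L) stop("reader_rmse needs at least 2 readers")
  d2 <- sweep(V[-i, , drop = FALSE], 2L, V[i, ])^2
  sqrt(sum(d2) / (ncol(V) * (nrow(V) - 1L)))
}

#' Consensus RMSE
#'
#' Agreement between the consensus and all readers:
#' \deqn{E_C = \sqrt{\sum_{j} \sum_k \frac{(F_C(k) - F_j(k))^2}{N R}}}
#'
#' @param M a [function_matrix] with its consensus row.
#' @return E_C, in the index's units.
#' @export
consensus_rmse <- function(M) {
  stopifnot(inherits(M, "function_matrix"))
  d2 <- sweep(M$values, 2L, M$consensus)^2
  sqrt(sum(d2) / (ncol(M$values) * nrow(M$values)))
}

#' Bland-Altman statistics of one reader against the consensus
#'
#' Differences d_k = F_i(k) - F_C(k); bias is their mean, precision the
#' sample SD (denominator N-1), limits of agreement bias +- 1.96 SD.
#'
#' @param M a [function_matrix].
#' @param i reader index or label.
#' @return list with `bias`, `precision`, `limits` (length-2 lower/upper),
#'   `differences`.
#' @export
bland_altman <- function(M, i) {
  stopifnot(inherits(M, "function_matrix"))
  if (is.character(i)) i <- match(i, M$readers)
  stopifnot(!is.na(i))
  d <- M$values[i, ] - M$consensus
  if (length(d) < 2L) stop("bland_altman needs N >= 2 cases for a precision")
  bias <- mean(d)
  precision <- stats::sd(d)
  list(bias = bias, precision = precision,
       limits = c(lower = bias - 1.96 * precision,
                  upper = bias + 1.96 * precision),
       differences = d)
}

#' Per-case consensus standard error
#'
#' The RMS deviation of the readers from the consensus on case k, divided by
#' sqrt(R):
#' \deqn{SE_k = \sqrt{\sum_j (F_j(k) - F_C(k))^2 / R} \; / \; \sqrt{R}}
#' This is the spread-of-readers reading of a "consensus +- standard error"
#' table entry; it is isolated here so another estimator can be swapped in.
#'
#' @param M a [function_matrix].
#' @param k case index or label; default all cases.
#' @return named vector of SE_k.
#' @export
consensus_se <- function(M, k = NULL) {
  stopifnot(inherits(M, "function_matrix"))
  if (is.null(k)) k <- seq_len(ncol(M$values))
  if (is.character(k)) k <- match(k, M$cases)
  R <- nrow(M$values)
  out <- vapply(k, function(kk) {
    dev <- M$values[, kk] - M$consensus[kk]
    sqrt(sum(dev^2) / R) / sqrt(R)
  }, 0)
  stats::setNames(out, M$cases[k])
}

#' Agreement report for one functional index
#'
#' @param M a [function_matrix].
#' @return object of class `agreement_report`: `index`, `per_reader`
#'   (data.frame: reader, E_i, bias, precision, lower_limit, upper_limit),
#'   `E_C`, `consensus_best` (is E_C < min_i E_i?), `per_case` (data.frame:
#'   case, consensus, se).
#' @export
agreement_report <- function(M) {
  stopifnot(inherits(M, "function_matrix"))
  R <- nrow(M$values)
  rows <- lapply(seq_len(R), function(i) {
    ba <- bland_altman(M, i)
    data.frame(reader = M$readers[i], E_i = reader_rmse(M, i),
               bias = ba$bias, precision = ba$precision,
               lower_limit = ba$limits[["lower"]],
               upper_limit = ba$limits[["upper"]],
               stringsAsFactors = FALSE)
  })
  per_reader <- do.call(rbind, rows)
  ec <- consensus_rmse(M)
  structure(
    list(index = M$index, per_reader = per_reader, E_C = ec,
         consensus_best = ec < min(per_reader$E_i),
         per_case = data.frame(case = M$cases, consensus = M$consensus,
                               se = unname(consensus_se(M)),
                               stringsAsFactors = FALSE)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>", x$index, "- E_C =", signif(x$E_C, 4),
      "| reader E_i in [", signif(min(x$per_reader$E_i), 4), ",",
      signif(max(x$per_reader$E_i), 4), "] | consensus best:",
      x$consensus_best, "\n")
  invisible(x)
}

#' Agreement summary across all four functional indices
#'
#' @param matrices named list of [function_matrix] objects (typically
#'   EDV_ml/ESV_ml/LVM_g/EF_pct, as built by [cohort_function_matrices()]).
#' @return named list of [agreement_report()]s with an attribute
#'   `consensus_best_all` (TRUE when E_C < min_i E_i for every index).
#' @export
summarize_cohort <- function(matrices) {
  reports <- lapply(matrices, agreement_report)
  best <- vapply(reports, `[[`, logical(1L), "consensus_best")
  attr(reports, "consensus_best_all") <- all(best)
  reports
}

#' Build function matrices from per-source LV function results
#'
#' @param reader_fns per case, a named list of reader [compute_lv_function()]
#'   results (all cases must share the reader panel).
#' @param consensus_fns named list (by case) of consensus `lv_function`s.
#' @param indices which indices to tabulate.
#' @return named list of [function_matrix] objects.
#' @export
cohort_function_matrices <- function(reader_fns, consensus_fns,
                                     indices = c("EDV_ml", "ESV_ml",
                                                 "LVM_g", "EF_pct")) {
  cases <- names(reader_fns)
  stopifnot(length(cases) >= 1L, setequal(cases, names(consensus_fns)))
  readers <- names(reader_fns[[1L]])
  out <- lapply(indices, function(idx) {
    V <- vapply(cases, function(ck) {
      vapply(readers, function(rk) reader_fns[[ck]][[rk]][[idx]], 0)
    }, numeric(length(readers)))
    V <- matrix(V, nrow = length(readers),
                dimnames = list(readers, cases))
    cons <- vapply(cases, function(ck) consensus_fns[[ck]][[idx]], 0)
    function_matrix(V, cons, index = idx)
  })
  stats::setNames(out, indices)
}
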