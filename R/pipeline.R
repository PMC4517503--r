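#' Run the full consensus analysis on an in-memory cohort
#'
#' For every case: fuse the readers' contours into a consensus
#' ([consensus_contour_set()], most-readers rule), compute per-source LV
#' function, and assemble the agreement statistics across the cohort.
#'
#' @param cohort an `lv_cohort` from [simulate_cohort()], or a bare list with
#'   a `readers` element (per case, a named list of reader [contour_set]s).
#' @param params a [staple_params].
#' @param min_readers most-readers rule threshold (default 4).
#' @param factor supersampling factor (default 4).
#' @param backend area backend for reader volumetrics: `"polygon"` (default)
#'   or `"mask"`. Consensus volumetrics always use the raster-derived areas
#'   (`"mask"` uses the thresholded probability-map area; `"polygon"` the
#'   traced consensus polygon).
#' @return list of class `lv_analysis`: `consensus` (per-case [contour_set]),
#'   `reader_functions`, `consensus_functions`, `matrices` (per-index
#'   [function_matrix]), `reports` ([summarize_cohort()] output),
#'   `diagnostics`, `skipped`.
#' @export
analyze_cohort <- function(cohort, params = staple_params(), min_readers = 4L,
                           factor = 4L, backend = c("polygon", "mask")) {
  backend <- match.arg(backend)
  readers_by_case <- cohort$readers
  stopifnot(length(readers_by_case) >= 1L)
  consensus <- list()
  reader_fns <- list()
  consensus_fns <- list()
  diags <- list()
  skips <- list()
  for (case_id in names(readers_by_case)) {
    rsets <- readers_by_case[[case_id]]
    fused <- consensus_contour_set(rsets, params, min_readers, factor)
    consensus[[case_id]] <- fused$consensus
    if (!is.null(fused$diagnostics)) diags[[case_id]] <- fused$diagnostics
    if (nrow(fused$skipped)) skips[[case_id]] <- fused$skipped
    reader_fns[[case_id]] <- lapply(rsets, compute_lv_function,
                                    backend = backend, factor = factor)
    consensus_fns[[case_id]] <- compute_lv_function(
      fused$consensus,
      backend = if (backend == "mask") "mask" else "polygon",
      factor = factor)
  }
  matrices <- cohort_function_matrices(reader_fns, consensus_fns)
  structure(
    list(consensus = consensus, reader_functions = reader_fns,
         consensus_functions = consensus_fns, matrices = matrices,
         reports = summarize_cohort(matrices),
         diagnostics = if (length(diags)) do.call(rbind, c(diags, list(make.row.names = FALSE))) else NULL,
         skipped = if (length(skips)) do.call(rbind, c(skips, list(make.row.names = FALSE))) else NULL),
    class = "lv_analysis"
  )
}

#' @export
print.lv_analysis <- function(x, ...) {
  cat("<lv_analysis>", length(x$consensus), "cases\n")
  for (r in x$reports) print(r)
  invisible(x)
}

#' LV function results as a per-case table
#' @param analysis an [analyze_cohort()] result.
#' @return data.frame with one row per case and source.
#' @export
lv_function_table <- function(analysis) {
  rows <- list()
  for (case_id in names(analysis$reader_functions)) {
    for (fn in analysis$reader_functions[[case_id]]) {
      rows[[length(rows) + 1L]] <- as.data.frame(fn)
    }
    rows[[length(rows) + 1L]] <-
      as.data.frame(analysis$consensus_functions[[case_id]])
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Consensus-with-standard-error table across indices
#'
#' One row per case with `<index>` and `<index>_se` columns — the per-case
#' consensus value with the between-reader standard error.
#'
#' @param analysis an [analyze_cohort()] result.
#' @return data.frame.
#' @export
consensus_table <- function(analysis) {
  out <- NULL
  for (idx in names(analysis$reports)) {
    pc <- analysis$reports[[idx]]$per_case
    df <- data.frame(case = pc$case, stringsAsFactors = FALSE)
    df[[idx]] <- pc$consensus
    df[[paste0(idx, "_se")]] <- pc$se
    out <- if (is.null(out)) df else merge(out, df, by = "case", sort = FALSE)
  }
  out
}

#' Simulate a cohort and write it to disk
#'
#' Writes one contour exchange file per case and source (readers and truth),
#' a truth CSV of per-case true EDV/ESV/LVM/EF, and the seed manifest.
#'
#' @param config a [cohort_config].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the simulated `lv_cohort`.
#' @export
pipeline_simulate <- function(config = cohort_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  truth_rows <- list()
  for (case_id in names(cohort$truths)) {
    ph <- cohort$truths[[case_id]]
    write_contour_set(ph$truth, file.path(out_dir,
                                          paste0(case_id, "_truth.csv")))
    truth_rows[[case_id]] <- as.data.frame(ph$lv_function)
    for (rid in names(cohort$readers[[case_id]])) {
      write_contour_set(cohort$readers[[case_id]][[rid]],
                        file.path(out_dir, paste0(case_id, "_", rid, ".csv")))
    }
  }
  utils::write.csv(do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
                   file.path(out_dir, "truth_lv_function.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$manifest, file.path(out_dir, "seed_manifest.csv"),
                   row.names = FALSE)
  invisible(cohort)
}

read_cohort_dir <- function(in_dir, exclude = c("truth", "consensus")) {
  files <- list.files(in_dir, pattern = "^case.*_.*\\.csv$", full.names = TRUE)
  files <- files[!grepl("lv_function|manifest|diagnostics|skipped", files)]
  sets <- lapply(files, read_contour_set)
  keep <- !vapply(sets, function(s) s$source_id %in% exclude, logical(1L))
  sets <- sets[keep]
  by_case <- split(sets, vapply(sets, `[[`, "", "case_id"))
  lapply(by_case, function(ss) {
    stats::setNames(ss, vapply(ss, `[[`, "", "source_id"))
  })
}

#' Fuse an on-disk cohort into consensus contour files
#'
#' Reads every reader exchange file under `in_dir` (files named
#' `<case>_<source>.csv`; sources `truth`/`consensus` are ignored), fuses
#' each case, and writes `<case>_consensus.csv` plus per-slice STAPLE
#' diagnostics and the skipped-keys list.
#'
#' @param in_dir directory of reader exchange files.
#' @param out_dir output directory (default `in_dir`).
#' @inheritParams analyze_cohort
#' @return invisibly, the per-case list of [consensus_contour_set()] results.
#' @export
pipeline_consensus <- function(in_dir, out_dir = in_dir,
                               params = staple_params(), min_readers = 4L,
                               factor = 4L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readers <- read_cohort_dir(in_dir)
  if (!length(readers)) stop("no reader contour files found under ", in_dir)
  out <- list()
  diags <- list()
  skips <- list()
  for (case_id in names(readers)) {
    fused <- consensus_contour_set(readers[[case_id]], params, min_readers,
                                   factor)
    write_contour_set(fused$consensus,
                      file.path(out_dir, paste0(case_id, "_consensus.csv")))
    out[[case_id]] <- fused
    if (!is.null(fused$diagnostics)) diags[[case_id]] <- fused$diagnostics
    if (nrow(fused$skipped)) skips[[case_id]] <- fused$skipped
  }
  if (length(diags)) {
    utils::write.csv(do.call(rbind, c(diags, list(make.row.names = FALSE))),
                     file.path(out_dir, "staple_diagnostics.csv"),
                     row.names = FALSE)
  }
  skipped <- if (length(skips)) {
    do.call(rbind, c(skips, list(make.row.names = FALSE)))
  } else {
    data.frame(case_id = character(), frame = character(),
               slice_index = integer(), surface = character(),
               n_readers = integer(), stringsAsFactors = FALSE)
  }
  utils::write.csv(skipped, file.path(out_dir, "skipped_slices.csv"),
                   row.names = FALSE)
  invisible(out)
}

#' Analyze an on-disk cohort against its consensus
#'
#' Reads reader and consensus exchange files, computes per-source LV
#' function, the per-index agreement tables, the consensus +- SE table, and
#' (optionally) per-reader discrepancy reports.
#'
#' @param in_dir directory holding `<case>_<reader>.csv` and
#'   `<case>_consensus.csv` files (the latter from [pipeline_consensus()]).
#' @param out_dir output directory.
#' @param threshold_mm discrepancy flag threshold (default 3 mm).
#' @param render if `TRUE` (default) write per-reader discrepancy PDFs/CSVs.
#' @param backend reader area backend, `"polygon"` or `"mask"`.
#' @return invisibly, a list with `matrices`, `reports`, and the output
#'   file paths.
#' @export
pipeline_analyze <- function(in_dir, out_dir = in_dir, threshold_mm = 3.0,
                             render = TRUE, backend = "polygon") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readers <- read_cohort_dir(in_dir)
  cons_files <- list.files(in_dir, pattern = "_consensus\\.csv$",
                           full.names = TRUE)
  if (!length(cons_files)) {
    stop("no consensus contour files under ", in_dir,
         "; run pipeline_consensus() first")
  }
  consensus <- lapply(cons_files, read_contour_set)
  names(consensus) <- vapply(consensus, `[[`, "", "case_id")
  missing <- setdiff(names(readers), names(consensus))
  if (length(missing)) {
    stop("missing consensus for case(s): ", paste(missing, collapse = ", "))
  }
  reader_fns <- lapply(names(readers), function(ck) {
    lapply(readers[[ck]], compute_lv_function, backend = backend)
  })
  names(reader_fns) <- names(readers)
  consensus_fns <- lapply(consensus[names(readers)], compute_lv_function)
  matrices <- cohort_function_matrices(reader_fns, consensus_fns)
  reports <- summarize_cohort(matrices)
  fn_rows <- list()
  for (ck in names(reader_fns)) {
    for (fn in reader_fns[[ck]]) fn_rows[[length(fn_rows) + 1L]] <- as.data.frame(fn)
    fn_rows[[length(fn_rows) + 1L]] <- as.data.frame(consensus_fns[[ck]])
  }
  utils::write.csv(do.call(rbind, c(fn_rows, list(make.row.names = FALSE))),
                   file.path(out_dir, "lv_function.csv"), row.names = FALSE)
  for (idx in names(reports)) {
    rep <- reports[[idx]]
    tab <- rbind(rep$per_reader,
                 data.frame(reader = "consensus", E_i = rep$E_C, bias = 0,
                            precision = 0, lower_limit = 0, upper_limit = 0,
                            stringsAsFactors = FALSE))
    utils::write.csv(tab, file.path(out_dir, paste0("agreement_", idx, ".csv")),
                     row.names = FALSE)
  }
  cons_tab <- NULL
  for (idx in names(reports)) {
    pc <- reports[[idx]]$per_case
    df <- data.frame(case = pc$case, stringsAsFactors = FALSE)
    df[[idx]] <- pc$consensus
    df[[paste0(idx, "_se")]] <- pc$se
    cons_tab <- if (is.null(cons_tab)) df else merge(cons_tab, df, by = "case",
                                                     sort = FALSE)
  }
  utils::write.csv(cons_tab, file.path(out_dir, "consensus_lv_function.csv"),
                   row.names = FALSE)
  if (render) {
    for (ck in names(readers)) {
      for (rid in names(readers[[ck]])) {
        rep <- discrepancy_report(readers[[ck]][[rid]], consensus[[ck]],
                                  all_readers = readers[[ck]],
                                  threshold_mm = threshold_mm)
        render_report(rep, file.path(out_dir, paste0("report_", ck, "_", rid)),
                      readers[[ck]][[rid]], consensus[[ck]])
      }
    }
  }
  invisible(list(matrices = matrices, reports = reports, out_dir = out_dir))
}
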