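#' Write a QC report as JSON
#'
#' Serialises the counts, per-batch thresholds and per-cell flags of a
#' [filter_cells()] report. Requires the `jsonlite` package.
#'
#' @param report a `qc_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the jsonlite package is required to write JSON")
  jsonlite::write_json(list(n_cells_in = report$n_cells_in,
                            n_cells_kept = report$n_cells_kept,
                            thresholds = lapply(report$thresholds,
                                                as.list),
                            keep = report$keep,
                            reason = report$reason),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' Serialises the planted labels of a [generate_counts()] or
#' [generate_image()] truth object. Requires the `jsonlite` package.
#'
#' @param truth the `truth` element of a generator result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the jsonlite package is required to write JSON")
  clean <- lapply(truth, function(x) {
    if (is.matrix(x)) unclass(as.data.frame(x)) else x
  })
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
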