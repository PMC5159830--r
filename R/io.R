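#' Write / read per-cell traces as long-format CSV
#'
#' Columns: `cell_id`, `time_min`, `value`, `channel`. Values survive the
#' round trip to better than 1e-12 relative precision (15 significant
#' digits are written).
#'
#' @param ts a [TraceSet-class].
#' @param path CSV file path.
#' @export
writeTracesCsv <- function(ts, path) {
  stopifnot(is(ts, "TraceSet"))
  sig <- traceSignal(ts)
  tm <- traceTimes(ts)
  ids <- as.character(rowData(ts)$cell_id)
  df <- data.frame(
    cell_id = rep(ids, times = length(tm)),
    time_min = rep(tm, each = length(ids)),
    value = as.vector(sig),
    channel = traceChannel(ts))
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTracesCsv
#' @export
readTracesCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_min", "value", "channel")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  ids <- unique(df$cell_id)
  tm <- sort(unique(df$time_min))
  mat <- matrix(NA_real_, length(ids), length(tm),
                dimnames = list(ids, NULL))
  mat[cbind(match(df$cell_id, ids), match(df$time_min, tm))] <- df$value
  if (anyNA(mat)) stop("trace CSV is not a complete cell x time grid")
  TraceSet(mat, tm, channel = df$channel[1L],
           cellData = S4Vectors::DataFrame(cell_id = ids))
}

#' Write / read the cell (live-imaging ROI) table as CSV
#' @param cells a cell table ([samplePopulation()] output or the live ROI
#'   table with at least `cell_id`, `x_um`, `y_um`, `square_id`).
#' @param path CSV file path.
#' @export
writeCellsCsv <- function(cells, path) {
  utils::write.csv(format(as.data.frame(cells), digits = 15,
                          scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCellsCsv
#' @export
readCellsCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the staining table as CSV
#' @param stains staining table from [simulateStaining()] or a measured
#'   equivalent (`stain_id`, `x_um`, `y_um`, `square_id`, `insulin`,
#'   `glucagon`).
#' @param path CSV file path.
#' @export
writeStainsCsv <- function(stains, path) {
  utils::write.csv(format(as.data.frame(stains), digits = 15,
                          scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeStainsCsv
#' @export
readStainsCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a ClassificationReport to JSON
#' @param report a [ClassificationReport-class].
#' @param path JSON file path.
#' @export
writeReportJson <- function(report, path) {
  stopifnot(is(report, "ClassificationReport"))
  obj <- list(
    n_total = report@nTotal,
    threshold = report@threshold,
    type_summary = report@typeSummary,
    fp_count = report@fpCount, fp_rate = report@fpRate,
    fn_count = report@fnCount, fn_rate = report@fnRate,
    excluded = as.list(report@excluded),
    distribution = report@distribution)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}
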