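#' Construct a TraceSet
#'
#' @param values numeric matrix of signal values, cells x time points.
#' @param timesMin numeric vector of acquisition times in minutes (one per
#'   column, strictly increasing; the nominal cycle time shared by all
#'   cells).
#' @param channel `"nadph"`, `"calcium_ratio"`, or `"nadph_pct"` for
#'   KCN/FCCP-normalized traces.
#' @param cellData optional per-cell metadata ([S4Vectors::DataFrame] or
#'   data.frame) with one row per matrix row; a `cell_id` column, if
#'   present, provides the row names.
#' @return A [TraceSet-class].
#' @export
TraceSet <- function(values, timesMin,
                     channel = c("nadph", "calcium_ratio", "nadph_pct"),
                     cellData = NULL) {
  channel <- match.arg(channel)
  values <- as.matrix(values)
  if (ncol(values) != length(timesMin))
    stop("length(timesMin) must equal ncol(values)")
  if (is.null(cellData))
    cellData <- S4Vectors::DataFrame(
      cell_id = if (is.null(rownames(values)))
        sprintf("cell%04d", seq_len(nrow(values))) else rownames(values))
  cellData <- as(cellData, "DataFrame")
  if (!is.null(cellData$cell_id)) rownames(values) <- cellData$cell_id
  colnames(values) <- sprintf("t%g", timesMin)
  se <- SummarizedExperiment(
    assays = list(signal = values),
    rowData = cellData,
    colData = S4Vectors::DataFrame(time_min = as.numeric(timesMin),
                                   row.names = colnames(values)))
  S4Vectors::metadata(se)$channel <- channel
  new("TraceSet", se)
}

#' TraceSet accessors
#'
#' @param x a [TraceSet-class].
#' @return `traceSignal()`: the cells x time points signal matrix;
#'   `traceTimes()`: acquisition times in minutes; `traceChannel()`: the
#'   channel string; `cellInfo()`: the per-cell `rowData`.
#' @export
traceSignal <- function(x) {
  stopifnot(is(x, "TraceSet"))
  assay(x, "signal")
}

#' @rdname traceSignal
#' @export
traceTimes <- function(x) {
  stopifnot(is(x, "TraceSet"))
  colData(x)$time_min
}

#' @rdname traceSignal
#' @export
traceChannel <- function(x) {
  stopifnot(is(x, "TraceSet"))
  metadata(x)$channel
}

#' @rdname traceSignal
#' @export
cellInfo <- function(x) {
  stopifnot(is(x, "TraceSet"))
  rowData(x)
}

setMethod("show", "TraceSet", function(object) {
  tm <- traceTimes(object)
  cat(sprintf("TraceSet: %d cells x %d time points (%s)\n",
              nrow(object), ncol(object), traceChannel(object)))
  cat(sprintf("  time %g-%g min, sampling every %g min\n",
              tm[1L], tm[length(tm)],
              if (length(tm) > 1L) tm[2L] - tm[1L] else NA_real_))
  cd <- names(rowData(object))
  if (length(cd)) cat("  rowData:", paste(cd, collapse = ", "), "\n")
})
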