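#' Steady-state level of a trace over a time window
#'
#' The arithmetic mean of all samples with `start_min <= t <= end_min`
#' (closed interval). At the standard 120-s sampling a 10-min window holds
#' 5-6 samples.
#'
#' @param values numeric vector of trace values.
#' @param timesMin sample times in minutes, same length.
#' @param window numeric `c(start_min, end_min)`.
#' @param label window name used in error messages.
#' @return the mean value over the window.
#' @export
steadyState <- function(values, timesMin, window, label = "window") {
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("window must be c(start_min, end_min) with start < end")
  keep <- timesMin >= window[1L] - 1e-9 & timesMin <= window[2L] + 1e-9
  if (!any(keep))
    stop(sprintf("no samples in %s [%g, %g] min", label,
                 window[1L], window[2L]))
  mean(values[keep])
}

## per-cell window means over a TraceSet (rows = cells)
.windowMeans <- function(ts, window, label = "window") {
  tm <- traceTimes(ts)
  keep <- tm >= window[1L] - 1e-9 & tm <= window[2L] + 1e-9
  if (!any(keep))
    stop(sprintf("no samples in %s [%g, %g] min", label,
                 window[1L], window[2L]))
  rowMeans(traceSignal(ts)[, keep, drop = FALSE])
}

.winRow <- function(windows, label) {
  i <- match(label, windows$label)
  if (is.na(i)) stop("windows table has no '", label, "' window")
  c(windows$start_min[i], windows$end_min[i])
}

#' Calibrate NAD(P)H traces against the KCN and FCCP plateaus
#'
#' For each cell the steady-state RFU during KCN exposure (`RFU_KCN`, the
#' maximal NAD(P)H plateau) and during FCCP exposure (`RFU_FCCP`, the
#' minimal plateau) are measured from the calibration windows, and every
#' value is rescaled so that `RFU_FCCP` maps to 0% and `RFU_KCN` to 100%:
#' `v -> 100 * (v - RFU_FCCP) / (RFU_KCN - RFU_FCCP)`. Cells whose KCN
#' plateau does not exceed their FCCP plateau cannot be calibrated; their
#' normalized values are set to `NA` and they are flagged
#' (`calibration_ok = FALSE` in `rowData`) for downstream exclusion and QC
#' counting rather than silently dropped.
#'
#' @param ts a raw NAD(P)H [TraceSet-class].
#' @param windows windows table from [analysisWindows()] (needs `kcn` and
#'   `fccp` rows), or `NULL` to use the default NAD(P)H protocol windows.
#' @return A [TraceSet-class] with channel `"nadph_pct"` and added
#'   `rowData` columns `rfu_kcn`, `rfu_fccp`, `calibration_ok`.
#' @export
normalizeTraces <- function(ts, windows = NULL) {
  stopifnot(is(ts, "TraceSet"))
  if (traceChannel(ts) != "nadph")
    stop("KCN/FCCP normalization applies to the 'nadph' channel only")
  if (is.null(windows)) windows <- analysisWindows(nadphProtocol(), "nadph")
  kcn <- .windowMeans(ts, .winRow(windows, "kcn"), "kcn window")
  fccp <- .windowMeans(ts, .winRow(windows, "fccp"), "fccp window")
  ok <- kcn > fccp
  span <- kcn - fccp
  norm <- 100 * (traceSignal(ts) - fccp) / span
  norm[!ok, ] <- NA_real_
  cd <- rowData(ts)
  cd$rfu_kcn <- kcn
  cd$rfu_fccp <- fccp
  cd$calibration_ok <- ok
  TraceSet(norm, traceTimes(ts), channel = "nadph_pct", cellData = cd)
}

#' Drift-robust minimum-change NAD(P)H response statistic
#'
#' For each cell, with `SS(w)` the steady-state level over window `w` of
#' the normalized trace, the two glucose-transition changes are
#' `delta_up = SS(high_glucose) - SS(baseline)` and
#' `delta_down = SS(high_glucose) - SS(post_return)`, and the response
#' statistic is `min(delta_up, delta_down)`. A monotone signal drift
#' inflates one transition but deflates the other, so the minimum cannot be
#' driven positive by drift alone; both components are retained.
#'
#' @param ts a normalized [TraceSet-class] (channel `"nadph_pct"`, from
#'   [normalizeTraces()]).
#' @param windows windows table with `baseline`, `high_glucose` and
#'   `post_return` rows; `NULL` for the default NAD(P)H windows.
#' @return data.frame with `cell_id`, `delta_up`, `delta_down`,
#'   `statistic` (% of KCN-FCCP span) and `qc` (`"ok"` or
#'   `"failed_calibration"`).
#' @export
responseMinChange <- function(ts, windows = NULL) {
  stopifnot(is(ts, "TraceSet"))
  if (traceChannel(ts) != "nadph_pct")
    stop("responseMinChange expects KCN/FCCP-normalized traces; ",
         "run normalizeTraces() first")
  if (is.null(windows)) windows <- analysisWindows(nadphProtocol(), "nadph")
  ssB <- .windowMeans(ts, .winRow(windows, "baseline"), "baseline window")
  ssH <- .windowMeans(ts, .winRow(windows, "high_glucose"),
                      "high-glucose window")
  ssP <- .windowMeans(ts, .winRow(windows, "post_return"),
                      "post-return window")
  up <- ssH - ssB
  down <- ssH - ssP
  ok <- rowData(ts)$calibration_ok
  if (is.null(ok)) ok <- rep(TRUE, nrow(ts))
  data.frame(cell_id = as.character(rowData(ts)$cell_id),
             delta_up = up, delta_down = down,
             statistic = pmin(up, down),
             qc = ifelse(ok, "ok", "failed_calibration"))
}

#' Calcium response statistic
#'
#' The change of steady-state Fura fluorescence ratio on glucose
#' stimulation: `SS(stimulated) - SS(baseline)`, in ratio units. No
#' KCN/FCCP normalization and no down-step term are applied (the calcium
#' ratio does not fully return to baseline after the stimulus).
#'
#' @param ts a raw calcium-ratio [TraceSet-class].
#' @param windows windows table with `baseline` and `stimulated` rows;
#'   `NULL` for the default calcium windows.
#' @return data.frame with `cell_id`, `delta_up`, `delta_down` (`NA`),
#'   `statistic` (ratio units), `qc`.
#' @export
calciumResponse <- function(ts, windows = NULL) {
  stopifnot(is(ts, "TraceSet"))
  if (traceChannel(ts) != "calcium_ratio")
    stop("calciumResponse expects the 'calcium_ratio' channel")
  if (is.null(windows))
    windows <- analysisWindows(calciumProtocol(), "calcium_ratio")
  ssB <- .windowMeans(ts, .winRow(windows, "baseline"), "baseline window")
  ssS <- .windowMeans(ts, .winRow(windows, "stimulated"),
                      "stimulated window")
  data.frame(cell_id = as.character(rowData(ts)$cell_id),
             delta_up = ssS - ssB, delta_down = NA_real_,
             statistic = ssS - ssB,
             qc = "ok")
}

#' Per-cell response table for either channel
#'
#' Dispatches on the TraceSet channel: raw NAD(P)H traces are calibrated
#' with [normalizeTraces()] and scored with [responseMinChange()]; calcium
#' traces are scored with [calciumResponse()].
#'
#' @param ts a [TraceSet-class] (channel `"nadph"`, `"nadph_pct"` or
#'   `"calcium_ratio"`).
#' @param windows windows table from [analysisWindows()], or `NULL` for
#'   the channel default.
#' @return data.frame as from [responseMinChange()]/[calciumResponse()].
#' @export
responseTable <- function(ts, windows = NULL) {
  switch(traceChannel(ts),
    nadph = responseMinChange(normalizeTraces(ts, windows), windows),
    nadph_pct = responseMinChange(ts, windows),
    calcium_ratio = calciumResponse(ts, windows))
}
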