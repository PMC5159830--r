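#' Build a stage-scanning acquisition schedule
#'
#' The stage visits each region once per cycle, in order; region `k`
#' (0-based within the cycle) of cycle `c` (0-based) is acquired at
#' `c * cyclePeriodS + k * acquisitionTimeS` seconds. All regions must fit
#' within one cycle.
#'
#' @param regionIds ordered vector of region identifiers.
#' @param acquisitionTimeS per-region acquisition slot in seconds (image
#'   integration plus stage advance; default 0.2 s, i.e. ~3 regions/s... see
#'   [maxThroughput()]).
#' @param cyclePeriodS time between successive visits to the same region
#'   (default 120 s).
#' @param nCycles number of cycles.
#' @return data.frame with `region_id`, `cycle` (1-based), `time_s`.
#' @export
buildScanSchedule <- function(regionIds, acquisitionTimeS = 0.2,
                              cyclePeriodS = 120, nCycles) {
  nReg <- length(regionIds)
  if (nReg < 1L) stop("need at least one region")
  if (acquisitionTimeS <= 0 || cyclePeriodS <= 0 || nCycles < 1)
    stop("acquisitionTimeS, cyclePeriodS and nCycles must be positive")
  needed <- nReg * acquisitionTimeS
  if (needed > cyclePeriodS)
    stop(sprintf(paste0("infeasible schedule: %d regions x %g s = %g s per ",
                        "cycle exceeds the %g s cycle period; minimum ",
                        "feasible cycle period is %g s"),
                 nReg, acquisitionTimeS, needed, cyclePeriodS, needed))
  cycles <- rep(seq_len(nCycles), each = nReg)
  slots <- rep(seq_len(nReg) - 1L, times = nCycles)
  data.frame(region_id = rep(regionIds, times = nCycles),
             cycle = cycles,
             time_s = (cycles - 1L) * cyclePeriodS + slots * acquisitionTimeS)
}

#' Maximal real-time analysis throughput
#'
#' `regionsPerSecond * 60 * cellsPerRegion` cells per minute. With the
#' published stage rate of ~3 regions/s and ~20 visible cells per region
#' this arithmetic gives 3600 cells/min; the figure of ~7200 cells/min also
#' in circulation corresponds to ~40 cells per region at the same stage
#' rate. This function implements the formula; both readings are obtained
#' by the corresponding arguments.
#'
#' @param regionsPerSecond stage advance rate (regions per second).
#' @param cellsPerRegion cells quantified per region image.
#' @return cells analysed per minute.
#' @export
maxThroughput <- function(regionsPerSecond, cellsPerRegion) {
  if (!is.numeric(regionsPerSecond) || !is.numeric(cellsPerRegion) ||
      any(regionsPerSecond <= 0) || any(cellsPerRegion <= 0))
    stop("regionsPerSecond and cellsPerRegion must be > 0")
  regionsPerSecond * 60 * cellsPerRegion
}

## circular-mask pixel indices; pixel (r, c) has centre (c - 0.5, r - 0.5)
## in pixel units (origin at the image's top-left corner)
.circleMask <- function(nrow, ncol, xPx, yPx, radiusPx) {
  cx <- seq_len(ncol) - 0.5
  cy <- seq_len(nrow) - 0.5
  which(outer((cy - yPx)^2, (cx - xPx)^2, "+") <= radiusPx^2)
}

#' Extract per-cell traces from an image stack via ROI masks
#'
#' For every frame, the trace value of a cell is the mean pixel intensity
#' within its mask. Circular masks use the centre-in rule: a pixel belongs
#' to the ROI when its centre lies within the radius.
#'
#' @param stack a 3-D array (rows x cols x frames) or list of equal-sized
#'   matrices, one per time point.
#' @param roiSet data.frame with `cell_id`, `x_px`, `y_px`, `radius_px`
#'   (pixel coordinates, origin top-left).
#' @param timestampsMin acquisition time of each frame, minutes.
#' @param channel channel label for the resulting [TraceSet-class].
#' @return A [TraceSet-class], one row per ROI.
#' @export
extractRoiTraces <- function(stack, roiSet, timestampsMin,
                             channel = c("nadph", "calcium_ratio")) {
  channel <- match.arg(channel)
  if (is.list(stack)) {
    frames <- stack
  } else if (is.array(stack) && length(dim(stack)) == 3L) {
    frames <- lapply(seq_len(dim(stack)[3L]), function(i) stack[, , i])
  } else if (is.matrix(stack)) {
    frames <- list(stack)
  } else stop("stack must be a matrix, 3-D array, or list of matrices")
  if (length(frames) != length(timestampsMin))
    stop("frame count (", length(frames), ") does not match timestamp count (",
         length(timestampsMin), ")")
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  need <- c("cell_id", "x_px", "y_px", "radius_px")
  if (!all(need %in% names(roiSet)))
    stop("roiSet must have columns: ", paste(need, collapse = ", "))

  masks <- vector("list", nrow(roiSet))
  for (i in seq_len(nrow(roiSet))) {
    x <- roiSet$x_px[i]; y <- roiSet$y_px[i]; r <- roiSet$radius_px[i]
    if (x - r < 0 || x + r > w || y - r < 0 || y + r > h)
      stop("ROI for ", roiSet$cell_id[i], " extends outside the image bounds")
    m <- .circleMask(h, w, x, y, r)
    if (length(m) == 0L)
      stop("ROI for ", roiSet$cell_id[i], " contains no pixel centres")
    masks[[i]] <- m
  }
  vals <- vapply(frames, function(f) {
    if (nrow(f) != h || ncol(f) != w) stop("frames differ in size")
    vapply(masks, function(m) mean(f[m]), 0)
  }, numeric(nrow(roiSet)))
  if (nrow(roiSet) == 1L) vals <- matrix(vals, nrow = 1L)
  cd <- S4Vectors::DataFrame(roiSet)
  TraceSet(vals, timestampsMin, channel = channel, cellData = cd)
}

#' Read/write multi-page grayscale TIFF stacks
#'
#' Images are stored as 16-bit grayscale with intensities on a 0-65535
#' scale; `readImageStack()` returns intensities on that scale.
#'
#' @param stack list of numeric matrices (or a single matrix) with values
#'   in `[0, 65535]`.
#' @param path TIFF file path.
#' @return `readImageStack()`: a list of matrices.
#' @export
writeImageStack <- function(stack, path) {
  if (is.matrix(stack)) stack <- list(stack)
  stack <- lapply(stack, function(m) {
    m <- m / 65535
    if (any(m < 0 | m > 1)) stop("intensities must lie in [0, 65535]")
    m
  })
  tiff::writeTIFF(stack, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(m) m * 65535)
}

#' Read/write an ROI set as CSV
#' @param roiSet data.frame with `region_id`, `cell_id`, `shape`, `x_px`,
#'   `y_px`, `radius_px`.
#' @param path CSV file path.
#' @export
writeRoiSet <- function(roiSet, path) {
  utils::write.csv(roiSet, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRoiSet
#' @export
readRoiSet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
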