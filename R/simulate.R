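## Per-segment target plateau for each cell, given its generator parameters.
## NAD(P)H: glucose stimulus raises the signal by response_param percent of
## the cell's KCN-FCCP span; KCN/FCCP pin the signal at the calibration
## plateaus. Calcium: the stimulus raises the Fura ratio by response_param;
## after glucose returns the ratio retains recoveryFrac of the response;
## KCl depolarizes every cell by a fixed ratio increment.
.segmentTargets <- function(cells, protocol, recoveryFrac = 0.25,
                            kclStep = 0.5) {
  seg <- protocolSegments(protocol)
  n <- nrow(cells)
  channel <- cells$channel[1L]
  span <- cells$plateau_kcn - cells$plateau_fccp
  targets <- matrix(NA_real_, n, nrow(seg))
  for (j in seq_len(nrow(seg))) {
    targets[, j] <- switch(seg$role[j],
      baseline = cells$baseline,
      stimulus = if (channel == "nadph")
        cells$baseline + cells$response_param / 100 * span
      else cells$baseline + cells$response_param,
      recovery = if (channel == "nadph") cells$baseline
        else cells$baseline + recoveryFrac * cells$response_param,
      kcn  = cells$plateau_kcn,
      fccp = cells$plateau_fccp,
      kcl  = cells$baseline + kclStep)
  }
  targets
}

#' Simulate per-cell fluorescence traces under a perifusion protocol
#'
#' Each cell's noiseless signal is a piecewise plateau sequence defined by
#' the protocol segments, approached with first-order kinetics (per-cell
#' time constant `tau_min`; a non-positive value means instantaneous
#' transitions). Linear drift (`drift_slope` per minute) and additive
#' Gaussian noise (`noise_sd`) are superimposed. Samples are taken at the
#' nominal cycle times `0, dt, 2 dt, ...` strictly inside the protocol,
#' with `dt = samplingPeriodS / 60` minutes.
#'
#' @param cells population table from [samplePopulation()] (or any
#'   data.frame with the same generator-parameter columns).
#' @param protocol a [Protocol-class]; [nadphProtocol()] by default for the
#'   NAD(P)H channel.
#' @param samplingPeriodS sampling period in seconds (default 120).
#' @param seed optional integer seed.
#' @param recoveryFrac,kclStep calcium-channel plateau details, see
#'   [populationSpec()].
#' @return A [TraceSet-class] with the cell table in `rowData`.
#' @export
simulateTraces <- function(cells, protocol = NULL, samplingPeriodS = 120,
                           seed = NULL, recoveryFrac = 0.25, kclStep = 0.5) {
  if (nrow(cells) == 0L) stop("no cells to simulate")
  if (!is.numeric(samplingPeriodS) || samplingPeriodS <= 0)
    stop("samplingPeriodS must be > 0")
  channel <- cells$channel[1L]
  if (is.null(protocol))
    protocol <- if (channel == "nadph") nadphProtocol() else calciumProtocol()
  stopifnot(is(protocol, "Protocol"))
  seg <- protocolSegments(protocol)
  if (nrow(seg) == 0L) stop("empty protocol")
  if (!is.null(seed)) set.seed(seed)

  dt <- samplingPeriodS / 60
  endMin <- protocolEnd(protocol)
  times <- seq(0, endMin, by = dt)
  times <- times[times < endMin - 1e-9]
  if (length(times) < 2L)
    stop("protocol too short for the sampling period")

  n <- nrow(cells)
  targets <- .segmentTargets(cells, protocol, recoveryFrac, kclStep)
  tau <- cells$tau_min
  vals <- matrix(NA_real_, n, length(times))
  vstart <- cells$baseline
  for (j in seq_len(nrow(seg))) {
    idx <- which(times >= seg$start_min[j] - 1e-9 &
                 times < seg$end_min[j] - 1e-9)
    tgt <- targets[, j]
    gap <- vstart - tgt
    if (length(idx)) {
      dtm <- matrix(times[idx] - seg$start_min[j], n, length(idx),
                    byrow = TRUE)
      E <- ifelse(tau > 0, 1, 0) * exp(-dtm / ifelse(tau > 0, tau, 1))
      vals[, idx] <- tgt + gap * E
    }
    segLen <- seg$end_min[j] - seg$start_min[j]
    vstart <- tgt + gap * ifelse(tau > 0, exp(-segLen / tau), 0)
  }
  drift <- outer(cells$drift_slope, times)
  noise <- matrix(stats::rnorm(n * length(times)), n) * cells$noise_sd
  TraceSet(vals + drift + noise, times, channel = channel,
           cellData = cells)
}

#' Simulate the post-fixation immunostaining table
#'
#' Each cell yields one stain record: beta cells are insulin-bright and
#' glucagon-dim, alpha cells the reverse, "other" cells dim in both.
#' An exact quota of `unstainedFraction` cells is forced hormone-negative
#' (the "other" type first) and a quota of `coStainFraction` cells is
#' forced double-positive. Stained-image centroids are the live centroids
#' plus isotropic Gaussian jitter (`jitterSdUm`); the stained record's grid
#' square is re-read from the jittered position.
#'
#' @param cells population table from [samplePopulation()].
#' @param spec the [PopulationSpec-class] holding the staining model.
#' @param layout a [GridLayout-class] used to re-address jittered
#'   centroids; if `NULL` the live square is kept.
#' @param seed optional integer seed.
#' @return data.frame with `stain_id`, `x_um`, `y_um`, `square_id`,
#'   `insulin`, `glucagon`, plus the source `cell_id` (ground truth for
#'   validation; the matching step never uses it).
#' @export
simulateStaining <- function(cells, spec, layout = NULL, seed = NULL) {
  stopifnot(is(spec, "PopulationSpec"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cells)
  type <- cells$type

  high <- function(k) pmax(stats::rnorm(k, spec@stainHigh, spec@stainHighSd), 0)
  low <- function(k) pmax(stats::rnorm(k, spec@stainLow, spec@stainLowSd), 0)

  insulin <- numeric(n); glucagon <- numeric(n)
  isBeta <- type == "beta"; isAlpha <- type == "alpha"
  insulin[isBeta] <- high(sum(isBeta)); glucagon[isBeta] <- low(sum(isBeta))
  glucagon[isAlpha] <- high(sum(isAlpha)); insulin[isAlpha] <- low(sum(isAlpha))
  rest <- !(isBeta | isAlpha)
  insulin[rest] <- low(sum(rest)); glucagon[rest] <- low(sum(rest))

  nUnstained <- round(spec@unstainedFraction * n)
  if (nUnstained > 0) {
    otherIdx <- which(rest)
    extra <- nUnstained - length(otherIdx)
    pick <- if (extra > 0)
      c(otherIdx, sample(which(!rest), extra)) else otherIdx[seq_len(nUnstained)]
    insulin[pick] <- low(length(pick))
    glucagon[pick] <- low(length(pick))
  } else pick <- integer(0)

  nCo <- round(spec@coStainFraction * n)
  if (nCo > 0) {
    eligible <- setdiff(seq_len(n), pick)
    co <- sample(eligible, min(nCo, length(eligible)))
    insulin[co] <- high(length(co)); glucagon[co] <- high(length(co))
  }

  x <- cells$x_um + stats::rnorm(n, 0, spec@jitterSdUm)
  y <- cells$y_um + stats::rnorm(n, 0, spec@jitterSdUm)
  sq <- if (is.null(layout)) cells$square_id else locateSquare(layout, x, y)

  data.frame(stain_id = sprintf("stain%04d", seq_len(n)),
             x_um = x, y_um = y, square_id = sq,
             insulin = insulin, glucagon = glucagon,
             cell_id = cells$cell_id)
}

#' Render one grid region as a synthetic fluorescence image
#'
#' Cells are drawn as uniform disks of the given intensity on a constant
#' background, in a square image covering exactly one grid square. The
#' pixel size (um/px) is stored as an attribute so ROI masks can be
#' transformed between image and stage coordinates. A pixel belongs to a
#' disk when its centre lies within the radius.
#'
#' @param cells rows of a population table, all within `squareId`.
#' @param layout a [GridLayout-class].
#' @param squareId the grid square to render.
#' @param intensities per-cell disk intensity (recycled).
#' @param imageSizePx image side length in pixels.
#' @param cellRadiusUm disk radius in micrometres.
#' @param background background intensity.
#' @return numeric matrix (rows = y) with attributes `pixel_size_um` and
#'   `square_id`.
#' @export
renderRegionImage <- function(cells, layout, squareId, intensities = 100,
                              imageSizePx = 256L, cellRadiusUm = 7.5,
                              background = 0) {
  stopifnot(is(layout, "GridLayout"))
  n <- nrow(cells)
  if (n > 0 && !all(cells$square_id == squareId))
    stop("all cells must lie in square ", squareId)
  b <- squareBounds(layout, squareId)
  scale <- layout@squareSizeUm / imageSizePx   # um per pixel
  img <- matrix(background, imageSizePx, imageSizePx)
  if (n == 0L) {
    attr(img, "pixel_size_um") <- scale
    attr(img, "square_id") <- squareId
    return(img)
  }
  intensities <- rep_len(intensities, n)
  px <- (seq_len(imageSizePx) - 0.5) * scale   # pixel-centre coordinates, um
  for (i in seq_len(n)) {
    cx <- cells$x_um[i] - b$x0_um
    cy <- cells$y_um[i] - b$y0_um
    if (cx < 0 || cx > layout@squareSizeUm ||
        cy < 0 || cy > layout@squareSizeUm)
      stop("cell ", cells$cell_id[i], " lies outside square ", squareId)
    dx2 <- (px - cx)^2
    dy2 <- (px - cy)^2
    mask <- outer(dy2, dx2, "+") <= cellRadiusUm^2
    img[mask] <- intensities[i]
  }
  attr(img, "pixel_size_um") <- scale
  attr(img, "square_id") <- squareId
  img
}

#' Circular ROI set for the cells of one rendered region
#'
#' Companion to [renderRegionImage()]: returns the pixel-space circular
#' ROIs centred on each cell, using the same pixel grid convention, for use
#' with [extractRoiTraces()].
#'
#' @inheritParams renderRegionImage
#' @param radiusPx ROI radius in pixels; defaults to the rendered disk
#'   radius so the ROI mean equals the disk intensity exactly.
#' @return data.frame with `region_id`, `cell_id`, `shape`, `x_px`,
#'   `y_px`, `radius_px`.
#' @export
regionRois <- function(cells, layout, squareId, imageSizePx = 256L,
                       cellRadiusUm = 7.5, radiusPx = NULL) {
  b <- squareBounds(layout, squareId)
  scale <- layout@squareSizeUm / imageSizePx
  if (is.null(radiusPx)) radiusPx <- cellRadiusUm / scale
  data.frame(region_id = squareId,
             cell_id = cells$cell_id,
             shape = "circle",
             x_px = (cells$x_um - b$x0_um) / scale,
             y_px = (cells$y_um - b$y0_um) / scale,
             radius_px = radiusPx)
}
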