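#' Specify a synthetic mixed-cell population
#'
#' Defaults reproduce the study conditions of the dispersed-islet NAD(P)H
#' experiment: 183 beta-like cells (response mean 27% of the KCN-FCCP
#' span), 32 alpha-like (mean -5.0%) and 12 "other" (hormone-negative,
#' near-zero response) - 227 cells across ten imaged grid regions. Per-type
#' response sds are back-computed from the reported SEMs (0.9 * sqrt(183)
#' ~ 12.2; 1.6 * sqrt(32) ~ 9.1). For the calcium channel the per-type
#' response means/sds default to the Fura-ratio changes (beta 0.33, alpha
#' 0.051) with sds back-computed the same way from n = 40 and n = 14.
#'
#' @param channel `"nadph"` or `"calcium_ratio"`.
#' @param nCells total number of cells.
#' @param composition named fractions per type, summing to 1.
#' @param responseMean,responseSd,responseLo,responseHi named per-type
#'   response distribution parameters (truncated normal; `-Inf`/`Inf`
#'   bounds disable truncation). Units: percent of KCN-FCCP span (NAD(P)H)
#'   or Fura ratio units (calcium).
#' @param samplingMode `"quota"` (largest-remainder exact counts, the
#'   default, reproducible cell-type totals) or `"multinomial"`.
#' @param rfuKcn,rfuKcnSd,rfuFccp,rfuFccpSd per-cell calibration plateau
#'   distribution (RFU). KCN is the maximal NAD(P)H plateau, FCCP the
#'   minimal one.
#' @param baselineFrac,baselineFracSd baseline NAD(P)H level as a fraction
#'   of the per-cell KCN-FCCP span.
#' @param baselineRatio,baselineRatioSd baseline Fura ratio (calcium).
#' @param recoveryFrac fraction of the calcium response that persists after
#'   glucose returns to baseline (the ratio does not fully recover).
#' @param driftSd sd of the per-cell linear drift slope (signal units/min).
#' @param noiseSd additive Gaussian measurement noise sd (signal units).
#' @param tauMin first-order response time constant in minutes.
#' @param nRegions number of imaged grid squares the cells occupy.
#' @param minSpacingUm minimum centre-to-centre cell spacing within a region.
#' @param edgeMarginUm margin kept free along each square edge.
#' @param unstainedFraction fraction of cells forced hormone-negative in the
#'   staining simulation, beyond the "other" type (exact quota).
#' @param coStainFraction fraction of stained cells positive in both
#'   channels (exact quota).
#' @param jitterSdUm Gaussian sd of the live-to-stained centroid jitter.
#' @param stainHigh,stainHighSd,stainLowSd,stainLow stain intensity model
#'   (arbitrary units) for positive and negative channels.
#' @return A [PopulationSpec-class].
#' @export
populationSpec <- function(channel = c("nadph", "calcium_ratio"),
                           nCells = 227L,
                           composition = c(beta = 183, alpha = 32,
                                           other = 12) / 227,
                           responseMean = NULL,
                           responseSd = NULL,
                           responseLo = NULL,
                           responseHi = NULL,
                           samplingMode = c("quota", "multinomial"),
                           rfuKcn = 500, rfuKcnSd = 40,
                           rfuFccp = 50, rfuFccpSd = 8,
                           baselineFrac = 0.4, baselineFracSd = 0.05,
                           baselineRatio = 1.0, baselineRatioSd = 0.05,
                           recoveryFrac = 0.25,
                           driftSd = NULL, noiseSd = NULL, tauMin = 3,
                           nRegions = 10L, minSpacingUm = 20,
                           edgeMarginUm = 10,
                           unstainedFraction = 0, coStainFraction = 0,
                           jitterSdUm = 2,
                           stainHigh = 800, stainHighSd = 80,
                           stainLow = 20, stainLowSd = 10) {
  channel <- match.arg(channel)
  samplingMode <- match.arg(samplingMode)
  types <- names(composition)
  fill <- function(x, default) {
    if (is.null(x)) x <- default
    if (is.null(names(x))) stop("per-type parameters must be named by type")
    out <- x[types]
    names(out) <- types
    if (any(is.na(out))) stop("per-type parameter missing for some types")
    out
  }
  if (channel == "nadph") {
    responseMean <- fill(responseMean, c(beta = 27, alpha = -5, other = 0))
    responseSd   <- fill(responseSd, c(beta = 12.2, alpha = 9.1, other = 4))
    if (is.null(driftSd)) driftSd <- 0.05   # RFU/min; a few RFU over a run
    if (is.null(noiseSd)) noiseSd <- 10     # RFU, ~2% of the KCN-FCCP span
  } else {
    responseMean <- fill(responseMean,
                         c(beta = 0.33, alpha = 0.051, other = 0.02))
    responseSd   <- fill(responseSd,
                         c(beta = 0.054 * sqrt(40), alpha = 0.013 * sqrt(14),
                           other = 0.02))
    if (is.null(driftSd)) driftSd <- 0.0002 # ratio units/min
    if (is.null(noiseSd)) noiseSd <- 0.01   # ratio units
  }
  responseLo <- fill(responseLo,
                     stats::setNames(rep(-Inf, length(types)), types))
  responseHi <- fill(responseHi,
                     stats::setNames(rep(Inf, length(types)), types))
  new("PopulationSpec",
      nCells = as.integer(nCells), composition = composition,
      responseMean = responseMean, responseSd = responseSd,
      responseLo = responseLo, responseHi = responseHi,
      samplingMode = samplingMode, channel = channel,
      rfuKcn = rfuKcn, rfuKcnSd = rfuKcnSd,
      rfuFccp = rfuFccp, rfuFccpSd = rfuFccpSd,
      baselineFrac = baselineFrac, baselineFracSd = baselineFracSd,
      baselineRatio = baselineRatio, baselineRatioSd = baselineRatioSd,
      recoveryFrac = recoveryFrac,
      driftSd = driftSd, noiseSd = noiseSd, tauMin = tauMin,
      nRegions = as.integer(nRegions), minSpacingUm = minSpacingUm,
      edgeMarginUm = edgeMarginUm,
      unstainedFraction = unstainedFraction,
      coStainFraction = coStainFraction,
      jitterSdUm = jitterSdUm,
      stainHigh = stainHigh, stainHighSd = stainHighSd,
      stainLow = stainLow, stainLowSd = stainLowSd)
}

## largest-remainder apportionment: exact integer counts matching fractions
.quotaCounts <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

## truncated-normal draw by rejection (bounds far in the tail are fine at
## the scales used here; falls back to clamping after many rejections)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], lo), hi)
  x
}

## dart-throwing placement of k points in [m, s-m]^2 with min spacing
.placeCells <- function(k, side, margin, minSpacing, maxTries = 20000L) {
  if (k == 0L) return(matrix(numeric(0), 0, 2))
  pts <- matrix(NA_real_, k, 2)
  placed <- 0L
  lo <- margin; hi <- side - margin
  if (hi <= lo) stop("edge margin leaves no room inside the square")
  for (tries in seq_len(maxTries)) {
    cand <- stats::runif(2, lo, hi)
    if (placed == 0L ||
        min((pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2) >= minSpacing^2) {
      placed <- placed + 1L
      pts[placed, ] <- cand
      if (placed == k) return(pts)
    }
  }
  stop("could not place ", k, " cells with ", minSpacing,
       " um spacing in one square; lower the density or spacing")
}

#' Sample a ground-truth cell population onto the grid
#'
#' Draws cell types (exact-quota or multinomial), places cells in
#' `nRegions` randomly chosen grid squares with a minimum spacing, and
#' draws every per-cell generator parameter: the true response magnitude
#' from the type's (truncated) normal distribution, the KCN/FCCP
#' calibration plateaus (NAD(P)H) or baseline ratio (calcium), the linear
#' drift slope, and the measurement noise sd.
#'
#' @param spec a [PopulationSpec-class].
#' @param layout a [GridLayout-class].
#' @param seed optional integer seed for reproducibility.
#' @return A [S4Vectors::DataFrame] with one row per cell: `cell_id`,
#'   `type`, `x_um`, `y_um`, `square_id`, `response_param`, `baseline`,
#'   `plateau_kcn`, `plateau_fccp`, `drift_slope`, `noise_sd`, `tau_min`,
#'   `channel`.
#' @export
samplePopulation <- function(spec, layout, seed = NULL) {
  stopifnot(is(spec, "PopulationSpec"), is(layout, "GridLayout"))
  validObject(spec)
  if (!is.null(seed)) set.seed(seed)
  n <- spec@nCells
  types <- names(spec@composition)

  counts <- if (spec@samplingMode == "quota") {
    .quotaCounts(n, spec@composition)
  } else {
    as.integer(stats::rmultinom(1, n, spec@composition))
  }
  typeVec <- sample(rep(types, counts))

  nReg <- min(spec@nRegions, nSquares(layout))
  regIdx <- sample.int(nSquares(layout), nReg)
  allIds <- squareIds(layout)
  regIds <- allIds[regIdx]
  cellRegion <- regIds[rep_len(seq_len(nReg), n)[sample.int(n)]]

  s <- layout@squareSizeUm
  xy <- matrix(NA_real_, n, 2)
  for (rid in unique(cellRegion)) {
    i <- which(cellRegion == rid)
    local <- .placeCells(length(i), s, spec@edgeMarginUm, spec@minSpacingUm)
    b <- squareBounds(layout, rid)
    xy[i, 1] <- b$x0_um + local[, 1]
    xy[i, 2] <- b$y0_um + local[, 2]
  }

  resp <- numeric(n)
  for (ty in types) {
    i <- which(typeVec == ty)
    resp[i] <- .rtruncnorm(length(i), spec@responseMean[[ty]],
                           spec@responseSd[[ty]],
                           spec@responseLo[[ty]], spec@responseHi[[ty]])
  }

  if (spec@channel == "nadph") {
    fccp <- pmax(.rtruncnorm(n, spec@rfuFccp, spec@rfuFccpSd, 1, Inf), 1)
    kcn <- .rtruncnorm(n, spec@rfuKcn, spec@rfuKcnSd, -Inf, Inf)
    kcn <- pmax(kcn, fccp + 10)   # keep the calibration span positive
    blFrac <- .rtruncnorm(n, spec@baselineFrac, spec@baselineFracSd, 0.05, 0.95)
    baseline <- fccp + blFrac * (kcn - fccp)
  } else {
    fccp <- rep(NA_real_, n)
    kcn <- rep(NA_real_, n)
    baseline <- pmax(.rtruncnorm(n, spec@baselineRatio, spec@baselineRatioSd,
                                 0.2, Inf), 0.2)
  }

  S4Vectors::DataFrame(
    cell_id = sprintf("cell%04d", seq_len(n)),
    type = typeVec,
    x_um = xy[, 1], y_um = xy[, 2],
    square_id = cellRegion,
    response_param = resp,
    baseline = baseline,
    plateau_kcn = kcn,
    plateau_fccp = fccp,
    drift_slope = stats::rnorm(n, 0, spec@driftSd),
    noise_sd = rep(spec@noiseSd, n),
    tau_min = rep(spec@tauMin, n),
    channel = rep(spec@channel, n),
    row.names = sprintf("cell%04d", seq_len(n)))
}

setMethod("show", "PopulationSpec", function(object) {
  cat(sprintf("PopulationSpec: %d cells (%s channel, %s sampling)\n",
              object@nCells, object@channel, object@samplingMode))
  for (ty in names(object@composition))
    cat(sprintf("  %-6s frac %.3f  response %g +/- %g\n", ty,
                object@composition[[ty]], object@responseMean[[ty]],
                object@responseSd[[ty]]))
  cat(sprintf("  noise sd %g, drift sd %g/min, tau %g min, jitter %g um\n",
              object@noiseSd, object@driftSd, object@tauMin,
              object@jitterSdUm))
})
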