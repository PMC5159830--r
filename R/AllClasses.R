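#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData rowData<- colData<-
#' @importFrom stats rnorm runif sd setNames rmultinom
#' @importFrom utils read.csv write.csv packageVersion
NULL

.VALID_CHANNELS <- c("nadph", "calcium_ratio", "nadph_pct")
.SEGMENT_ROLES <- c("baseline", "stimulus", "recovery", "kcn", "fccp", "kcl")
.IDENTITY_LABELS <- c("beta", "alpha", "unclassified", "ambiguous", "unmatched")

#' GridLayout: fiducial grid patterned on the perifusion coverslip
#'
#' The coverslip carries a photolithographed grid of squares, each with a
#' unique row/column label, used to re-locate the same cells in the live
#' imaging session and in the post-fixation immunostaining session.
#'
#' @slot squareSizeUm side length of one grid square, in micrometres.
#' @slot nRows,nCols grid dimensions.
#'
#' @seealso [makeGridLayout()], [locateSquare()], [squareIds()]
#' @export
setClass("GridLayout",
  representation(squareSizeUm = "numeric", nRows = "integer", nCols = "integer"))

setValidity("GridLayout", function(object) {
  msg <- character()
  if (length(object@squareSizeUm) != 1L || !is.finite(object@squareSizeUm) ||
      object@squareSizeUm <= 0)
    msg <- c(msg, "squareSizeUm must be a single positive number")
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be >= 1")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Protocol: ordered perifusion segments
#'
#' A perifusion protocol is an ordered, contiguous sequence of solution
#' segments. Each segment carries the applied condition (glucose, KCN, FCCP,
#' KCl), its level (mM for glucose, a flag level otherwise), the role the
#' segment plays in the analysis (baseline, stimulus, recovery, kcn, fccp,
#' kcl) and its start/end times in minutes.
#'
#' @slot segments data.frame with columns `condition`, `level`, `role`,
#'   `start_min`, `end_min`.
#'
#' @seealso [makeProtocol()], [nadphProtocol()], [calciumProtocol()]
#' @export
setClass("Protocol", representation(segments = "data.frame"))

setValidity("Protocol", function(object) {
  seg <- object@segments
  need <- c("condition", "level", "role", "start_min", "end_min")
  if (!all(need %in% names(seg)))
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  if (nrow(seg) == 0L)
    return("protocol must contain at least one segment")
  msg <- character()
  if (!all(seg$role %in% .SEGMENT_ROLES))
    msg <- c(msg, paste("segment roles must be one of:",
                        paste(.SEGMENT_ROLES, collapse = ", ")))
  if (any(seg$start_min >= seg$end_min))
    msg <- c(msg, "each segment must have start_min < end_min")
  if (seg$start_min[1L] != 0)
    msg <- c(msg, "first segment must start at 0 min")
  if (nrow(seg) > 1L &&
      any(abs(seg$start_min[-1L] - seg$end_min[-nrow(seg)]) > 1e-9))
    msg <- c(msg, "segments must be contiguous and non-overlapping")
  if (length(msg)) msg else TRUE
})

#' PopulationSpec: generative model for a mixed cell population
#'
#' Describes a synthetic mixture of cell types plated on the gridded
#' coverslip: the composition, the per-type distribution of the true
#' functional response, the per-cell calibration plateaus (KCN/FCCP for
#' NAD(P)H; baseline ratio for calcium), measurement noise and drift, and
#' the staining model used for the post-fixation identification step.
#'
#' Response units are percent of the per-cell KCN-FCCP span for the NAD(P)H
#' channel and Fura ratio units for the calcium channel.
#'
#' @seealso [populationSpec()] for the constructor and its defaults.
#' @export
setClass("PopulationSpec",
  representation(
    nCells = "integer",
    composition = "numeric",
    responseMean = "numeric",
    responseSd = "numeric",
    responseLo = "numeric",
    responseHi = "numeric",
    samplingMode = "character",
    channel = "character",
    rfuKcn = "numeric", rfuKcnSd = "numeric",
    rfuFccp = "numeric", rfuFccpSd = "numeric",
    baselineFrac = "numeric", baselineFracSd = "numeric",
    baselineRatio = "numeric", baselineRatioSd = "numeric",
    recoveryFrac = "numeric",
    driftSd = "numeric", noiseSd = "numeric", tauMin = "numeric",
    nRegions = "integer", minSpacingUm = "numeric", edgeMarginUm = "numeric",
    unstainedFraction = "numeric", coStainFraction = "numeric",
    jitterSdUm = "numeric",
    stainHigh = "numeric", stainHighSd = "numeric",
    stainLow = "numeric", stainLowSd = "numeric"))

setValidity("PopulationSpec", function(object) {
  msg <- character()
  comp <- object@composition
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (is.null(names(comp)) || any(!nzchar(names(comp))))
    msg <- c(msg, "composition must be a named vector of type fractions")
  if (any(comp < 0) || any(comp > 1) || abs(sum(comp) - 1) > 1e-8)
    msg <- c(msg, "composition fractions must lie in [0,1] and sum to 1")
  for (nm in c("responseMean", "responseSd", "responseLo", "responseHi")) {
    v <- slot(object, nm)
    if (!all(names(comp) %in% names(v)))
      msg <- c(msg, sprintf("%s must name every type in composition", nm))
  }
  if (any(object@responseSd < 0)) msg <- c(msg, "response sds must be >= 0")
  if (!object@samplingMode %in% c("quota", "multinomial"))
    msg <- c(msg, "samplingMode must be 'quota' or 'multinomial'")
  if (!object@channel %in% c("nadph", "calcium_ratio"))
    msg <- c(msg, "channel must be 'nadph' or 'calcium_ratio'")
  for (nm in c("driftSd", "noiseSd", "jitterSdUm", "unstainedFraction",
               "coStainFraction"))
    if (slot(object, nm) < 0) msg <- c(msg, paste(nm, "must be >= 0"))
  if (object@unstainedFraction > 1 || object@coStainFraction > 1)
    msg <- c(msg, "stain fractions must be <= 1")
  if (object@rfuKcn <= object@rfuFccp)
    msg <- c(msg, "rfuKcn must exceed rfuFccp")
  if (object@rfuFccp <= 0) msg <- c(msg, "rfuFccp must be > 0")
  if (object@nRegions < 1L) msg <- c(msg, "nRegions must be >= 1")
  if (length(msg)) msg else TRUE
})

#' TraceSet: per-cell fluorescence time series
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one channel of per-cell time series: rows are cells, columns are time
#' points shared by every cell (the acquisition cycle index), and the
#' `signal` assay holds raw RFU (NAD(P)H), Fura ratios (calcium), or
#' normalized percent after KCN/FCCP calibration. Per-cell metadata (ROI
#' position, grid square, generator ground truth) lives in `rowData`;
#' acquisition times in minutes live in `colData$time_min`.
#'
#' @seealso [TraceSet()], [traceSignal()], [traceTimes()], [traceChannel()]
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

setValidity("TraceSet", function(object) {
  msg <- character()
  if (!"signal" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "TraceSet requires a 'signal' assay")
  if (ncol(object) < 2L)
    msg <- c(msg, "a TraceSet needs at least 2 time points per cell")
  tm <- colData(object)$time_min
  if (is.null(tm))
    msg <- c(msg, "colData must contain 'time_min'")
  else if (any(diff(tm) <= 0))
    msg <- c(msg, "time_min must be strictly increasing")
  ch <- metadata(object)$channel
  if (is.null(ch) || !ch %in% .VALID_CHANNELS)
    msg <- c(msg, paste("metadata()$channel must be one of:",
                        paste(.VALID_CHANNELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ClassificationReport: per-type summary with error rates
#'
#' End-product of the phenotyping pipeline: per-type cell counts, mean
#' response and SEM, the binned frequency distribution, false-positive and
#' false-negative counts and rates at the classification threshold, and the
#' cells excluded from the contrast with their reasons.
#'
#' @slot typeSummary data.frame with `label`, `n`, `mean`, `sem`.
#' @slot distribution data.frame with `label`, `bin_lo`, `bin_hi`, `count`.
#' @slot fpCount,fnCount,fpRate,fnRate error counts/rates at `threshold`.
#' @slot threshold classification threshold on the response statistic.
#' @slot excluded named integer vector of excluded-cell counts by reason.
#' @slot nTotal total number of live-imaged cells entering the pipeline.
#'
#' @seealso [classifyFpFn()], [fpRate()], [fnRate()], [typeSummary()]
#' @export
setClass("ClassificationReport",
  representation(
    typeSummary = "data.frame",
    distribution = "data.frame",
    fpCount = "integer", fnCount = "integer",
    fpRate = "numeric", fnRate = "numeric",
    threshold = "numeric",
    excluded = "integer",
    nTotal = "integer"))

setValidity("ClassificationReport", function(object) {
  msg <- character()
  rates <- c(object@fpRate, object@fnRate)
  if (any(!is.na(rates) & (rates < 0 | rates > 1)))
    msg <- c(msg, "rates must lie in [0, 1]")
  if (any(object@excluded < 0)) msg <- c(msg, "excluded counts must be >= 0")
  if (length(msg)) msg else TRUE
})
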