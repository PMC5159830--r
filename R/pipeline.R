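#' Default run configuration
#'
#' A plain named list mirroring the study defaults: 120-s sampling, 35-45
#' min steady-state windows, 4% bins over 0-52% (NAD(P)H) or 0.1-ratio
#' bins over 0-0.7 (calcium), a 4% (or 0.1) classification threshold, a
#' 10-um matching tolerance, and the 224-cell 183/32/12 population on the
#' 133 x 133 grid of 150-um squares.
#'
#' @param channel `"nadph"` or `"calcium_ratio"`.
#' @param seed integer seed for the simulate workflow.
#' @return named list; see [validateConfig()] for the required fields.
#' @export
defaultConfig <- function(channel = c("nadph", "calcium_ratio"), seed = 1L) {
  channel <- match.arg(channel)
  nadph <- channel == "nadph"
  list(
    channel = channel,
    seed = as.integer(seed),
    n_cells = 227L,
    composition = list(beta = 183 / 227, alpha = 32 / 227, other = 12 / 227),
    sampling_period_s = 120,
    n_regions = 10L,
    jitter_sd_um = 2,
    matching_tolerance_um = 10,
    insulin_threshold = 100,
    glucagon_threshold = 100,
    fpfn_threshold = if (nadph) 4 else 0.1,
    bin_width = if (nadph) 4 else 0.1,
    range_lo = 0,
    range_hi = if (nadph) 52 else 0.7,
    grid = list(square_size_um = 150, n_rows = 133L, n_cols = 133L),
    paths = list(cells = "cells.csv", traces = "traces.csv",
                 stains = "staining.csv", protocol = "protocol.json"))
}

#' Validate a run configuration
#'
#' Checks every field a workflow stage relies on; stops with a message
#' naming the first offending field.
#'
#' @param config named list as produced by [defaultConfig()] (possibly
#'   with overridden values).
#' @return the config, invisibly, if valid.
#' @export
validateConfig <- function(config) {
  fail <- function(...) stop("invalid config: ", sprintf(...), call. = FALSE)
  if (!is.list(config)) fail("config must be a list")
  need <- c("channel", "seed", "n_cells", "composition", "sampling_period_s",
            "fpfn_threshold", "bin_width", "range_lo", "range_hi", "grid")
  miss <- setdiff(need, names(config))
  if (length(miss)) fail("missing field '%s'", miss[1L])
  if (!config$channel %in% c("nadph", "calcium_ratio"))
    fail("channel must be 'nadph' or 'calcium_ratio'")
  if (!is.numeric(config$n_cells) || config$n_cells < 1)
    fail("n_cells must be >= 1")
  comp <- unlist(config$composition)
  if (is.null(names(comp)) || any(comp < 0) || abs(sum(comp) - 1) > 1e-8)
    fail("composition must be named, non-negative and sum to 1")
  if (config$sampling_period_s <= 0) fail("sampling_period_s must be > 0")
  if (config$bin_width <= 0) fail("bin_width must be > 0")
  if (config$range_lo >= config$range_hi) fail("range_lo must be < range_hi")
  g <- config$grid
  if (g$square_size_um <= 0 || g$n_rows < 1 || g$n_cols < 1)
    fail("grid dimensions must be positive")
  invisible(config)
}

#' Read a JSON run configuration
#'
#' Missing fields are filled from [defaultConfig()] for the configured
#' channel; the merged config is validated.
#'
#' @param path JSON file path.
#' @return validated config list.
#' @export
readConfig <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  channel <- if (!is.null(user$channel)) user$channel else "nadph"
  config <- defaultConfig(channel)
  config[names(user)] <- user
  validateConfig(config)
  config
}

.configObjects <- function(config) {
  g <- config$grid
  layout <- makeGridLayout(g$square_size_um, g$n_rows, g$n_cols)
  protocol <- if (config$channel == "nadph") nadphProtocol() else
    calciumProtocol()
  comp <- unlist(config$composition)
  num <- function(x) if (is.null(x)) NULL else unlist(x)
  spec <- populationSpec(channel = config$channel,
                         nCells = config$n_cells,
                         composition = comp / sum(comp),
                         responseMean = num(config$response_mean),
                         responseSd = num(config$response_sd),
                         responseLo = num(config$response_lo),
                         responseHi = num(config$response_hi),
                         nRegions = config$n_regions,
                         jitterSdUm = config$jitter_sd_um)
  list(layout = layout, protocol = protocol, spec = spec)
}

#' Simulate workflow: write a fixture bundle
#'
#' Generates a ground-truth population, its traces and staining table under
#' the configured seed and writes `cells.csv`, `traces.csv`,
#' `staining.csv`, `protocol.json` and `manifest.json` to `outDir`.
#' Re-running with the same config produces byte-identical files (the
#' manifest records the seed, config and package version, never a
#' timestamp).
#'
#' @param config validated config list ([defaultConfig()]/[readConfig()]).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the generated `cells`, `traces`,
#'   `stains` and the file paths.
#' @export
runSimulate <- function(config = defaultConfig(), outDir) {
  validateConfig(config)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  obj <- .configObjects(config)
  set.seed(config$seed)
  cells <- samplePopulation(obj$spec, obj$layout)
  ts <- simulateTraces(cells, obj$protocol,
                       samplingPeriodS = config$sampling_period_s)
  stains <- simulateStaining(cells, obj$spec, layout = obj$layout)

  p <- file.path(outDir, unlist(config$paths))
  names(p) <- names(config$paths)
  writeCellsCsv(cells, p[["cells"]])
  writeTracesCsv(ts, p[["traces"]])
  writeStainsCsv(stains, p[["stains"]])
  writeProtocolJson(obj$protocol, p[["protocol"]])

  cfgJson <- jsonlite::toJSON(config, digits = NA, auto_unbox = TRUE)
  manifest <- list(
    package = "gridPheno",
    package_version = as.character(utils::packageVersion("gridPheno")),
    seed = config$seed,
    config_md5 = unname(.md5String(cfgJson)),
    config = config,
    files = as.list(basename(p)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("simulate: %d cells in %d regions -> %s",
                  nrow(cells), length(unique(cells$square_id)), outDir))
  invisible(list(cells = cells, traces = ts, stains = stains, paths = p))
}

.md5String <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(x), f)
  tools::md5sum(f)
}

#' Analyze a population in memory
#'
#' The core pipeline: score every trace ([responseTable()]), map stain
#' identities back to live ROIs through the grid ([identityTable()]), and
#' build the per-type report ([classifyFpFn()]).
#'
#' @param cells live-imaging ROI table (`cell_id`, `x_um`, `y_um`,
#'   `square_id`).
#' @param ts a [TraceSet-class] for those cells.
#' @param stains staining table.
#' @param config config list for thresholds, binning and tolerance.
#' @param windows optional windows table overriding the channel default.
#' @return list with `responses`, `identities`, `report`
#'   (a [ClassificationReport-class]) and `pct_unclassified`.
#' @export
analyzePopulation <- function(cells, ts, stains, config = defaultConfig(),
                              windows = NULL) {
  validateConfig(config)
  responses <- responseTable(ts, windows)
  identities <- identityTable(cells, stains,
                              toleranceUm = config$matching_tolerance_um,
                              insulinThreshold = config$insulin_threshold,
                              glucagonThreshold = config$glucagon_threshold)
  report <- classifyFpFn(responses, identities,
                         threshold = config$fpfn_threshold,
                         binWidth = config$bin_width,
                         rangeLo = config$range_lo,
                         rangeHi = config$range_hi)
  list(responses = responses, identities = identities, report = report,
       pct_unclassified = exclusionSummary(identities))
}

#' Analyze workflow: traces + staining -> report bundle
#'
#' Reads the cell, trace and staining tables, runs [analyzePopulation()],
#' and writes `responses.csv`, `distribution.csv`, `report.json` and
#' `qc.csv` (excluded cells with reason codes) to `outDir`. Per-cell
#' calibration failures are summarized in the QC table, not fatal.
#'
#' @param config validated config list.
#' @param tracesFile,stainsFile,cellsFile input paths; default to the
#'   config's `paths` entries.
#' @param outDir output directory.
#' @return invisibly, the [analyzePopulation()] result list.
#' @export
runAnalyze <- function(config = defaultConfig(), tracesFile = NULL,
                       stainsFile = NULL, cellsFile = NULL, outDir) {
  validateConfig(config)
  if (is.null(tracesFile)) tracesFile <- config$paths$traces
  if (is.null(stainsFile)) stainsFile <- config$paths$stains
  if (is.null(cellsFile)) cellsFile <- config$paths$cells
  for (f in c(tracesFile, stainsFile, cellsFile))
    if (!file.exists(f)) stop("input file not found: ", f)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)

  cells <- readCellsCsv(cellsFile)
  ts <- readTracesCsv(tracesFile)
  stains <- readStainsCsv(stainsFile)
  res <- analyzePopulation(cells, ts, stains, config)

  utils::write.csv(merge(res$responses, res$identities, by = "cell_id"),
                   file.path(outDir, "responses.csv"), row.names = FALSE)
  utils::write.csv(responseDistribution(res$report),
                   file.path(outDir, "distribution.csv"), row.names = FALSE)
  writeReportJson(res$report, file.path(outDir, "report.json"))

  qc <- merge(res$responses[, c("cell_id", "qc", "statistic")],
              res$identities[, c("cell_id", "label")], by = "cell_id")
  qc$reason <- ifelse(qc$qc == "failed_calibration", "failed_calibration",
                ifelse(qc$label %in% c("beta", "alpha"), "", qc$label))
  qc <- qc[nzchar(qc$reason), c("cell_id", "label", "statistic", "reason")]
  utils::write.csv(qc, file.path(outDir, "qc.csv"), row.names = FALSE)
  for (i in seq_len(nrow(qc)))
    warning("cell ", qc$cell_id[i], " excluded: ", qc$reason[i],
            call. = FALSE)
  message(sprintf(paste0("analyze: %d cells, FP rate %s, FN rate %s, ",
                         "%d excluded -> %s"),
                  res$report@nTotal, format(fpRate(res$report), digits = 4),
                  format(fnRate(res$report), digits = 4), nrow(qc), outDir))
  invisible(res)
}
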