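#' Bin per-cell responses into a per-type frequency distribution
#'
#' Bins are left-closed, right-open, of constant width across
#' `[rangeLo, rangeHi)` (4 %-units across 0-52% for NAD(P)H, 0.1 ratio
#' units across 0-0.7 for calcium, by default in [classifyFpFn()]).
#' Values below `rangeLo` or at/above `rangeHi` are collected into
#' open-ended edge bins (`bin_lo = -Inf` / `bin_hi = Inf`) so that every
#' classified cell is counted: per-type negative responses, in particular,
#' fall in the low edge bin rather than being dropped.
#'
#' @param statistic numeric vector of per-cell response statistics.
#' @param label per-cell type labels, same length.
#' @param binWidth bin width (> 0).
#' @param rangeLo,rangeHi range covered by the regular bins; the span must
#'   be a whole number of bins.
#' @return data.frame with `label`, `bin_lo`, `bin_hi`, `count`; one row
#'   per label per bin (including empty bins).
#' @export
binResponses <- function(statistic, label, binWidth = 4,
                         rangeLo = 0, rangeHi = 52) {
  if (!is.numeric(binWidth) || binWidth <= 0)
    stop("binWidth must be > 0")
  if (rangeLo >= rangeHi) stop("rangeLo must be < rangeHi")
  nb <- (rangeHi - rangeLo) / binWidth
  if (abs(nb - round(nb)) > 1e-8)
    stop("rangeHi - rangeLo must be a whole number of bins")
  nb <- as.integer(round(nb))
  edges <- rangeLo + binWidth * (0:nb)
  lo <- c(-Inf, edges)                   # low edge bin, regular bins, high edge bin
  hi <- c(edges, Inf)
  keep <- !is.na(statistic) & !is.na(label)
  statistic <- statistic[keep]; label <- as.character(label[keep])
  labs <- sort(unique(label))
  ## bin index: 0 = low edge bin, 1..nb regular, nb+1 = high edge bin
  idx <- findInterval(statistic, edges, rightmost.closed = FALSE,
                      left.open = FALSE)
  out <- do.call(rbind, lapply(labs, function(lb) {
    counts <- tabulate(idx[label == lb] + 1L, nbins = nb + 2L)
    data.frame(label = lb, bin_lo = lo, bin_hi = hi, count = counts)
  }))
  if (is.null(out))
    out <- data.frame(label = character(), bin_lo = numeric(),
                      bin_hi = numeric(), count = integer())
  rownames(out) <- NULL
  out
}

#' Per-type response summary (n, mean, SEM)
#'
#' SEM uses the sample standard deviation (n - 1 denominator) divided by
#' `sqrt(n)`; it is `0` for a single-cell type. Labels with no cells are
#' absent from the result, not reported as zero.
#'
#' @param statistic numeric vector of per-cell response statistics.
#' @param label per-cell type labels, same length.
#' @param types preferred label order; other labels observed in the data
#'   are appended.
#' @return data.frame with `label`, `n`, `mean`, `sem`.
#' @export
summarizeByType <- function(statistic, label, types = c("beta", "alpha")) {
  keep <- !is.na(statistic) & !is.na(label)
  statistic <- statistic[keep]; label <- as.character(label[keep])
  labs <- c(intersect(types, label), setdiff(sort(unique(label)), types))
  out <- do.call(rbind, lapply(labs, function(lb) {
    x <- statistic[label == lb]
    data.frame(label = lb, n = length(x), mean = mean(x),
               sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0)
  }))
  if (is.null(out))
    out <- data.frame(label = character(), n = integer(), mean = numeric(),
                      sem = numeric())
  rownames(out) <- NULL
  out
}

#' Classify responses against identities and report error rates
#'
#' A false positive is a glucagon-stained (alpha) cell whose response
#' statistic reaches the threshold, i.e. responds like a beta cell; a
#' false negative is an insulin-stained (beta) cell whose statistic falls
#' below it. Rates are relative to each label's classified-cell count.
#' Cells labelled `unclassified` (hormone-negative), `ambiguous`
#' (double-positive) or `unmatched`, and cells with a failed KCN/FCCP
#' calibration, are excluded from the contrast and tallied in the report's
#' `excluded` counts.
#'
#' @param responses response table from [responseTable()] (columns
#'   `cell_id`, `statistic`, `qc`).
#' @param identities identity table from [identityTable()] (columns
#'   `cell_id`, `label`).
#' @param threshold response threshold separating beta-like from alpha-like
#'   behaviour. The default, 4 (one NAD(P)H bin width, in % of the
#'   KCN-FCCP span), reflects the observation that no insulinoma cell
#'   responds below 4%. Use a ratio-unit value for the calcium channel.
#' @param binWidth,rangeLo,rangeHi frequency-distribution binning, passed
#'   to [binResponses()].
#' @return A [ClassificationReport-class].
#' @export
classifyFpFn <- function(responses, identities, threshold = 4,
                         binWidth = 4, rangeLo = 0, rangeHi = 52) {
  df <- merge(responses, identities, by = "cell_id", all.x = TRUE,
              sort = FALSE)
  df$label[is.na(df$label)] <- "unmatched"
  failedCal <- !is.na(df$qc) & df$qc == "failed_calibration"
  excluded <- c(
    unclassified = sum(df$label == "unclassified"),
    ambiguous = sum(df$label == "ambiguous"),
    unmatched = sum(df$label == "unmatched"),
    failed_calibration = sum(failedCal & df$label %in% c("beta", "alpha")))
  use <- df$label %in% c("beta", "alpha") & !failedCal & !is.na(df$statistic)
  cls <- df[use, ]
  nBeta <- sum(cls$label == "beta")
  nAlpha <- sum(cls$label == "alpha")
  fp <- sum(cls$label == "alpha" & cls$statistic >= threshold)
  fn <- sum(cls$label == "beta" & cls$statistic < threshold)
  new("ClassificationReport",
      typeSummary = summarizeByType(cls$statistic, cls$label),
      distribution = binResponses(cls$statistic, cls$label, binWidth,
                                  rangeLo, rangeHi),
      fpCount = as.integer(fp), fnCount = as.integer(fn),
      fpRate = if (nAlpha > 0) fp / nAlpha else NA_real_,
      fnRate = if (nBeta > 0) fn / nBeta else NA_real_,
      threshold = threshold,
      excluded = excluded,
      nTotal = nrow(df))
}

#' Percentage of cells not definitively classified
#'
#' @param identities identity table from [identityTable()].
#' @param excludedLabels labels counted as not definitively classified.
#' @param digits rounding for display (default nearest integer); use
#'   `NULL` for the exact percentage.
#' @return percentage of all imaged cells.
#' @export
exclusionSummary <- function(identities,
                             excludedLabels = c("unclassified", "ambiguous",
                                                "unmatched"),
                             digits = 0) {
  if (nrow(identities) == 0L) stop("identity table is empty")
  pct <- 100 * sum(identities$label %in% excludedLabels) / nrow(identities)
  if (is.null(digits)) pct else round(pct, digits)
}

#' ClassificationReport accessors
#' @param report a [ClassificationReport-class].
#' @return the corresponding slot value.
#' @export
fpRate <- function(report) { stopifnot(is(report, "ClassificationReport")); report@fpRate }

#' @rdname fpRate
#' @export
fnRate <- function(report) { stopifnot(is(report, "ClassificationReport")); report@fnRate }

#' @rdname fpRate
#' @export
fpCount <- function(report) { stopifnot(is(report, "ClassificationReport")); report@fpCount }

#' @rdname fpRate
#' @export
fnCount <- function(report) { stopifnot(is(report, "ClassificationReport")); report@fnCount }

#' @rdname fpRate
#' @export
typeSummary <- function(report) { stopifnot(is(report, "ClassificationReport")); report@typeSummary }

#' @rdname fpRate
#' @export
responseDistribution <- function(report) { stopifnot(is(report, "ClassificationReport")); report@distribution }

#' @rdname fpRate
#' @export
excludedCounts <- function(report) { stopifnot(is(report, "ClassificationReport")); report@excluded }

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport: %d cells, threshold %g\n",
              object@nTotal, object@threshold))
  ts <- object@typeSummary
  for (i in seq_len(nrow(ts)))
    cat(sprintf("  %-12s n = %3d  mean %7.3f  SEM %6.3f\n",
                ts$label[i], ts$n[i], ts$mean[i], ts$sem[i]))
  cat(sprintf("  false positives: %d (rate %s)   false negatives: %d (rate %s)\n",
              object@fpCount, format(object@fpRate, digits = 4),
              object@fnCount, format(object@fnRate, digits = 4)))
  ex <- object@excluded
  cat("  excluded:", paste(sprintf("%s %d", names(ex), ex), collapse = ", "),
      "\n")
})
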