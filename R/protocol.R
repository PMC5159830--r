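#' Construct a perifusion protocol
#'
#' @param condition character vector of applied conditions
#'   (e.g. "glucose", "KCN", "FCCP", "KCl").
#' @param level numeric level per segment (mM for glucose; 1 for inhibitor /
#'   uncoupler / depolarization segments).
#' @param role analysis role per segment: one of `"baseline"`, `"stimulus"`,
#'   `"recovery"`, `"kcn"`, `"fccp"`, `"kcl"`.
#' @param startMin,endMin segment boundaries in minutes; segments must be
#'   contiguous and the first must start at 0.
#' @return A [Protocol-class].
#' @export
makeProtocol <- function(condition, level, role, startMin, endMin) {
  seg <- data.frame(condition = as.character(condition),
                    level = as.numeric(level),
                    role = as.character(role),
                    start_min = as.numeric(startMin),
                    end_min = as.numeric(endMin))
  new("Protocol", segments = seg)
}

#' Standard NAD(P)H perifusion protocol
#'
#' Glucose is stepped 3 -> 20 -> 3 mM, followed by KCN (drives NAD(P)H to
#' its maximal plateau, the 100% calibration anchor) and then FCCP (minimal
#' plateau, the 0% anchor). Segment lengths leave the 35-45 min steady-state
#' windows after each glucose transition well inside their segments.
#'
#' @param lowGlucose,highGlucose glucose levels in mM.
#' @return A [Protocol-class] spanning 0-155 min.
#' @export
nadphProtocol <- function(lowGlucose = 3, highGlucose = 20) {
  makeProtocol(
    condition = c("glucose", "glucose", "glucose", "KCN", "FCCP"),
    level     = c(lowGlucose, highGlucose, lowGlucose, 1, 1),
    role      = c("baseline", "stimulus", "recovery", "kcn", "fccp"),
    startMin  = c(0, 15, 65, 115, 135),
    endMin    = c(15, 65, 115, 135, 155))
}

#' Standard calcium perifusion protocol
#'
#' Glucose is stepped 4 -> 20 -> 4 mM; a terminal KCl segment depolarizes
#' every cell. Calcium responses are scored from the baseline and stimulated
#' windows only (the ratio does not fully return to baseline, so no
#' down-step term is used).
#'
#' @param lowGlucose,highGlucose glucose levels in mM.
#' @return A [Protocol-class] spanning 0-125 min.
#' @export
calciumProtocol <- function(lowGlucose = 4, highGlucose = 20) {
  makeProtocol(
    condition = c("glucose", "glucose", "glucose", "KCl"),
    level     = c(lowGlucose, highGlucose, lowGlucose, 30),
    role      = c("baseline", "stimulus", "recovery", "kcl"),
    startMin  = c(0, 15, 65, 115),
    endMin    = c(15, 65, 115, 125))
}

#' Protocol segments and duration
#' @param protocol a [Protocol-class].
#' @return `protocolSegments()`: the segment data.frame; `protocolEnd()`:
#'   the protocol duration in minutes.
#' @export
protocolSegments <- function(protocol) {
  stopifnot(is(protocol, "Protocol"))
  protocol@segments
}

#' @rdname protocolSegments
#' @export
protocolEnd <- function(protocol) {
  stopifnot(is(protocol, "Protocol"))
  max(protocol@segments$end_min)
}

#' Default steady-state analysis windows for a protocol
#'
#' Windows are closed intervals `[start_min, end_min]` in minutes. For the
#' NAD(P)H channel: the baseline window is the last 10 min of the initial
#' glucose segment; the high-glucose and post-return windows span 35-45 min
#' after the respective glucose transition; the KCN and FCCP calibration
#' windows are the final minutes of their segments, where the plateau has
#' been reached. A 1-min guard keeps windows clear of segment boundaries so
#' no sample straddles a solution change. For the calcium channel only the
#' baseline and stimulated windows are produced.
#'
#' @param protocol a [Protocol-class].
#' @param channel `"nadph"` or `"calcium_ratio"`.
#' @param ssStart,ssEnd steady-state window placement, minutes after the
#'   glucose transition (defaults 35 and 45).
#' @param baselineLen baseline window length in minutes.
#' @param calLen KCN/FCCP calibration window length in minutes.
#' @param guard clearance from segment boundaries in minutes.
#' @return data.frame with columns `label`, `start_min`, `end_min`.
#' @export
analysisWindows <- function(protocol, channel = c("nadph", "calcium_ratio"),
                            ssStart = 35, ssEnd = 45,
                            baselineLen = 10, calLen = 7, guard = 1) {
  channel <- match.arg(channel)
  seg <- protocolSegments(protocol)
  segWin <- function(role) {
    i <- which(seg$role == role)
    if (length(i) == 0L) stop("protocol has no '", role, "' segment")
    seg[i[1L], ]
  }
  bl <- segWin("baseline")
  stim <- segWin("stimulus")
  win <- data.frame(label = "baseline",
                    start_min = bl$end_min - guard - baselineLen,
                    end_min = bl$end_min - guard)
  high <- data.frame(label = "high_glucose",
                     start_min = stim$start_min + ssStart,
                     end_min = stim$start_min + ssEnd)
  win <- rbind(win, high)
  if (channel == "nadph") {
    rec <- segWin("recovery"); kcn <- segWin("kcn"); fccp <- segWin("fccp")
    win <- rbind(win,
      data.frame(label = "post_return",
                 start_min = rec$start_min + ssStart,
                 end_min = rec$start_min + ssEnd),
      data.frame(label = "kcn",
                 start_min = kcn$end_min - guard - calLen,
                 end_min = kcn$end_min - guard),
      data.frame(label = "fccp",
                 start_min = fccp$end_min - guard - calLen,
                 end_min = fccp$end_min - guard))
  } else {
    win$label <- c("baseline", "stimulated")
  }
  endMin <- protocolEnd(protocol)
  if (any(win$start_min < 0) || any(win$end_min > endMin) ||
      any(win$start_min >= win$end_min))
    stop("analysis windows fall outside the protocol time range")
  rownames(win) <- win$label
  win
}

#' Read/write a protocol as JSON
#' @param protocol a [Protocol-class].
#' @param path file path.
#' @export
writeProtocolJson <- function(protocol, path) {
  stopifnot(is(protocol, "Protocol"))
  jsonlite::write_json(protocolSegments(protocol), path,
                       digits = NA, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeProtocolJson
#' @export
readProtocolJson <- function(path) {
  seg <- jsonlite::read_json(path, simplifyVector = TRUE)
  makeProtocol(seg$condition, seg$level, seg$role, seg$start_min, seg$end_min)
}

setMethod("show", "Protocol", function(object) {
  seg <- object@segments
  cat(sprintf("Protocol: %d segments, %g min total\n", nrow(seg),
              protocolEnd(object)))
  for (i in seq_len(nrow(seg)))
    cat(sprintf("  %6.1f-%6.1f min  %-8s level %g  [%s]\n",
                seg$start_min[i], seg$end_min[i], seg$condition[i],
                seg$level[i], seg$role[i]))
})
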