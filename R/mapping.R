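#' Estimate the rigid offset between live and stained centroids in a square
#'
#' Finds the translation `o` (stained ~ live + o) minimizing the sum over
#' live centroids of the squared distance to the nearest stained centroid
#' after the shift, with each per-cell term truncated at `capUm` so that
#' cells with no counterpart in the other session (lost or extra records)
#' contribute a constant instead of dragging the optimum toward them
#' (trimmed least squares, the standard robustification in point-set
#' registration). The search covers +/- half a square side and reaches
#' 1-um resolution via a coarse 5-um pass refined at 1 um around the coarse
#' optimum (the truncated cost is smooth at the jitter scales the matcher
#' tolerates, so the refinement locates the same optimum as a flat 1-um
#' search at a fraction of the cost). Returns `c(0, 0)` when either side is
#' empty.
#'
#' @param liveXY,stainXY numeric matrices (n x 2) of centroids in
#'   micrometres.
#' @param halfRangeUm half-width of the search range (default 75, half the
#'   standard square side).
#' @param coarseUm,fineUm grid steps of the two passes.
#' @param capUm truncation distance of the per-cell cost (default the
#'   standard matching tolerance, 10 um).
#' @return numeric `c(dx, dy)`: the displacement from live to stained
#'   coordinates.
#' @export
estimateSquareOffset <- function(liveXY, stainXY, halfRangeUm = 75,
                                 coarseUm = 5, fineUm = 1, capUm = 10) {
  liveXY <- matrix(as.numeric(liveXY), ncol = 2)
  stainXY <- matrix(as.numeric(stainXY), ncol = 2)
  n <- nrow(liveXY); m <- nrow(stainXY)
  if (n == 0L || m == 0L) return(c(0, 0))

  cost <- function(ox, oy) {
    ## candidate offsets (K) x stained (m) nearest-neighbour cost per live
    K <- length(ox)
    total <- numeric(K)
    for (i in seq_len(n)) {
      dx <- stainXY[, 1] - liveXY[i, 1]   # target displacement per stain
      dy <- stainXY[, 2] - liveXY[i, 2]
      d2 <- (matrix(dx, K, m, byrow = TRUE) - ox)^2 +
            (matrix(dy, K, m, byrow = TRUE) - oy)^2
      total <- total + pmin(do.call(pmin, as.data.frame(d2)), capUm^2)
    }
    total
  }
  searchGrid <- function(cx, cy, half, step) {
    g <- seq(-half, half, by = step)
    cand <- expand.grid(ox = cx + g, oy = cy + g)
    tot <- cost(cand$ox, cand$oy)
    best <- which.min(tot)
    c(cand$ox[best], cand$oy[best])
  }
  o <- searchGrid(0, 0, halfRangeUm, coarseUm)
  searchGrid(o[1L], o[2L], coarseUm, fineUm)
}

## greedy one-to-one matching by ascending distance within a square,
## after shifting live centroids by the estimated offset
.greedyMatch <- function(liveXY, stainXY, offset, toleranceUm) {
  n <- nrow(liveXY); m <- nrow(stainXY)
  match <- rep(NA_integer_, n)
  dist <- rep(NA_real_, n)
  if (n == 0L || m == 0L) return(list(match = match, dist = dist))
  shifted <- sweep(liveXY, 2, -offset)  # live + offset
  d <- sqrt(outer(shifted[, 1], stainXY[, 1], "-")^2 +
            outer(shifted[, 2], stainXY[, 2], "-")^2)
  ord <- order(d)
  usedL <- rep(FALSE, n); usedS <- rep(FALSE, m)
  for (k in ord) {
    if (d[k] > toleranceUm) break
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    if (usedL[i] || usedS[j]) next
    usedL[i] <- TRUE; usedS[j] <- TRUE
    match[i] <- j; dist[i] <- d[k]
  }
  list(match = match, dist = dist)
}

#' Match live-imaging cells to post-fixation stain records
#'
#' Matching is per grid square: the fiducial grid guarantees that a square
#' identifier refers to the same physical region in both imaging sessions,
#' so cross-square matches are disallowed. Within each square the rigid
#' offset between sessions is estimated with [estimateSquareOffset()], then
#' cells and stain records are paired greedily in ascending distance order,
#' one-to-one, discarding pairs farther apart than `toleranceUm`.
#'
#' @param cells live-imaging cell table (`cell_id`, `x_um`, `y_um`,
#'   `square_id`).
#' @param stains stain table (`stain_id`, `x_um`, `y_um`, `square_id`,
#'   `insulin`, `glucagon`).
#' @param toleranceUm maximum accepted match distance (default 10, about
#'   one cell radius).
#' @return data.frame, one row per live cell: `cell_id`, `square_id`,
#'   `stain_id` (`NA` if unmatched), `distance_um`, `offset_x_um`,
#'   `offset_y_um`.
#' @export
matchCells <- function(cells, stains, toleranceUm = 10) {
  cells <- as.data.frame(cells[, c("cell_id", "x_um", "y_um", "square_id")])
  out <- data.frame(cell_id = as.character(cells$cell_id),
                    square_id = as.character(cells$square_id),
                    stain_id = NA_character_,
                    distance_um = NA_real_,
                    offset_x_um = 0, offset_y_um = 0,
                    stringsAsFactors = FALSE)
  for (sq in unique(cells$square_id)) {
    li <- which(cells$square_id == sq)
    si <- which(stains$square_id == sq)
    liveXY <- cbind(cells$x_um[li], cells$y_um[li])
    stainXY <- cbind(stains$x_um[si], stains$y_um[si])
    off <- estimateSquareOffset(liveXY, stainXY, capUm = max(toleranceUm, 1))
    g <- .greedyMatch(liveXY, stainXY, off, toleranceUm)
    out$stain_id[li] <- ifelse(is.na(g$match), NA_character_,
                               as.character(stains$stain_id[si][g$match]))
    out$distance_um[li] <- g$dist
    out$offset_x_um[li] <- off[1L]
    out$offset_y_um[li] <- off[2L]
  }
  out
}

#' Assign a cell-type label from stain intensities
#'
#' Insulin-positive only: `beta`; glucagon-positive only: `alpha`; neither:
#' `unclassified` (hormone-negative); both: `ambiguous` (double-positive
#' records are excluded from type statistics and reported separately);
#' missing record: `unmatched`.
#'
#' @param insulin,glucagon stain intensities (a.u.); `NA` means no record.
#' @param insulinThreshold,glucagonThreshold positivity thresholds (a.u.).
#' @return character vector of labels.
#' @export
assignIdentity <- function(insulin, glucagon,
                           insulinThreshold = 100, glucagonThreshold = 100) {
  if (insulinThreshold <= 0 || glucagonThreshold <= 0)
    stop("thresholds must be > 0")
  insPos <- insulin >= insulinThreshold
  glcPos <- glucagon >= glucagonThreshold
  out <- ifelse(insPos & glcPos, "ambiguous",
         ifelse(insPos, "beta",
         ifelse(glcPos, "alpha", "unclassified")))
  out[is.na(insulin) | is.na(glucagon)] <- "unmatched"
  out
}

#' Identity table for a matched population
#'
#' Combines [matchCells()] and [assignIdentity()]: every live cell appears
#' exactly once with its immunostain-derived label.
#'
#' @inheritParams matchCells
#' @inheritParams assignIdentity
#' @return data.frame with `cell_id`, `label`, `stain_id`, `distance_um`.
#' @export
identityTable <- function(cells, stains, toleranceUm = 10,
                          insulinThreshold = 100, glucagonThreshold = 100) {
  mt <- matchCells(cells, stains, toleranceUm)
  idx <- match(mt$stain_id, stains$stain_id)
  label <- assignIdentity(stains$insulin[idx], stains$glucagon[idx],
                          insulinThreshold, glucagonThreshold)
  data.frame(cell_id = mt$cell_id, label = label,
             stain_id = mt$stain_id, distance_um = mt$distance_um,
             stringsAsFactors = FALSE)
}
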