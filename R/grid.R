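#' Construct a coverslip grid layout
#'
#' The default reproduces the patterned perifusion coverslip: a 133 x 133
#' grid (17,689 squares) of 150-um squares, each square addressable by a
#' unique "row-col" label. Coordinates are in micrometres with the origin at
#' the grid's top-left corner and y increasing downward (image convention).
#'
#' @param squareSizeUm side length of one square in micrometres.
#' @param nRows,nCols number of grid rows and columns.
#' @return A [GridLayout-class] object.
#' @examples
#' layout <- makeGridLayout()
#' nSquares(layout)          # 17689
#' locateSquare(layout, 160, 40)  # "1-2": row 1, column 2
#' @export
makeGridLayout <- function(squareSizeUm = 150, nRows = 133L, nCols = 133L) {
  if (!is.numeric(squareSizeUm) || length(squareSizeUm) != 1L ||
      !is.finite(squareSizeUm) || squareSizeUm <= 0)
    stop("squareSizeUm must be a single positive number")
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  if (is.na(nRows) || nRows < 1L || is.na(nCols) || nCols < 1L)
    stop("nRows and nCols must be integers >= 1")
  new("GridLayout", squareSizeUm = squareSizeUm, nRows = nRows, nCols = nCols)
}

#' Number of squares in a grid layout
#' @param layout a [GridLayout-class].
#' @return integer count `nRows * nCols`.
#' @export
nSquares <- function(layout) {
  stopifnot(is(layout, "GridLayout"))
  as.integer(layout@nRows) * as.integer(layout@nCols)
}

#' @rdname nSquares
#' @export
gridRows <- function(layout) { stopifnot(is(layout, "GridLayout")); layout@nRows }

#' @rdname nSquares
#' @export
gridCols <- function(layout) { stopifnot(is(layout, "GridLayout")); layout@nCols }

#' @rdname nSquares
#' @export
squareSize <- function(layout) { stopifnot(is(layout, "GridLayout")); layout@squareSizeUm }

#' Square labels
#'
#' Each square is addressed as `"row-col"`, mirroring the dual number labels
#' etched in opposite corners of every square on the physical coverslip.
#'
#' @param layout a [GridLayout-class].
#' @param row,col vectors of 1-based row/column indices (recycled).
#' @return character vector of unique square identifiers.
#' @export
squareLabel <- function(layout, row, col) {
  stopifnot(is(layout, "GridLayout"))
  row <- as.integer(row); col <- as.integer(col)
  if (any(is.na(row)) || any(is.na(col)) ||
      any(row < 1L) || any(row > layout@nRows) ||
      any(col < 1L) || any(col > layout@nCols))
    stop("row/col indices outside the grid")
  sprintf("%d-%d", row, col)
}

#' All square identifiers of a layout, row-major
#' @inheritParams squareLabel
#' @export
squareIds <- function(layout) {
  stopifnot(is(layout, "GridLayout"))
  idx <- expand.grid(col = seq_len(layout@nCols), row = seq_len(layout@nRows))
  sprintf("%d-%d", idx$row, idx$col)
}

#' Map positions to grid squares
#'
#' @param layout a [GridLayout-class].
#' @param xUm,yUm coordinates in micrometres (grid origin top-left, y down).
#'   A point on a shared edge belongs to the square below/right of the edge,
#'   except on the outer boundary which belongs to the last square.
#' @return character vector of square identifiers.
#' @export
locateSquare <- function(layout, xUm, yUm) {
  stopifnot(is(layout, "GridLayout"))
  s <- layout@squareSizeUm
  w <- layout@nCols * s; h <- layout@nRows * s
  if (any(xUm < 0 | xUm > w | yUm < 0 | yUm > h))
    stop("position outside the gridded area")
  col <- pmin(floor(xUm / s) + 1L, layout@nCols)
  row <- pmin(floor(yUm / s) + 1L, layout@nRows)
  sprintf("%d-%d", row, col)
}

#' Bounding box of a grid square
#'
#' @param layout a [GridLayout-class].
#' @param squareId square identifier(s) as produced by [squareLabel()].
#' @return data.frame with `square_id`, `x0_um`, `y0_um` (top-left corner),
#'   `x1_um`, `y1_um`.
#' @export
squareBounds <- function(layout, squareId) {
  stopifnot(is(layout, "GridLayout"))
  parts <- strsplit(as.character(squareId), "-", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad)) stop("malformed square identifier: ", squareId[bad][1L])
  row <- as.integer(vapply(parts, `[`, "", 1L))
  col <- as.integer(vapply(parts, `[`, "", 2L))
  if (any(is.na(row) | is.na(col) | row < 1L | row > layout@nRows |
          col < 1L | col > layout@nCols))
    stop("square identifier outside the grid")
  s <- layout@squareSizeUm
  data.frame(square_id = as.character(squareId),
             x0_um = (col - 1L) * s, y0_um = (row - 1L) * s,
             x1_um = col * s, y1_um = row * s)
}

setMethod("show", "GridLayout", function(object) {
  cat(sprintf("GridLayout: %d x %d squares of %g um (%d squares, %.1f x %.1f mm)\n",
              object@nRows, object@nCols, object@squareSizeUm,
              nSquares(object),
              object@nCols * object@squareSizeUm / 1000,
              object@nRows * object@squareSizeUm / 1000))
})
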