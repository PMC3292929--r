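#' Accessors for gridded objects
#'
#' `gridValues()` returns the value matrix, `gridSpec()` the shared grid
#' geometry of any raster-backed object in the package.
#'
#' @param x a [GridRaster-class], [FrictionSurface-class],
#'   [CatchmentSet-class] or [GridSpec-class] holder
#' @return a matrix (`gridValues`) or a [GridSpec-class] (`gridSpec`)
#' @aliases gridValues gridSpec
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname gridValues
setMethod("gridValues", "GridRaster", function(x) x@values)
#' @rdname gridValues
setMethod("gridSpec", "GridRaster", function(x) x@spec)
#' @rdname gridValues
setMethod("gridSpec", "FrictionSurface", function(x) x@spec)
#' @rdname gridValues
setMethod("gridSpec", "CatchmentSet", function(x) x@spec)
#' @rdname gridValues
setMethod("gridValues", "CatchmentSet", function(x) x@membership)

#' Speed, mode and barrier accessors for a friction surface
#'
#' @param x a [FrictionSurface-class]
#' @return a matrix of speeds (km/h), integer mode codes, or logicals
#' @export
frictionSpeed <- function(x) x@speed

#' @rdname frictionSpeed
#' @export
frictionMode <- function(x) x@mode

#' @rdname frictionSpeed
#' @export
frictionBarrier <- function(x) x@barrier

same_grid <- function(a, b) {
  isTRUE(all.equal(c(a@nrows, a@ncols, a@cellSize, a@originX, a@originY),
                   c(b@nrows, b@ncols, b@cellSize, b@originX, b@originY)))
}

stop_if_grid_mismatch <- function(..., what = "inputs") {
  specs <- list(...)
  for (i in seq_along(specs)[-1])
    if (!same_grid(specs[[1]], specs[[i]]))
      stop(sprintf("%s do not share a common grid (input 1 vs input %d)",
                   what, i), call. = FALSE)
  invisible(TRUE)
}

#' Cell centre coordinates of a grid
#'
#' Row 1 is the northernmost row. Returns the planar (x, y) centre of each
#' requested cell.
#'
#' @param spec a [GridSpec-class]
#' @param row,col cell indices (1-based); vectors are recycled together
#' @return a two-column matrix of x and y in metres
#' @export
cellCenter <- function(spec, row, col) {
  x <- spec@originX + (col - 0.5) * spec@cellSize
  y <- spec@originY + (spec@nrows - row + 0.5) * spec@cellSize
  cbind(x = x, y = y)
}

#' Locate points on a grid
#'
#' @param spec a [GridSpec-class]
#' @param x,y planar coordinates in metres
#' @return a two-column matrix of row and col indices; an error if any point
#'   falls outside the grid extent
#' @export
cellFromXY <- function(spec, x, y) {
  col <- floor((x - spec@originX) / spec@cellSize) + 1
  row <- spec@nrows - floor((y - spec@originY) / spec@cellSize)
  # points exactly on the top/right edge belong to the last cell
  col[x == spec@originX + spec@ncols * spec@cellSize] <- spec@ncols
  row[y == spec@originY + spec@nrows * spec@cellSize] <- 1
  bad <- col < 1 | col > spec@ncols | row < 1 | row > spec@nrows
  if (any(bad))
    stop(sprintf("%d point(s) fall outside the grid extent", sum(bad)),
         call. = FALSE)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Finite-difference slope of an elevation raster
#'
#' Maximum absolute slope, in degrees, over the eight neighbour edges of
#' each cell (diagonal run length cellSize * sqrt(2)). Used for reporting
#' and fixtures; the travel-time engine computes slope per edge itself.
#'
#' @param dem a [GridRaster-class] of elevation in metres
#' @return a [GridRaster-class] of slope in degrees
#' @export
slopeRaster <- function(dem) {
  z <- dem@values
  cs <- dem@spec@cellSize
  nr <- nrow(z); nc <- ncol(z)
  best <- matrix(0, nr, nc)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (s in shifts) {
    d <- cs * if (s[1] != 0 && s[2] != 0) sqrt(2) else 1
    rows <- seq_len(nr) + s[1]; cols <- seq_len(nc) + s[2]
    ok_r <- rows >= 1 & rows <= nr; ok_c <- cols >= 1 & cols <= nc
    dz <- matrix(NA_real_, nr, nc)
    dz[ok_r, ok_c] <- z[rows[ok_r], cols[ok_c]] - z[ok_r, ok_c]
    sl <- atan2(abs(dz), d) * 180 / pi
    best <- pmax(best, sl, na.rm = TRUE)
  }
  GridRaster(best, dem@spec)
}
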