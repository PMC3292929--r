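#' @import methods
#' @importFrom stats median quantile rbinom rnorm runif rpois coef deviance
#'   qnorm cor optim setNames aggregate
#' @importFrom utils read.csv write.csv
#' @useDynLib AccessBurden, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Transport-mode codes; must match src/dijkstra.cpp
MODE_NONE <- 0L
MODE_WALKING <- 1L
MODE_CYCLING <- 2L
MODE_MOTORIZED <- 3L
MODE_LEVELS <- c(NONE = 0L, WALKING = 1L, CYCLING = 2L, MOTORIZED = 3L)

#' GridSpec: geometry shared by every raster in an analysis
#'
#' All rasters in one scenario live on a single planar projected grid
#' (coordinates in metres). Rows run north to south: row 1 is the top
#' (highest y) row, matching the usual raster file convention.
#'
#' @slot nrows,ncols grid dimensions (each at least 2)
#' @slot cellSize cell edge length in metres (default 1000, i.e. 1 km pixels)
#' @slot originX,originY coordinates of the lower-left corner of the grid
#' @slot nodata sentinel value used when writing rasters to disk
#' @exportClass GridSpec
setClass("GridSpec",
  representation(nrows = "integer", ncols = "integer", cellSize = "numeric",
                 originX = "numeric", originY = "numeric", nodata = "numeric"),
  prototype(cellSize = 1000, originX = 0, originY = 0, nodata = -9999))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nrows) != 1L || is.na(object@nrows) || object@nrows < 2L)
    msg <- c(msg, "nrows must be a single integer >= 2")
  if (length(object@ncols) != 1L || is.na(object@ncols) || object@ncols < 2L)
    msg <- c(msg, "ncols must be a single integer >= 2")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param nrows,ncols grid dimensions
#' @param cellSize cell edge in metres
#' @param originX,originY lower-left corner coordinates (metres)
#' @param nodata nodata sentinel for file output
#' @return a [GridSpec-class] object
#' @examples
#' GridSpec(50, 50)
#' @export
GridSpec <- function(nrows, ncols, cellSize = 1000, originX = 0, originY = 0,
                     nodata = -9999) {
  new("GridSpec", nrows = as.integer(nrows), ncols = as.integer(ncols),
      cellSize = as.numeric(cellSize), originX = as.numeric(originX),
      originY = as.numeric(originY), nodata = as.numeric(nodata))
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g m, origin (%g, %g)\n",
              object@nrows, object@ncols, object@cellSize,
              object@originX, object@originY))
})

#' GridRaster: a single-band raster on a GridSpec
#'
#' Values are stored as a matrix with `nrows` rows and `ncols` columns;
#' `values[1, 1]` is the north-west cell.
#'
#' @slot values numeric matrix of cell values
#' @slot spec the [GridSpec-class] geometry
#' @exportClass GridRaster
setClass("GridRaster",
  representation(values = "matrix", spec = "GridSpec"))

setValidity("GridRaster", function(object) {
  if (nrow(object@values) != object@spec@nrows ||
      ncol(object@values) != object@spec@ncols)
    return("values matrix does not match the GridSpec dimensions")
  TRUE
})

#' Construct a GridRaster
#'
#' @param values numeric matrix (nrows x ncols), or a single value recycled
#' @param spec a [GridSpec-class]
#' @return a [GridRaster-class]
#' @examples
#' g <- GridSpec(4, 5)
#' GridRaster(0, g)
#' @export
GridRaster <- function(values, spec) {
  if (length(values) == 1L)
    values <- matrix(values, spec@nrows, spec@ncols)
  new("GridRaster", values = as.matrix(values), spec = spec)
}

setMethod("show", "GridRaster", function(object) {
  v <- object@values
  fin <- v[is.finite(v)]
  cat(sprintf("GridRaster on %d x %d grid (%g m cells)\n",
              object@spec@nrows, object@spec@ncols, object@spec@cellSize))
  if (length(fin))
    cat(sprintf("  finite values: %d, range [%g, %g]\n",
                length(fin), min(fin), max(fin)))
})

#' FrictionSurface: per-pixel permissible speed, mode and barrier mask
#'
#' The "cost" grid: each cell carries the maximum permissible travel speed
#' (km/h), the transport mode that applies there, and a barrier flag.
#' Barrier cells (water, rivers) have speed 0 and are excluded from the
#' travel-time graph.
#'
#' @slot speed numeric matrix of km/h (0 on barriers)
#' @slot mode integer matrix of mode codes (0 NONE, 1 WALKING, 2 CYCLING,
#'   3 MOTORIZED)
#' @slot barrier logical matrix
#' @slot spec the shared [GridSpec-class]
#' @exportClass FrictionSurface
setClass("FrictionSurface",
  representation(speed = "matrix", mode = "matrix", barrier = "matrix",
                 spec = "GridSpec"))

setValidity("FrictionSurface", function(object) {
  d <- c(object@spec@nrows, object@spec@ncols)
  for (s in c("speed", "mode", "barrier"))
    if (!identical(dim(slot(object, s)), as.integer(d)))
      return(sprintf("slot '%s' does not match the GridSpec dimensions", s))
  if (any(object@speed[!object@barrier] <= 0))
    return("non-barrier cells must have strictly positive speed")
  if (any(object@speed[object@barrier] != 0))
    return("barrier cells must have speed 0")
  if (any(object@barrier != (object@mode == MODE_NONE)))
    return("barrier mask must coincide with mode NONE")
  TRUE
})

setMethod("show", "FrictionSurface", function(object) {
  cat(sprintf("FrictionSurface on %d x %d grid: speeds %g-%g km/h, %d barrier cells\n",
              object@spec@nrows, object@spec@ncols,
              min(object@speed[!object@barrier]),
              max(object@speed[!object@barrier]), sum(object@barrier)))
})

#' TravelTimeSurface: minutes to the least-cost nearest facility
#'
#' Cells not connected to any facility carry `Inf`.
#'
#' @exportClass TravelTimeSurface
setClass("TravelTimeSurface", contains = "GridRaster")

setValidity("TravelTimeSurface", function(object) {
  v <- object@values
  if (any(v[!is.na(v)] < 0)) return("travel times must be non-negative")
  TRUE
})

#' AllocationSurface: id of the least-cost nearest facility per cell
#'
#' Unreached cells carry `NA`. A cell has an allocation exactly when its
#' travel time is finite.
#'
#' @exportClass AllocationSurface
setClass("AllocationSurface", contains = "GridRaster")

#' DecayModel: three-parameter logistic distance decay
#'
#' Attendance probability against transformed travel time x:
#' \deqn{Y = C / (1 + e^{(A - x)/B})}
#' where C is the limiting probability (upper asymptote), A the inflection
#' location on the transformed scale and B the decay parameter (negative for
#' a decreasing curve).
#'
#' @slot C,A,B model coefficients
#' @slot transform one of "log10", "ln", "identity" (applied to minutes)
#' @slot tFloor minutes floor guarding the log at t = 0
#' @slot diagnostics list with sum-of-squared residuals (`ssr`), residual
#'   standard error (`rse`), residual degrees of freedom (`df`), coefficient
#'   table (`coefTable`: estimate, std. error, t, p per coefficient), number
#'   of bins (`nBins`), convergence flag and a `monotoneIncreasing` flag
#' @exportClass DecayModel
setClass("DecayModel",
  representation(C = "numeric", A = "numeric", B = "numeric",
                 transform = "character", tFloor = "numeric",
                 diagnostics = "list"),
  prototype(transform = "log10", tFloor = 1, diagnostics = list()))

setValidity("DecayModel", function(object) {
  msg <- character()
  if (length(object@C) != 1 || !(object@C > 0 && object@C <= 1))
    msg <- c(msg, "C must lie in (0, 1]")
  if (length(object@B) != 1 || object@B == 0)
    msg <- c(msg, "B must be non-zero")
  if (!object@transform %in% c("log10", "ln", "identity"))
    msg <- c(msg, "transform must be 'log10', 'ln' or 'identity'")
  if (object@tFloor < 0) msg <- c(msg, "tFloor must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a DecayModel
#'
#' @param C limiting probability in (0, 1]
#' @param A inflection location on the transformed time scale
#' @param B decay parameter (negative for decreasing utilisation)
#' @param transform time transform: "log10" (default), "ln" or "identity"
#' @param tFloor minutes floor applied before the log transform
#' @param diagnostics optional list of fit diagnostics
#' @return a [DecayModel-class]
#' @examples
#' DecayModel(C = 0.766, A = 3.736, B = -0.609)
#' @export
DecayModel <- function(C, A, B, transform = "log10", tFloor = 1,
                       diagnostics = list()) {
  # Class= spelled out: a slot named C would otherwise partially match it
  new(Class = "DecayModel", C = as.numeric(C), A = as.numeric(A), B = as.numeric(B),
      transform = transform, tFloor = as.numeric(tFloor),
      diagnostics = diagnostics)
}

setMethod("show", "DecayModel", function(object) {
  cat(sprintf("DecayModel: Y = C/(1 + exp((A - x)/B)) on %s(minutes)\n",
              object@transform))
  cat(sprintf("  C = %.4f  A = %.4f  B = %.4f\n", object@C, object@A, object@B))
  d <- object@diagnostics
  if (length(d) && !is.null(d$ssr))
    cat(sprintf("  SSR = %.5f, RSE = %.4f on %d df (%d bins)\n",
                d$ssr, d$rse, d$df, d$nBins))
})

#' CatchmentSet: facility catchments under a travel-time threshold
#'
#' @slot membership integer matrix: facility id where travel time is within
#'   the threshold, `NA` outside every catchment
#' @slot threshold minutes (default 180, the 3-hour rule)
#' @slot spec the shared [GridSpec-class]
#' @exportClass CatchmentSet
setClass("CatchmentSet",
  representation(membership = "matrix", threshold = "numeric",
                 spec = "GridSpec"))

setValidity("CatchmentSet", function(object) {
  if (!identical(dim(object@membership),
                 c(object@spec@nrows, object@spec@ncols)))
    return("membership matrix does not match the GridSpec dimensions")
  if (object@threshold < 0) return("threshold must be non-negative")
  TRUE
})

setMethod("show", "CatchmentSet", function(object) {
  cat(sprintf("CatchmentSet: %d facilities, %d cells inside, threshold %g min\n",
              length(unique(object@membership[!is.na(object@membership)])),
              sum(!is.na(object@membership)), object@threshold))
})

#' SyntheticScenario: full specification of a simulated study
#'
#' Bundles the grid, the random seed and all scenario-level parameters:
#' region count, facility count, survey design (clusters x households),
#' the true distance-decay model driving attendance, and per-region fever
#' prevalence and under-five population fractions.
#'
#' @slot grid a [GridSpec-class]
#' @slot seed integer seed fixing all randomness end-to-end
#' @slot nRegions,nFacilities,nClusters,householdsPerCluster design counts
#' @slot trueDecay the generating [DecayModel-class]
#' @slot feverPrevalence per-region fever prevalence (two-week recall)
#' @slot under5Fraction per-region fraction of the population aged 0-4
#' @slot childrenPerHouseholdMean mean of the truncated-Poisson household
#'   child-count distribution
#' @slot landcoverProportions named class proportions for the land-cover
#'   generator
#' @slot reliefAmplitude terrain relief in metres
#' @slot nRoads,nRivers,nPopCentres landscape feature counts
#' @slot totalPopulation total population placed on the grid
#' @exportClass SyntheticScenario
setClass("SyntheticScenario",
  representation(grid = "GridSpec", seed = "integer", nRegions = "integer",
                 nFacilities = "integer", nClusters = "integer",
                 householdsPerCluster = "integer", trueDecay = "DecayModel",
                 feverPrevalence = "numeric", under5Fraction = "numeric",
                 childrenPerHouseholdMean = "numeric",
                 landcoverProportions = "numeric",
                 reliefAmplitude = "numeric", nRoads = "integer",
                 nRivers = "integer", nPopCentres = "integer",
                 totalPopulation = "numeric"))

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (object@nClusters < 1L) msg <- c(msg, "nClusters must be >= 1")
  if (object@nFacilities < 1L) msg <- c(msg, "nFacilities must be >= 1")
  if (length(object@feverPrevalence) != object@nRegions)
    msg <- c(msg, "feverPrevalence must have one entry per region")
  if (length(object@under5Fraction) != object@nRegions)
    msg <- c(msg, "under5Fraction must have one entry per region")
  if (any(object@feverPrevalence <= 0 | object@feverPrevalence >= 1))
    msg <- c(msg, "fever prevalences must lie in (0, 1)")
  if (any(object@under5Fraction <= 0 | object@under5Fraction >= 1))
    msg <- c(msg, "under-five fractions must lie in (0, 1)")
  if (abs(sum(object@landcoverProportions) - 1) > 1e-9)
    msg <- c(msg, "land-cover proportions must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf(
    "SyntheticScenario (seed %d): %d x %d km grid, %d regions, %d facilities\n",
    object@seed, object@grid@nrows, object@grid@ncols, object@nRegions,
    object@nFacilities))
  cat(sprintf("  survey: %d clusters x %d households; prevalence %.2f-%.2f\n",
              object@nClusters, object@householdsPerCluster,
              min(object@feverPrevalence), max(object@feverPrevalence)))
})
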