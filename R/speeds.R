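#' Slope-dependent walking speed (Tobler's hiking function)
#'
#' Empirical walking-speed model
#' \deqn{V = 6 \exp(-3.5\,|\tan(\theta) + 0.05|)}
#' with the slope angle \eqn{\theta} in degrees. On flat terrain the speed
#' is about 5.0 km/h; the global maximum of 6 km/h occurs on a slight
#' downhill where \eqn{\tan\theta = -0.05}. The function uses the absolute
#' value, so travel is symmetric in the sign of the gradient apart from
#' that offset.
#'
#' @param slopeDegrees signed slope in degrees, strictly between -90 and 90
#' @return walking speed in km/h, in (0, 6]
#' @examples
#' toblerSpeed(0)    # ~5.04 km/h on the flat
#' toblerSpeed(5)    # 3.71 km/h
#' toblerSpeed(20)   # 1.41 km/h
#' @export
toblerSpeed <- function(slopeDegrees) {
  if (any(abs(slopeDegrees) >= 90))
    stop("slope must be strictly between -90 and 90 degrees", call. = FALSE)
  6 * exp(-3.5 * abs(tan(slopeDegrees * pi / 180) + 0.05))
}

#' Slope multiplier applied to human-powered travel
#'
#' Ratio of the Tobler speed at the given slope to the flat-terrain speed.
#' Applied multiplicatively to the land-cover speed of WALKING (and, by the
#' same factor, CYCLING) cells; MOTORIZED cells are unaffected by slope.
#'
#' @param slopeDegrees signed slope in degrees
#' @return dimensionless factor (1 at 0 degrees)
#' @export
walkingSpeedMultiplier <- function(slopeDegrees) {
  toblerSpeed(slopeDegrees) / toblerSpeed(0)
}

# Land-cover legend: integer codes used in land-cover rasters
LANDCOVER_CLASSES <- c(
  tree_broadleaved = 1L, tree_needleleaved = 2L, tree_other = 3L,
  shrub = 4L, herbaceous = 5L, sparse_herbaceous = 6L,
  cultivated = 7L, bare_desert = 8L, water = 9L)

ROAD_CLASSES <- c(primary = 1L, secondary = 2L, tertiary = 3L)

#' Default speed table
#'
#' Permissible speeds and transport modes per land-cover class and road
#' class. Broadleaved/needleleaved tree cover, shrub and cultivated land
#' walk at 5 km/h; herbaceous 3; sparse herbaceous 4; other tree cover and
#' bare/desert 2; water is an absolute barrier. Primary and secondary roads
#' are motorized (80 and 60 km/h); tertiary roads are cycled at 10 km/h.
#' Rivers are barriers unless a road crosses them.
#'
#' @return a data.frame with columns `class` (name), `kind`
#'   ("landcover"/"road"/"river"), `speed` (km/h) and `mode`
#' @examples
#' defaultSpeedTable()
#' @export
defaultSpeedTable <- function() {
  data.frame(
    class = c(names(LANDCOVER_CLASSES), names(ROAD_CLASSES), "river"),
    kind = c(rep("landcover", length(LANDCOVER_CLASSES)),
             rep("road", length(ROAD_CLASSES)), "river"),
    speed = c(5, 5, 2, 5, 3, 4, 5, 2, 0, 80, 60, 10, 0),
    mode = c(rep("WALKING", 8), "NONE", "MOTORIZED", "MOTORIZED", "CYCLING",
             "NONE"),
    stringsAsFactors = FALSE)
}

validate_speed_table <- function(table) {
  need <- c("class", "kind", "speed", "mode")
  if (!all(need %in% names(table)))
    stop("speed table must have columns class, kind, speed, mode",
         call. = FALSE)
  if (any(table$speed < 0)) stop("speeds must be >= 0", call. = FALSE)
  bad <- xor(table$speed == 0, table$mode == "NONE")
  if (any(bad))
    stop("speed 0 must pair with mode NONE (barrier) and vice versa",
         call. = FALSE)
  if (!all(table$mode %in% names(MODE_LEVELS)))
    stop("unknown transport mode in speed table", call. = FALSE)
  invisible(table)
}

#' Read or write a speed table as JSON
#'
#' @param path file path
#' @param table a speed table data.frame as returned by [defaultSpeedTable()]
#' @return `readSpeedTable` returns the validated data.frame
#' @export
readSpeedTable <- function(path) {
  tab <- as.data.frame(jsonlite::fromJSON(path))
  validate_speed_table(tab)
}

#' @rdname readSpeedTable
#' @export
writeSpeedTable <- function(table, path) {
  validate_speed_table(table)
  jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}
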