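#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster interchange. Values are written at full
#' double precision so a write-read round trip reproduces the raster
#' exactly. Non-finite cells (e.g. unreached travel times) are stored as
#' the grid's nodata sentinel; `nodataAs` controls what they become on
#' reading (`NA` by default, `Inf` for travel-time surfaces).
#'
#' @param raster a [GridRaster-class] (or subclass)
#' @param path file path (conventionally `.asc`)
#' @param nodataAs value substituted for nodata cells on reading
#' @return `readGridRaster` returns a [GridRaster-class]
#' @export
writeGridRaster <- function(raster, path) {
  spec <- raster@spec
  v <- raster@values
  v[!is.finite(v)] <- spec@nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", spec@ncols),
    paste("nrows", spec@nrows),
    paste("xllcorner", format(spec@originX, digits = 17)),
    paste("yllcorner", format(spec@originY, digits = 17)),
    paste("cellsize", format(spec@cellSize, digits = 17)),
    paste("NODATA_value", format(spec@nodata, digits = 17))), con)
  for (r in seq_len(spec@nrows))
    writeLines(paste(formatC(v[r, ], digits = 17, format = "g"),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname writeGridRaster
#' @export
readGridRaster <- function(path, nodataAs = NA_real_) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  spec <- GridSpec(nrows = vals[["nrows"]], ncols = vals[["ncols"]],
                   cellSize = vals[["cellsize"]],
                   originX = vals[["xllcorner"]],
                   originY = vals[["yllcorner"]],
                   nodata = vals[["nodata_value"]])
  v <- matrix(scan(text = lines[-(1:6)], quiet = TRUE), nrow = spec@nrows,
              ncol = spec@ncols, byrow = TRUE)
  v[v == spec@nodata] <- nodataAs
  GridRaster(v, spec)
}

#' Write or read a FrictionSurface as a pair of ASCII grids
#'
#' Speed and mode are stored side by side (`<stem>_speed.asc`,
#' `<stem>_mode.asc`); the barrier mask is implied by mode 0 (NONE), so a
#' round trip reproduces the surface exactly.
#'
#' @param friction a [FrictionSurface-class]
#' @param stem path stem without suffix
#' @return `readFrictionSurface` returns the [FrictionSurface-class]
#' @export
writeFrictionSurface <- function(friction, stem) {
  writeGridRaster(GridRaster(friction@speed, friction@spec),
                  paste0(stem, "_speed.asc"))
  writeGridRaster(GridRaster(friction@mode, friction@spec),
                  paste0(stem, "_mode.asc"))
  invisible(stem)
}

#' @rdname writeFrictionSurface
#' @export
readFrictionSurface <- function(stem) {
  sp <- readGridRaster(paste0(stem, "_speed.asc"))
  md <- readGridRaster(paste0(stem, "_mode.asc"))
  mode <- matrix(as.integer(md@values), sp@spec@nrows, sp@spec@ncols)
  new("FrictionSurface", speed = sp@values, mode = mode,
      barrier = mode == MODE_NONE, spec = sp@spec)
}

#' Read and write point/line features as GeoJSON
#'
#' Facilities travel as a FeatureCollection of Points with an `id`
#' property; roads and rivers as LineStrings with a `class` property.
#'
#' @param facilities data.frame with columns `id`, `x`, `y`
#' @param features list of `list(coords, class)` polyline features
#' @param path file path
#' @return readers return the corresponding R structure
#' @export
writeFacilitiesGeoJSON <- function(facilities, path) {
  feats <- lapply(seq_len(nrow(facilities)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(facilities$x[i], facilities$y[i])),
    properties = list(id = facilities$id[i])))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFacilitiesGeoJSON
#' @export
readFacilitiesGeoJSON <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(gj$features, function(f)
    data.frame(id = f$properties$id,
               x = f$geometry$coordinates[[1]],
               y = f$geometry$coordinates[[2]]))
  do.call(rbind, rows)
}

#' @rdname writeFacilitiesGeoJSON
#' @export
writeLinesGeoJSON <- function(features, path) {
  feats <- lapply(features, function(f) list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = lapply(seq_len(nrow(f$coords)), function(i)
                      as.numeric(f$coords[i, ]))),
    properties = list(class = f$class)))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFacilitiesGeoJSON
#' @export
readLinesGeoJSON <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(gj$features, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates, as.numeric))
    colnames(coords) <- c("x", "y")
    list(coords = coords, class = f$properties$class)
  })
}

#' Survey and region-table CSV interchange
#'
#' The survey CSV has one row per child with columns `cluster_id`,
#' `region_id`, `x`, `y`, `household_id`, `child_id`, `fever`,
#' `attended_public` (empty when fever = 0) and `travel_time_min`. The
#' region table has `region_id`, `name`, `prevalence`, `ci_low`,
#' `ci_high`, `under5_fraction`.
#'
#' @param survey,regionTable data.frames
#' @param path file path
#' @return readers return the data.frame
#' @export
writeSurveyCSV <- function(survey, path) {
  write.csv(survey, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeSurveyCSV
#' @export
readSurveyCSV <- function(path) read.csv(path)

#' @rdname writeSurveyCSV
#' @export
writeRegionTableCSV <- function(regionTable, path) {
  write.csv(regionTable, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSurveyCSV
#' @export
readRegionTableCSV <- function(path) read.csv(path)
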