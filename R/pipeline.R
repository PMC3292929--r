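#' Pipeline configuration
#'
#' A pipeline configuration is a plain list (serialized as JSON) naming
#' every input file, the analysis options and the output directory:
#' `landcover`, `dem`, `roads`, `rivers`, `population`, `regions`,
#' `facilities`, `survey`, `regionTable` (paths), optional `speedTable`
#' (path to a JSON speed table; the packaged default otherwise), `decay`
#' (list: `transform`, `bins`, `tFloor`), `thresholdMinutes`,
#' `timeBandEdges`, `probBandEdges`, `outDir`.
#'
#' @param config a configuration list
#' @param path file path
#' @return `readPipelineConfig` returns the list; the round trip through
#'   JSON leaves the configuration unchanged
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (k in c("timeBandEdges", "probBandEdges"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(cfg[[k]])
  cfg
}

log_stage <- function(stage, ...) {
  info <- list(stage = stage, ...)
  message(jsonlite::toJSON(info, auto_unbox = TRUE))
}

#' Run the full accessibility-and-burden pipeline
#'
#' Executes the analysis stages in dependency order: friction surface,
#' least-cost travel time and allocation, distance-decay fit from the
#' survey, probability surface, catchment delineation, and the stratified
#' burden summaries. All inputs are read from the paths in the
#' configuration; artifacts are written under `outDir` (rasters as ASCII
#' grids, the model as JSON, summaries as one CSV with a `stratification`
#' column). Machine-readable stage logs go to the message stream. The run
#' is deterministic: the same configuration and inputs reproduce identical
#' outputs byte for byte.
#'
#' @param config a configuration list or the path to a config JSON
#' @return invisibly, a list with all in-memory artifacts (`friction`,
#'   `tt`, `alloc`, `model`, `probability`, `catchments`, `summary`)
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  landcover <- readGridRaster(config$landcover)
  landcover@values <- matrix(as.integer(landcover@values),
                             landcover@spec@nrows, landcover@spec@ncols)
  dem <- if (!is.null(config$dem)) readGridRaster(config$dem) else NULL
  roads <- if (!is.null(config$roads)) readLinesGeoJSON(config$roads)
           else NULL
  rivers <- if (!is.null(config$rivers)) readLinesGeoJSON(config$rivers)
            else NULL
  population <- readGridRaster(config$population)
  regions <- readGridRaster(config$regions)
  facilities <- readFacilitiesGeoJSON(config$facilities)
  survey <- readSurveyCSV(config$survey)
  regionTable <- readRegionTableCSV(config$regionTable)
  speedTable <- if (!is.null(config$speedTable))
    readSpeedTable(config$speedTable) else defaultSpeedTable()
  specs <- list(landcover@spec, population@spec, regions@spec)
  if (!is.null(dem)) specs <- c(specs, list(dem@spec))
  do.call(stop_if_grid_mismatch, c(specs, list(what = "input rasters")))

  decayOpts <- config$decay
  transform <- if (is.null(decayOpts$transform)) "log10"
               else decayOpts$transform
  bins <- if (is.null(decayOpts$bins)) 15L else as.integer(decayOpts$bins)
  tFloor <- if (is.null(decayOpts$tFloor)) 1 else decayOpts$tFloor
  threshold <- if (is.null(config$thresholdMinutes)) 180
               else config$thresholdMinutes
  timeEdges <- if (is.null(config$timeBandEdges)) c(30, 60, 120, 180)
               else config$timeBandEdges
  probEdges <- if (is.null(config$probBandEdges)) c(0.5, 0.6, 0.7, 0.75)
               else config$probBandEdges

  log_stage("friction", cells = landcover@spec@nrows * landcover@spec@ncols)
  friction <- buildFrictionSurface(landcover, roads, rivers, speedTable)
  writeFrictionSurface(friction, file.path(outDir, "friction"))

  log_stage("traveltime", facilities = nrow(facilities))
  acc <- accumulateCost(friction, facilities, dem = dem)
  writeGridRaster(acc$minutes, file.path(outDir, "traveltime.asc"))
  writeGridRaster(acc$allocation, file.path(outDir, "allocation.asc"))

  log_stage("fit-decay", records = sum(survey$fever == 1), bins = bins)
  fevers <- survey[survey$fever == 1, ]
  records <- data.frame(travel_time = fevers$travel_time_min,
                        attended = fevers$attended_public)
  model <- fitLogistic3(records, transform = transform, tFloor = tFloor,
                        nBins = bins)
  writeDecayModel(model, file.path(outDir, "model.json"))

  log_stage("probability")
  prob <- probabilitySurface(model, acc$minutes)
  writeGridRaster(prob, file.path(outDir, "probability.asc"))

  log_stage("catchments", threshold = threshold)
  catch <- delineateCatchments(acc$minutes, acc$allocation, threshold)
  catchRaster <- GridRaster(catch@membership, catch@spec)
  writeGridRaster(catchRaster, file.path(outDir, "catchments.asc"))

  log_stage("burden")
  children <- childrenSurface(population, regions, regionTable)
  fever <- feverSurface(children, regions, regionTable)
  att <- expectedAttendance(fever, prob)
  strata <- list(
    total = summarizeBurden(children, fever, att$attendees, "total",
                            catchments = catch),
    region = summarizeBurden(children, fever, att$attendees, "region",
                             regions = regions, catchments = catch),
    time = summarizeBurden(children, fever, att$attendees, "time",
                           tt = acc$minutes, catchments = catch,
                           bandEdges = timeEdges),
    probability = summarizeBurden(children, fever, att$attendees,
                                  "probability", probability = prob,
                                  catchments = catch, bandEdges = probEdges),
    catchment = summarizeBurden(children, fever, att$attendees, "catchment",
                                catchments = catch))
  summary <- do.call(rbind, lapply(names(strata), function(nm)
    cbind(stratification = nm, strata[[nm]])))
  rownames(summary) <- NULL
  write.csv(summary, file.path(outDir, "summary.csv"), row.names = FALSE)

  log_stage("done")
  invisible(list(friction = friction, tt = acc$minutes,
                 alloc = acc$allocation, model = model, probability = prob,
                 catchments = catch, summary = summary))
}

#' Write every input a scenario generates and a ready-to-run config
#'
#' Materialises a [SyntheticScenario-class] to disk in the interchange
#' formats the pipeline reads (ASCII-grid rasters, GeoJSON vectors, CSV
#' survey and region table, JSON speed table and config) and returns the
#' path of the written configuration, whose `outDir` defaults to
#' `<dir>/out`.
#'
#' @param scenario a [SyntheticScenario-class]
#' @param dir output directory (created if needed)
#' @return path to `config.json`, invisibly the config list as attribute
#' @export
writeScenarioInputs <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  art <- generateScenario(scenario)
  p <- function(f) file.path(dir, f)
  writeGridRaster(art$dem, p("dem.asc"))
  writeGridRaster(art$landcover, p("landcover.asc"))
  writeLinesGeoJSON(art$roads, p("roads.geojson"))
  writeLinesGeoJSON(art$rivers, p("rivers.geojson"))
  writeGridRaster(art$population, p("population.asc"))
  writeGridRaster(art$regions, p("regions.asc"))
  writeFacilitiesGeoJSON(art$facilities, p("facilities.geojson"))
  writeSurveyCSV(art$survey, p("survey.csv"))
  writeRegionTableCSV(art$regionTable, p("regions.csv"))
  writeSpeedTable(defaultSpeedTable(), p("speed_table.json"))
  cfg <- list(landcover = p("landcover.asc"), dem = p("dem.asc"),
              roads = p("roads.geojson"), rivers = p("rivers.geojson"),
              population = p("population.asc"), regions = p("regions.asc"),
              facilities = p("facilities.geojson"), survey = p("survey.csv"),
              regionTable = p("regions.csv"),
              speedTable = p("speed_table.json"),
              decay = list(transform = scenario@trueDecay@transform,
                           bins = 15L, tFloor = scenario@trueDecay@tFloor),
              thresholdMinutes = 180,
              timeBandEdges = c(30, 60, 120, 180),
              probBandEdges = c(0.5, 0.6, 0.7, 0.75),
              seed = scenario@seed, outDir = file.path(dir, "out"))
  writePipelineConfig(cfg, p("config.json"))
  invisible(p("config.json"))
}
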