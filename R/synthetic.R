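#' Construct a synthetic study scenario
#'
#' Bundles every knob of the synthetic-landscape simulator. The defaults
#' emulate the structure of a national malaria indicator survey over a
#' semi-arid nine-region study area: 120 clusters of about 25 households,
#' regional two-week fever prevalence spanning roughly 7-28%, an under-five
#' population share of 16.8%, and attendance generated from a logistic
#' distance decay on log10 travel time with C = 0.766, A = 3.736,
#' B = -0.609. Land cover is dominated by shrub, herbaceous and bare/desert
#' classes with a small water fraction; population is clustered around a
#' handful of foci on a 1 km grid.
#'
#' @param grid a [GridSpec-class] (default 60 x 60 km at 1 km cells)
#' @param seed integer seed fixing all randomness end-to-end
#' @param nRegions number of regions (default 9)
#' @param nFacilities number of health facilities (default 20)
#' @param nClusters survey clusters (default 120)
#' @param householdsPerCluster households per cluster (default 25)
#' @param trueDecay the generating [DecayModel-class]
#' @param feverPrevalence per-region two-week fever prevalence
#' @param under5Fraction per-region under-five population fraction
#' @param childrenPerHouseholdMean mean of the household child-count
#'   distribution (Poisson truncated at 3); the default 0.81 reproduces the
#'   observed ratio of under-fives to surveyed households
#' @param landcoverProportions named land-cover class proportions
#' @param reliefAmplitude terrain relief in metres
#' @param nRoads,nRivers,nPopCentres landscape feature counts
#' @param totalPopulation total population on the grid
#' @return a [SyntheticScenario-class]
#' @examples
#' sc <- SyntheticScenario(GridSpec(30, 30), seed = 1)
#' sc
#' @export
SyntheticScenario <- function(grid = GridSpec(60, 60), seed = 1L,
    nRegions = 9L, nFacilities = 20L, nClusters = 120L,
    householdsPerCluster = 25L,
    trueDecay = DecayModel(C = 0.766, A = 3.736, B = -0.609),
    feverPrevalence = c(0.276, 0.239, 0.174, 0.118, 0.171, 0.127, 0.148,
                        0.070, 0.175)[seq_len(nRegions) %% 9 + 1],
    under5Fraction = rep(0.168, nRegions),
    childrenPerHouseholdMean = 0.81,
    landcoverProportions = c(tree_broadleaved = 0.04,
                             tree_needleleaved = 0.01, tree_other = 0.03,
                             shrub = 0.35, herbaceous = 0.20,
                             sparse_herbaceous = 0.15, cultivated = 0.05,
                             bare_desert = 0.15, water = 0.02),
    reliefAmplitude = 300, nRoads = 8L, nRivers = 2L, nPopCentres = 6L,
    totalPopulation = 2e5) {
  new("SyntheticScenario", grid = grid, seed = as.integer(seed),
      nRegions = as.integer(nRegions), nFacilities = as.integer(nFacilities),
      nClusters = as.integer(nClusters),
      householdsPerCluster = as.integer(householdsPerCluster),
      trueDecay = trueDecay, feverPrevalence = feverPrevalence,
      under5Fraction = under5Fraction,
      childrenPerHouseholdMean = childrenPerHouseholdMean,
      landcoverProportions = landcoverProportions,
      reliefAmplitude = reliefAmplitude, nRoads = as.integer(nRoads),
      nRivers = as.integer(nRivers), nPopCentres = as.integer(nPopCentres),
      totalPopulation = totalPopulation)
}

# Gaussian-smoothed white noise, edge-replicated separable convolution
smooth_field <- function(m, sigma = 3) {
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-half:half, sd = sigma); k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(m, 1, pad_conv))
}

#' Generate a smooth synthetic elevation raster
#'
#' Low-pass-filtered Gaussian noise rescaled to the requested relief.
#' Deterministic per (grid, seed); a relief amplitude of 0 gives flat
#' terrain.
#'
#' @param grid a [GridSpec-class]
#' @param seed integer seed
#' @param reliefAmplitude elevation range in metres (>= 0)
#' @return a [GridRaster-class] of elevation in metres
#' @export
generateDEM <- function(grid, seed, reliefAmplitude = 300) {
  if (reliefAmplitude < 0) stop("relief amplitude must be >= 0")
  set.seed(seed)
  z <- matrix(rnorm(grid@nrows * grid@ncols), grid@nrows, grid@ncols)
  z <- smooth_field(z)
  rng <- range(z)
  if (diff(rng) == 0 || reliefAmplitude == 0)
    z <- matrix(0, grid@nrows, grid@ncols)
  else
    z <- (z - rng[1]) / diff(rng) * reliefAmplitude
  GridRaster(z, grid)
}

#' Generate a categorical land-cover raster
#'
#' Cells draw a legend class independently with the given proportions;
#' spatial autocorrelation is introduced by ranking a smoothed noise field
#' so that class patches are contiguous while the marginal proportions are
#' kept (each class occupies its exact share of cells, up to rounding).
#' Water cells form the barrier set.
#'
#' @param grid a [GridSpec-class]
#' @param seed integer seed
#' @param classProportions named proportions over the legend classes (must
#'   sum to 1 within 1e-9); see [defaultSpeedTable()] for class names
#' @return a [GridRaster-class] of integer legend codes
#' @export
generateLandcover <- function(grid, seed, classProportions) {
  if (abs(sum(classProportions) - 1) > 1e-9)
    stop("class proportions must sum to 1", call. = FALSE)
  unknown <- setdiff(names(classProportions), names(LANDCOVER_CLASSES))
  if (length(unknown))
    stop(sprintf("unknown land-cover class(es): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  set.seed(seed + 1L)
  n <- grid@nrows * grid@ncols
  field <- smooth_field(matrix(rnorm(n), grid@nrows, grid@ncols), sigma = 2)
  # rank the field and slice it at the cumulative proportions
  ranks <- rank(as.vector(field), ties.method = "first")
  cuts <- round(cumsum(classProportions) * n)
  cls <- names(classProportions)[findInterval(ranks, c(0, cuts),
                                              left.open = TRUE)]
  GridRaster(matrix(LANDCOVER_CLASSES[cls], grid@nrows, grid@ncols), grid)
}

random_polyline <- function(grid, nWaypoints = 2) {
  w <- grid@ncols * grid@cellSize; h <- grid@nrows * grid@cellSize
  x <- grid@originX + runif(2 + nWaypoints) * w
  y <- grid@originY + runif(2 + nWaypoints) * h
  ord <- order(x)
  cbind(x = x[ord], y = y[ord])
}

#' Generate synthetic road polylines
#'
#' Random gently-bending polylines within the grid extent, each carrying
#' exactly one road class.
#'
#' @param grid a [GridSpec-class]
#' @param seed integer seed
#' @param nRoads number of roads
#' @param classMix named probabilities over "primary", "secondary",
#'   "tertiary"
#' @return list of features `list(coords, class)`
#' @export
generateRoads <- function(grid, seed, nRoads,
                          classMix = c(primary = 0.2, secondary = 0.3,
                                       tertiary = 0.5)) {
  set.seed(seed + 2L)
  classes <- sample(names(classMix), nRoads, replace = TRUE,
                    prob = classMix)
  lapply(seq_len(nRoads), function(i)
    list(coords = random_polyline(grid), class = classes[i]))
}

#' Generate synthetic river polylines (absolute barriers)
#'
#' @param grid a [GridSpec-class]
#' @param seed integer seed
#' @param nRivers number of rivers
#' @return list of features `list(coords, class = "river")`
#' @export
generateRivers <- function(grid, seed, nRivers) {
  set.seed(seed + 3L)
  lapply(seq_len(nRivers), function(i)
    list(coords = random_polyline(grid, nWaypoints = 3), class = "river"))
}

#' Generate a gridded population raster
#'
#' Population is allocated multinomially over cells with weights from a
#' Gaussian mixture around `nCentres` random foci, so the raster sums to
#' the requested total exactly. With `uniform = TRUE` every cell receives
#' the same (possibly fractional) count.
#'
#' @param grid a [GridSpec-class]
#' @param seed integer seed
#' @param nCentres number of population foci
#' @param totalPopulation total person count
#' @param uniform spread the population evenly instead
#' @return a [GridRaster-class] of counts summing to `totalPopulation`
#' @export
generatePopulation <- function(grid, seed, nCentres, totalPopulation,
                               uniform = FALSE) {
  n <- grid@nrows * grid@ncols
  if (uniform)
    return(GridRaster(matrix(totalPopulation / n, grid@nrows, grid@ncols),
                      grid))
  set.seed(seed + 4L)
  idx <- expand.grid(row = seq_len(grid@nrows), col = seq_len(grid@ncols))
  xy <- cellCenter(grid, idx$row, idx$col)
  sigma <- 0.12 * max(grid@nrows, grid@ncols) * grid@cellSize
  w <- numeric(n)
  for (k in seq_len(nCentres)) {
    cx <- grid@originX + runif(1) * grid@ncols * grid@cellSize
    cy <- grid@originY + runif(1) * grid@nrows * grid@cellSize
    w <- w + exp(-((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2) / (2 * sigma^2))
  }
  counts <- as.vector(rmultinom(1, size = round(totalPopulation),
                                prob = w / sum(w)))
  m <- matrix(0, grid@nrows, grid@ncols)
  m[cbind(idx$row, idx$col)] <- counts
  GridRaster(m, grid)
}

#' Partition the grid into regions
#'
#' Nearest-centre (Voronoi) partition. With `seed = NULL` the centres are
#' placed deterministically on a regular sub-grid; with a seed they are
#' random. Every cell belongs to exactly one region (ids 1..nRegions).
#'
#' @param grid a [GridSpec-class]
#' @param nRegions number of regions
#' @param seed optional integer seed for random centres
#' @return a [GridRaster-class] of region ids
#' @export
generateRegions <- function(grid, nRegions, seed = NULL) {
  w <- grid@ncols * grid@cellSize; h <- grid@nrows * grid@cellSize
  if (is.null(seed)) {
    k <- ceiling(sqrt(nRegions))
    gx <- ((seq_len(k) - 0.5) / k) * w + grid@originX
    gy <- ((seq_len(k) - 0.5) / k) * h + grid@originY
    centres <- expand.grid(x = gx, y = gy)[seq_len(nRegions), ]
  } else {
    set.seed(seed + 5L)
    centres <- data.frame(x = grid@originX + runif(nRegions) * w,
                          y = grid@originY + runif(nRegions) * h)
  }
  idx <- expand.grid(row = seq_len(grid@nrows), col = seq_len(grid@ncols))
  xy <- cellCenter(grid, idx$row, idx$col)
  d2 <- outer(xy[, 1], centres$x, "-")^2 + outer(xy[, 2], centres$y, "-")^2
  reg <- max.col(-d2, ties.method = "first")
  m <- matrix(0L, grid@nrows, grid@ncols)
  m[cbind(idx$row, idx$col)] <- reg
  GridRaster(m, grid)
}

#' Place health facilities proportional to population
#'
#' Samples distinct non-barrier cells with probability proportional to
#' their population count; facilities sit at cell centres with ids
#' 1..nFacilities.
#'
#' @param population a [GridRaster-class] of counts
#' @param nFacilities number of facilities
#' @param seed integer seed
#' @param barrier optional logical matrix of impassable cells to exclude
#' @return data.frame with columns `id`, `x`, `y`
#' @export
generateFacilities <- function(population, nFacilities, seed,
                               barrier = NULL) {
  spec <- population@spec
  w <- as.vector(population@values)
  ok <- rep(TRUE, length(w))
  if (!is.null(barrier)) ok <- !as.vector(barrier)
  w[!ok] <- 0
  w <- w + ifelse(ok, 1e-9, 0) # allow empty but passable cells
  if (sum(w > 0) < nFacilities)
    stop("not enough passable cells to place facilities")
  set.seed(seed + 6L)
  pick <- sample.int(length(w), nFacilities, prob = w)
  row <- ((pick - 1L) %% spec@nrows) + 1L
  col <- ((pick - 1L) %/% spec@nrows) + 1L
  xy <- cellCenter(spec, row, col)
  data.frame(id = seq_len(nFacilities), x = xy[, 1], y = xy[, 2])
}

#' Simulate a two-stage cluster household survey
#'
#' Clusters are allocated to regions proportional to regional population
#' (largest-remainder rounding, at least the populated regions covered) and
#' placed at population-weighted cell centres; impassable or unreached
#' cells are excluded from sampling, which is the resampling rule for
#' clusters that would otherwise fall on barriers. Each cluster holds
#' `householdsPerCluster` households whose child counts follow a Poisson
#' distribution truncated at 3. Every child has fever with the region's
#' prevalence; children with fever attend a public facility with the
#' probability the scenario's true decay model assigns to the cluster's
#' travel time. The true travel time is recorded per record, so model
#' recovery needs no re-extraction.
#'
#' @param scenario a [SyntheticScenario-class]
#' @param tt a [TravelTimeSurface-class] on the scenario grid
#' @param regions region-id raster
#' @param population population raster (cluster sampling weights)
#' @param barrier optional logical matrix of impassable cells
#' @return data.frame with one row per child: `cluster_id`, `region_id`,
#'   `x`, `y`, `household_id`, `child_id`, `fever`, `attended_public`
#'   (`NA` when fever = 0) and `travel_time_min`
#' @export
simulateSurvey <- function(scenario, tt, regions, population,
                           barrier = NULL) {
  spec <- scenario@grid
  stop_if_grid_mismatch(spec, tt@spec, regions@spec, population@spec,
                        what = "scenario rasters")
  set.seed(scenario@seed + 7L)
  valid <- is.finite(tt@values)
  if (!is.null(barrier)) valid <- valid & !barrier
  if (!any(valid)) stop("no valid cells to place survey clusters")

  regIds <- sort(unique(as.vector(regions@values)))
  popByRegion <- vapply(regIds, function(i)
    sum(population@values[regions@values == i & valid]), numeric(1))
  if (sum(popByRegion) == 0) popByRegion <- rep(1, length(regIds))
  # largest-remainder allocation of clusters to regions
  quota <- scenario@nClusters * popByRegion / sum(popByRegion)
  nClust <- floor(quota)
  rem <- scenario@nClusters - sum(nClust)
  if (rem > 0) {
    extra <- order(quota - nClust, decreasing = TRUE)[seq_len(rem)]
    nClust[extra] <- nClust[extra] + 1L
  }

  rows <- list(); clusterId <- 0L
  for (ri in seq_along(regIds)) {
    if (nClust[ri] == 0) next
    cells <- which(regions@values == regIds[ri] & valid)
    if (!length(cells))
      stop(sprintf("region %d has no valid cells for clusters", regIds[ri]))
    w <- population@values[cells] + 1e-9
    pick <- sample(cells, nClust[ri], replace = length(cells) < nClust[ri],
                   prob = w)
    prev <- scenario@feverPrevalence[regIds[ri]]
    for (cell in pick) {
      clusterId <- clusterId + 1L
      row <- ((cell - 1L) %% spec@nrows) + 1L
      col <- ((cell - 1L) %/% spec@nrows) + 1L
      xy <- cellCenter(spec, row, col)
      t_min <- tt@values[row, col]
      nChild <- pmin(rpois(scenario@householdsPerCluster,
                           scenario@childrenPerHouseholdMean), 3L)
      hh <- rep(seq_len(scenario@householdsPerCluster), nChild)
      nKids <- length(hh)
      if (!nKids) next
      fever <- rbinom(nKids, 1, prev)
      pAttend <- predictProbability(scenario@trueDecay, t_min)
      attended <- ifelse(fever == 1, rbinom(nKids, 1, pAttend), NA_integer_)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = clusterId, region_id = regIds[ri],
        x = xy[1], y = xy[2], household_id = hh,
        child_id = seq_len(nKids), fever = fever,
        attended_public = attended, travel_time_min = t_min)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the complete synthetic landscape for a scenario
#'
#' Runs every generator in a fixed order with sub-seeds derived from the
#' scenario seed, builds the friction and travel-time surfaces, and
#' simulates the household survey, returning all artifacts in one list.
#'
#' @param scenario a [SyntheticScenario-class]
#' @return list with elements `dem`, `landcover`, `roads`, `rivers`,
#'   `population`, `regions`, `facilities`, `friction`, `tt`, `alloc`,
#'   `survey` and `regionTable`
#' @export
generateScenario <- function(scenario) {
  g <- scenario@grid; s <- scenario@seed
  dem <- generateDEM(g, s, scenario@reliefAmplitude)
  lc <- generateLandcover(g, s, scenario@landcoverProportions)
  roads <- generateRoads(g, s, scenario@nRoads)
  rivers <- generateRivers(g, s, scenario@nRivers)
  pop <- generatePopulation(g, s, scenario@nPopCentres,
                            scenario@totalPopulation)
  regions <- generateRegions(g, scenario@nRegions, seed = s)
  friction <- buildFrictionSurface(lc, roads, rivers)
  fac <- generateFacilities(pop, scenario@nFacilities, s,
                            barrier = friction@barrier)
  acc <- accumulateCost(friction, fac, dem = dem)
  survey <- simulateSurvey(scenario, acc$minutes, regions, pop,
                           barrier = friction@barrier)
  regionTable <- surveyRegionTable(survey, scenario)
  list(dem = dem, landcover = lc, roads = roads, rivers = rivers,
       population = pop, regions = regions, facilities = fac,
       friction = friction, tt = acc$minutes, alloc = acc$allocation,
       survey = survey, regionTable = regionTable)
}

#' Region table estimated from a simulated survey
#'
#' Per-region fever prevalence (with a Wald 95% interval) estimated from
#' the survey records, joined to the scenario's under-five fractions —
#' the analogue of deriving regional prevalence from the survey while the
#' age structure comes from census-style inputs.
#'
#' @param survey data.frame from [simulateSurvey()]
#' @param scenario the generating [SyntheticScenario-class]
#' @return data.frame with columns `region_id`, `name`, `prevalence`,
#'   `ci_low`, `ci_high`, `under5_fraction`
#' @export
surveyRegionTable <- function(survey, scenario) {
  overall <- sum(survey$fever) / nrow(survey)
  rows <- lapply(seq_len(scenario@nRegions), function(i) {
    sub <- survey[survey$region_id == i, ]
    if (nrow(sub) > 0) {
      ci <- proportionCI(sum(sub$fever), nrow(sub))
      prev <- sum(sub$fever) / nrow(sub)
      lo <- ci[["lower"]] / 100; hi <- ci[["upper"]] / 100
    } else {
      # unsurveyed region: fall back to the pooled survey prevalence
      prev <- overall; lo <- NA_real_; hi <- NA_real_
    }
    data.frame(region_id = i, name = paste0("region_", i),
               prevalence = prev, ci_low = lo, ci_high = hi,
               under5_fraction = scenario@under5Fraction[i])
  })
  do.call(rbind, rows)
}
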