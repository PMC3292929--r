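test_that("every generator is deterministic under a fixed seed", {
  sc <- SyntheticScenario(GridSpec(20, 20), seed = 5, nClusters = 20,
                          nFacilities = 4)
  a <- generateScenario(sc)
  b <- generateScenario(sc)
  expect_identical(gridValues(a$dem), gridValues(b$dem))
  expect_identical(gridValues(a$landcover), gridValues(b$landcover))
  expect_identical(gridValues(a$population), gridValues(b$population))
  expect_identical(a$facilities, b$facilities)
  expect_identical(a$survey, b$survey)
})

test_that("flat relief produces constant elevation and zero slope", {
  g <- GridSpec(10, 10)
  dem <- generateDEM(g, seed = 1, reliefAmplitude = 0)
  expect_equal(length(unique(as.vector(gridValues(dem)))), 1)
  expect_true(all(gridValues(slopeRaster(dem)) == 0))
  expect_error(generateDEM(g, 1, reliefAmplitude = -5), ">= 0")
})

test_that("relief stays within the requested amplitude with sane slopes", {
  g <- GridSpec(50, 50)
  dem <- generateDEM(g, seed = 1, reliefAmplitude = 500)
  z <- gridValues(dem)
  expect_equal(min(z), 0)
  expect_equal(max(z), 500)
  sl <- gridValues(slopeRaster(dem))
  expect_true(all(sl >= 0 & sl < 90))
})

test_that("land-cover proportions are honoured and validated", {
  g <- GridSpec(30, 30)
  lc <- generateLandcover(g, 1, c(shrub = 1))
  expect_true(all(gridValues(lc) == 4L))
  mix <- c(shrub = 0.9, water = 0.1)
  lc2 <- generateLandcover(g, 1, mix)
  waterFrac <- mean(gridValues(lc2) == 9L)
  expect_lt(abs(waterFrac - 0.1), 0.01)
  expect_error(generateLandcover(g, 1, c(shrub = 0.9)), "sum to 1")
  expect_error(generateLandcover(g, 1, c(lava = 0.5, shrub = 0.5)),
               "unknown land-cover")
})

test_that("population is conserved and can be spread uniformly", {
  g <- GridSpec(25, 25)
  pop <- generatePopulation(g, 1, nCentres = 3, totalPopulation = 1000)
  expect_equal(sum(gridValues(pop)), 1000)
  expect_true(all(gridValues(pop) >= 0))
  u <- generatePopulation(g, 1, 1, 1250, uniform = TRUE)
  expect_true(all(gridValues(u) == 2))
  expect_equal(sum(gridValues(u)), 1250)
})

test_that("regions partition the grid and facilities sit on passable cells", {
  g <- GridSpec(20, 20)
  reg <- generateRegions(g, 7, seed = 2)
  ids <- as.vector(gridValues(reg))
  expect_true(all(ids %in% 1:7))
  expect_false(any(is.na(ids)))
  pop <- generatePopulation(g, 2, 3, 5000)
  lc <- generateLandcover(g, 2, c(shrub = 0.8, water = 0.2))
  fr <- buildFrictionSurface(lc)
  fac <- generateFacilities(pop, 5, 2, barrier = frictionBarrier(fr))
  expect_equal(fac$id, 1:5)
  cells <- cellFromXY(g, fac$x, fac$y)
  expect_false(any(frictionBarrier(fr)[cells]))
})

test_that("roads and rivers stay inside the grid with one class each", {
  g <- GridSpec(15, 15)
  roads <- generateRoads(g, 1, 6)
  expect_length(roads, 6)
  for (r in roads) {
    expect_true(r$class %in% c("primary", "secondary", "tertiary"))
    expect_true(all(r$coords[, 1] >= 0 & r$coords[, 1] <= 15000))
    expect_true(all(r$coords[, 2] >= 0 & r$coords[, 2] <= 15000))
  }
  rivers <- generateRivers(g, 1, 2)
  expect_length(rivers, 2)
  expect_true(all(vapply(rivers, function(x) x$class, "") == "river"))
})

test_that("survey structure is internally consistent", {
  sc <- SyntheticScenario(GridSpec(25, 25), seed = 11, nClusters = 30,
                          nFacilities = 5)
  art <- generateScenario(sc)
  sv <- art$survey
  expect_lte(length(unique(sv$cluster_id)), 30)
  # each child belongs to exactly one household/cluster/region row
  expect_false(any(duplicated(sv[, c("cluster_id", "household_id",
                                     "child_id")])))
  # the recorded travel time is the surface value at the cluster cell
  expect_equal(sv$travel_time_min,
               sampleTravelTime(art$tt, sv[, c("x", "y")]))
  # attendance only defined for fevers
  expect_true(all(is.na(sv$attended_public[sv$fever == 0])))
  expect_true(all(sv$attended_public[sv$fever == 1] %in% 0:1))
  # one region per cluster
  byCluster <- tapply(sv$region_id, sv$cluster_id,
                      function(x) length(unique(x)))
  expect_true(all(byCluster == 1))
})

test_that("degenerate scenario parameters propagate as expected", {
  # near-zero ceiling probability: no child attends
  sc <- SyntheticScenario(GridSpec(15, 15), seed = 3, nClusters = 10,
                          nFacilities = 3,
                          trueDecay = DecayModel(C = 1e-9, A = 2, B = -0.5),
                          feverPrevalence = rep(0.99, 9))
  art <- generateScenario(sc)
  expect_true(all(art$survey$attended_public[art$survey$fever == 1] == 0))
  # near-one prevalence: nearly every child has fever
  expect_gt(mean(art$survey$fever), 0.9)
})

test_that("attendance proportions converge to the generating curve", {
  # large survey: binned attendance within 3 SE of the mean model
  # probability in each travel-time band
  sc <- SyntheticScenario(GridSpec(40, 40), seed = 17, nClusters = 400,
                          householdsPerCluster = 120, nFacilities = 8,
                          feverPrevalence = rep(0.5, 9))
  art <- generateScenario(sc)
  sv <- art$survey[art$survey$fever == 1, ]
  expect_gt(nrow(sv), 10000)
  x <- transformTime(sv$travel_time_min)
  bin <- cut(x, quantile(x, seq(0, 1, 0.2)), include.lowest = TRUE)
  p_true <- predictProbability(sc@trueDecay, sv$travel_time_min)
  for (b in levels(bin)) {
    idx <- bin == b
    n <- sum(idx)
    pbar <- mean(p_true[idx])
    se <- sqrt(pbar * (1 - pbar) / n)
    expect_lt(abs(mean(sv$attended_public[idx]) - pbar), 3 * se + 1e-9)
  }
})
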