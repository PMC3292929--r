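make_tt <- function(v, g) new("TravelTimeSurface", values = v, spec = g)
make_alloc <- function(v, g) new("AllocationSurface", values = v, spec = g)

test_that("catchment membership is exactly the thresholded allocation", {
  g <- GridSpec(20, 20)
  set.seed(2)
  v <- matrix(runif(400, 0, 400), 20, 20)
  v[1, 1] <- 0; v[sample(400, 10)] <- Inf
  al <- matrix(sample(1:3, 400, TRUE), 20, 20)
  al[is.infinite(v)] <- NA_integer_
  tt <- make_tt(v, g); alloc <- make_alloc(al, g)
  cs <- delineateCatchments(tt, alloc, 180)
  oracle <- al
  oracle[!(is.finite(v) & v <= 180)] <- NA_integer_
  expect_identical(gridValues(cs), oracle)
  # infinite threshold keeps every reachable cell; zero keeps facilities only
  expect_identical(is.na(gridValues(delineateCatchments(tt, alloc, Inf))),
                   !is.finite(v))
  cs0 <- delineateCatchments(tt, alloc, 0)
  expect_identical(!is.na(gridValues(cs0)), v == 0)
})

test_that("children and fever surfaces scale population by region rates", {
  g <- GridSpec(4, 4)
  pop <- GridRaster(625, g) # 10,000 people
  reg <- GridRaster(1L, g)
  tab <- data.frame(region_id = 1, under5_fraction = 0.15, prevalence = 0.2)
  ch <- childrenSurface(pop, reg, tab)
  expect_equal(sum(gridValues(ch)), 1500)
  fv <- feverSurface(ch, reg, tab)
  expect_equal(sum(gridValues(fv)), 300)
  # zero fraction gives a zero raster
  tab0 <- data.frame(region_id = 1, under5_fraction = 0, prevalence = 0.2)
  expect_true(all(gridValues(childrenSurface(pop, reg, tab0)) == 0))
  # per-region sums match hand computation on a two-region split
  reg2 <- GridRaster(matrix(c(rep(1L, 8), rep(2L, 8)), 4, 4), g)
  tab2 <- data.frame(region_id = 1:2, under5_fraction = c(0.1, 0.2),
                     prevalence = c(0.1, 0.3))
  ch2 <- childrenSurface(pop, reg2, tab2)
  expect_equal(sum(gridValues(ch2)[gridValues(reg2) == 1]), 8 * 625 * 0.1)
  expect_equal(sum(gridValues(ch2)[gridValues(reg2) == 2]), 8 * 625 * 0.2)
  # an id missing from the table is an error
  expect_error(childrenSurface(pop, GridRaster(3L, g), tab), "missing")
})

test_that("attendee split conserves fever cases cell by cell", {
  g <- GridSpec(5, 5)
  set.seed(4)
  fv <- GridRaster(matrix(runif(25, 0, 50), 5, 5), g)
  pr <- GridRaster(matrix(runif(25), 5, 5), g)
  sp <- expectedAttendance(fv, pr)
  expect_equal(gridValues(sp$attendees) + gridValues(sp$nonAttendees),
               gridValues(fv))
  one <- expectedAttendance(fv, GridRaster(1, g))
  expect_true(all(gridValues(one$nonAttendees) == 0))
  half <- expectedAttendance(fv, GridRaster(0.5, g))
  expect_equal(gridValues(half$attendees), gridValues(half$nonAttendees))
})

burden_fixture <- function(seed = 10) {
  g <- GridSpec(12, 12)
  set.seed(seed)
  pop <- GridRaster(matrix(rpois(144, 50), 12, 12), g)
  reg <- generateRegions(g, 3)
  tab <- data.frame(region_id = 1:3, under5_fraction = c(0.15, 0.18, 0.2),
                    prevalence = c(0.1, 0.2, 0.15))
  v <- matrix(runif(144, 0, 400), 12, 12); v[1, 1] <- 0
  v[sample(144, 6)] <- Inf
  al <- matrix(sample(1:2, 144, TRUE), 12, 12)
  al[is.infinite(v)] <- NA_integer_
  tt <- make_tt(v, g)
  m <- DecayModel(C = 0.766, A = 3.736, B = -0.609)
  prob <- probabilitySurface(m, tt)
  ch <- childrenSurface(pop, reg, tab)
  fv <- feverSurface(ch, reg, tab)
  att <- expectedAttendance(fv, prob)
  list(g = g, pop = pop, reg = reg, tab = tab, tt = tt,
       alloc = make_alloc(al, g), prob = prob, ch = ch, fv = fv, att = att)
}

test_that("burden summaries partition and conserve across stratifications", {
  f <- burden_fixture()
  catch <- delineateCatchments(f$tt, f$alloc, 180)
  tot <- summarizeBurden(f$ch, f$fv, f$att$attendees, "total",
                         catchments = catch)
  expect_equal(tot$expected_attendees + tot$expected_non_attendees,
               tot$fever_cases)
  for (strata in c("region", "time", "probability", "catchment")) {
    s <- summarizeBurden(f$ch, f$fv, f$att$attendees, strata,
                         regions = f$reg, tt = f$tt, probability = f$prob,
                         catchments = catch,
                         bandEdges = if (strata == "probability")
                           c(0.5, 0.6, 0.7, 0.75) else c(30, 60, 120, 180))
    # conservation inside every stratum
    expect_equal(s$expected_attendees + s$expected_non_attendees,
                 s$fever_cases)
    # exclusive strata partition the grand totals
    expect_equal(sum(s$children_u5), tot$children_u5)
    expect_equal(sum(s$fever_cases), tot$fever_cases)
    expect_equal(sum(s$expected_attendees), tot$expected_attendees)
  }
  expect_lte(tot$children_in_catchment, tot$children_u5)
})

test_that("cumulative time bands nest and match direct masks", {
  f <- burden_fixture()
  catch <- delineateCatchments(f$tt, f$alloc, 180)
  s <- summarizeBurden(f$ch, f$fv, f$att$attendees, "time", tt = f$tt,
                       catchments = catch, bandEdges = c(30, 60, 120, 180),
                       cumulative = TRUE)
  expect_true(all(diff(s$children_u5) >= 0))
  expect_true(all(diff(s$fever_cases) >= 0))
  direct30 <- sum(gridValues(f$fv)[is.finite(gridValues(f$tt)) &
                                   gridValues(f$tt) <= 30])
  expect_equal(s$fever_cases[1], direct30)
})

test_that("widening the threshold never shrinks catchment population", {
  f <- burden_fixture()
  prev <- -Inf
  for (thr in c(30, 60, 120, 180, 240, Inf)) {
    catch <- delineateCatchments(f$tt, f$alloc, thr)
    tot <- summarizeBurden(f$ch, f$fv, f$att$attendees, "total",
                           catchments = catch)
    expect_gte(tot$children_in_catchment, prev)
    prev <- tot$children_in_catchment
  }
})

test_that("burden counts are linear in population", {
  f <- burden_fixture()
  catch <- delineateCatchments(f$tt, f$alloc, 180)
  tot1 <- summarizeBurden(f$ch, f$fv, f$att$attendees, "total",
                          catchments = catch)
  pop2 <- GridRaster(gridValues(f$pop) * 2, f$g)
  ch2 <- childrenSurface(pop2, f$reg, f$tab)
  fv2 <- feverSurface(ch2, f$reg, f$tab)
  att2 <- expectedAttendance(fv2, f$prob)
  tot2 <- summarizeBurden(ch2, fv2, att2$attendees, "total",
                          catchments = catch)
  for (col in c("children_u5", "children_in_catchment", "fever_cases",
                "expected_attendees", "expected_non_attendees"))
    expect_equal(tot2[[col]], 2 * tot1[[col]])
})

test_that("survey proportions reproduce the Wald interval arithmetic", {
  expect_equal(proportionCI(401, 2283),
               c(pct = 17.6, lower = 16.0, upper = 19.1))
  expect_equal(proportionCI(0, 50), c(pct = 0, lower = 0, upper = 0))
  ci <- proportionCI(50, 100)
  expect_equal(ci[["pct"]], 50)
  expect_equal(ci[["upper"]] - ci[["pct"]], 9.8)
  expect_equal(ci[["pct"]] - ci[["lower"]], 9.8)
  expect_error(proportionCI(1, 0), "positive")
})

test_that("percentages round half away from zero at one decimal", {
  expect_equal(roundHalfUp(0.05, 1), 0.1)
  expect_equal(roundHalfUp(-0.05, 1), -0.1)
  expect_equal(roundHalfUp(12.345, 2), 12.35)
  expect_equal(roundHalfUp(2.5, 0), 3)
})
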