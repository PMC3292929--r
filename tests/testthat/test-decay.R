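test_that("time transform floors at one minute and matches arithmetic", {
  expect_equal(transformTime(1), 0)
  expect_equal(transformTime(0), transformTime(1)) # floor rule
  expect_equal(transformTime(180), log10(180))
  expect_equal(round(transformTime(180), 4), 2.2553)
  expect_equal(transformTime(180, "ln"), log(180))
  expect_equal(transformTime(180, "identity"), 180)
  expect_error(transformTime(-1), "non-negative")
  expect_error(transformTime(10, "log2"), "unknown transform")
})

test_that("quantile binning balances counts and preserves totals", {
  set.seed(3)
  rec <- data.frame(travel_time = rexp(401, 1 / 60), attended = rbinom(401, 1, 0.5))
  b <- binAttendance(rec, nBins = 15)
  expect_equal(sum(b$n), 401)
  expect_lte(diff(range(b$n)), 1)
  expect_true(all(diff(b$x) > 0))
  # bins are non-overlapping and cover the data
  expect_true(all(b$xmax[-nrow(b)] <= b$xmin[-1]))
  expect_equal(min(b$xmin), min(transformTime(rec$travel_time)))
  expect_equal(max(b$xmax), max(transformTime(rec$travel_time)))
  # one bin recovers the overall attendance fraction
  b1 <- binAttendance(rec, nBins = 1)
  expect_equal(b1$p, mean(rec$attended))
  # equal-width scheme spans the transformed range
  bw <- binAttendance(rec, nBins = 10, scheme = "equal-width")
  expect_equal(sum(bw$n), 401)
})

test_that("noiseless data on the curve are recovered to numerical precision", {
  x <- seq(0.2, 3.5, length.out = 10)
  p <- 0.5 / (1 + exp((2 - x) / -0.5))
  fit <- fitLogistic3(data.frame(x = x, p = p))
  expect_equal(fit@C, 0.5, tolerance = 1e-6)
  expect_equal(fit@A, 2, tolerance = 1e-6)
  expect_equal(fit@B, -0.5, tolerance = 1e-6)
  expect_lt(fit@diagnostics$ssr, 1e-10)
})

test_that("too few bins for three parameters is an error", {
  d <- data.frame(x = 1:3, p = c(0.7, 0.5, 0.3))
  expect_error(fitLogistic3(d), "at least 4")
})

test_that("reported SSR and t statistics are internally consistent", {
  m0 <- DecayModel(C = 0.766, A = 3.736, B = -0.609)
  rec <- simulate_records(m0, 5000, xmax = 3.2, seed = 21)
  fit <- fitLogistic3(rec, nBins = 15)
  b <- binAttendance(rec, nBins = 15)
  resid <- b$p - fit@C / (1 + exp((fit@A - b$x) / fit@B))
  d <- fit@diagnostics
  expect_equal(d$ssr, sum(resid^2), tolerance = 1e-10)
  expect_equal(d$rse, sqrt(d$ssr / (nrow(b) - 3)), tolerance = 1e-12)
  ct <- d$coefTable
  expect_equal(unname(ct[, "t value"]), unname(ct[, "Estimate"] / ct[, "Std. Error"]))
  expect_true(all(ct[, "Pr(>|t|)"] >= 0 & ct[, "Pr(>|t|)"] <= 1))
  expect_false(d$monotoneIncreasing)
})

test_that("fixing C at 1 reduces to the two-parameter logistic", {
  set.seed(8)
  x <- seq(0.2, 4, length.out = 12)
  p <- 1 / (1 + exp((2.5 - x) / -0.7)) + rnorm(12, sd = 0.01)
  p <- pmin(pmax(p, 0.001), 0.999)
  fit <- fitLogistic3(data.frame(x = x, p = p), fixC = 1)
  expect_equal(fit@C, 1)
  # independent reference: direct least squares over (A, B) with optim
  obj <- function(th) sum((p - 1 / (1 + exp((th[1] - x) / th[2])))^2)
  ref <- optim(c(2, -1), obj, method = "BFGS")
  expect_equal(fit@A, ref$par[1], tolerance = 1e-3)
  expect_equal(fit@B, ref$par[2], tolerance = 1e-3)
  expect_equal(fit@diagnostics$ssr, ref$value, tolerance = 1e-6)
})

test_that("a rising attendance pattern is fitted but flagged", {
  x <- seq(0.2, 3, length.out = 8)
  p <- seq(0.2, 0.7, length.out = 8)
  fit <- fitLogistic3(data.frame(x = x, p = p))
  expect_true(fit@diagnostics$monotoneIncreasing)
})

test_that("predicted probabilities follow the curve and its limits", {
  m <- DecayModel(C = 0.766, A = 3.736, B = -0.609)
  # at the inflection point the probability is exactly C/2
  expect_equal(predictProbability(m, 10^m@A), m@C / 2)
  # near zero travel time the curve approaches C from below
  p0 <- predictProbability(m, 0)
  expect_lt(p0, m@C)
  expect_gt(p0, 0.99 * m@C)
  # reference value at the 3-hour mark
  expect_equal(round(predictProbability(m, 180), 3), 0.704)
  # monotone decreasing, bounded by (0, C)
  t <- c(0, 1, 5, 30, 120, 600, 5000, 1e5)
  p <- predictProbability(m, t)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= m@C))
  # infinite time collapses to the limit
  expect_equal(predictProbability(m, Inf), 0)
})

test_that("probability surfaces map the travel-time raster cellwise", {
  m <- DecayModel(C = 0.766, A = 3.736, B = -0.609)
  g <- GridSpec(3, 3)
  v <- matrix(c(0, 10, 60, 120, 180, 240, 600, Inf, 30), 3, 3)
  tt <- new("TravelTimeSurface", values = v, spec = g)
  pr <- probabilitySurface(m, tt)
  expect_equal(gridValues(pr)[1, 1], predictProbability(m, 0))
  expect_equal(gridValues(pr)[2, 3], 0) # unreached
  expect_equal(gridValues(pr)[2, 2],
               predictProbability(m, 180))
  constant <- new("TravelTimeSurface", values = matrix(45, 3, 3), spec = g)
  expect_true(all(gridValues(probabilitySurface(m, constant)) ==
                  predictProbability(m, 45)))
})

test_that("decay models survive a JSON round trip", {
  m0 <- DecayModel(C = 0.766, A = 3.736, B = -0.609)
  rec <- simulate_records(m0, 2000, xmax = 3.2, seed = 4)
  fit <- fitLogistic3(rec)
  path <- tempfile(fileext = ".json")
  writeDecayModel(fit, path)
  back <- readDecayModel(path)
  expect_equal(back@C, fit@C)
  expect_equal(back@A, fit@A)
  expect_equal(back@B, fit@B)
  expect_equal(back@transform, fit@transform)
  expect_equal(back@diagnostics$ssr, fit@diagnostics$ssr)
})
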