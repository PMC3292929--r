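#' Transform travel time for the decay model
#'
#' Applies the model's time transform with a floor of `tFloor` minutes
#' guarding the logarithm at t = 0 (households in a facility cell have
#' near-zero but positive access time).
#'
#' @param t travel time in minutes (non-negative; `Inf` allowed)
#' @param transform "log10" (default), "ln" or "identity"
#' @param tFloor minutes floor applied before a log transform
#' @return transformed time x
#' @examples
#' transformTime(1)    # 0
#' transformTime(180)  # 2.2553
#' @export
transformTime <- function(t, transform = "log10", tFloor = 1) {
  if (any(t < 0, na.rm = TRUE)) stop("travel times must be non-negative")
  switch(transform,
    log10 = log10(pmax(t, tFloor)),
    ln = log(pmax(t, tFloor)),
    identity = t,
    stop(sprintf("unknown transform '%s'", transform)))
}

#' Bin attendance records by transformed travel time
#'
#' Groups fever records into bins of transformed travel time and returns,
#' per bin, the mean transformed time, the observed attendance proportion
#' and the record count. The quantile scheme assigns near-equal counts
#' (sizes differing by at most one when times are distinct); the
#' equal-width scheme cuts the transformed range into equal intervals.
#' Empty bins are dropped.
#'
#' @param records data.frame with columns `travel_time` (minutes) and
#'   `attended` (0/1)
#' @param nBins number of bins (default 15)
#' @param scheme "quantile" (default) or "equal-width"
#' @param transform,tFloor passed to [transformTime()]
#' @return data.frame with columns `x` (mean transformed time), `p`
#'   (attendance proportion), `n` (records), `xmin`, `xmax`
#' @export
binAttendance <- function(records, nBins = 15, scheme = "quantile",
                          transform = "log10", tFloor = 1) {
  if (!all(c("travel_time", "attended") %in% names(records)))
    stop("records need columns travel_time and attended")
  x <- transformTime(records$travel_time, transform, tFloor)
  y <- records$attended
  ok <- is.finite(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < nBins) stop("fewer records than bins")
  if (scheme == "quantile") {
    idx <- integer(n)
    idx[order(x)] <- ceiling(seq_len(n) * nBins / n)
  } else if (scheme == "equal-width") {
    rng <- range(x)
    if (diff(rng) == 0) idx <- rep(1L, n)
    else idx <- pmin(pmax(ceiling((x - rng[1]) / diff(rng) * nBins), 1L),
                     nBins)
  } else stop(sprintf("unknown binning scheme '%s'", scheme))
  out <- data.frame(
    x = as.numeric(tapply(x, idx, mean)),
    p = as.numeric(tapply(y, idx, mean)),
    n = as.integer(tapply(y, idx, length)),
    xmin = as.numeric(tapply(x, idx, min)),
    xmax = as.numeric(tapply(x, idx, max)))
  out <- out[out$n > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the three-parameter logistic distance-decay model
#'
#' Nonlinear least squares of binned attendance proportions on binned mean
#' transformed travel times, for the model
#' \deqn{Y = C / (1 + e^{(A - x)/B})}
#' Bins are weighted equally. Initialisation is multi-start: C starts at
#' the maximum bin proportion, A at the median bin time, and B at each of
#' -0.5, -1, 0.5, 1; the converged fit with the smallest sum of squared
#' residuals is kept. Coefficient t statistics and two-sided p values come
#' from the asymptotic (Jacobian-based) standard errors.
#'
#' A monotone-increasing proportion pattern (utilisation rising with
#' travel time) is not an error: the fit is returned with
#' `diagnostics$monotoneIncreasing = TRUE`.
#'
#' @param binned data.frame from [binAttendance()] (columns `x`, `p`), or a
#'   record data.frame, in which case it is binned first with `nBins`
#' @param transform,tFloor recorded in the returned model
#' @param nBins used only when `binned` is a raw record table
#' @param fixC optional: fix the upper asymptote (e.g. `fixC = 1` gives the
#'   standard two-parameter logistic)
#' @return a [DecayModel-class] with fit diagnostics
#' @examples
#' x <- seq(0, 3, length.out = 10)
#' truth <- DecayModel(C = 0.5, A = 2, B = -0.5)
#' binned <- data.frame(x = x, p = 0.5 / (1 + exp((2 - x) / -0.5)))
#' fitLogistic3(binned)
#' @export
fitLogistic3 <- function(binned, transform = "log10", tFloor = 1,
                         nBins = 15, fixC = NULL) {
  if ("travel_time" %in% names(binned))
    binned <- binAttendance(binned, nBins = nBins, transform = transform,
                            tFloor = tFloor)
  df <- data.frame(x = binned$x, p = binned$p)
  nFree <- if (is.null(fixC)) 3L else 2L
  if (nrow(df) < nFree + 1L)
    stop(sprintf("need at least %d non-degenerate bins to fit %d parameters",
                 nFree + 1L, nFree), call. = FALSE)
  starts <- list()
  C0 <- min(max(max(df$p), 0.05), 0.999)
  for (B0 in c(-0.5, -1, 0.5, 1))
    starts[[length(starts) + 1L]] <-
      if (is.null(fixC)) list(C = C0, A = median(df$x), B = B0)
      else list(A = median(df$x), B = B0)
  # logit-grid start: for fixed C the model is linear in logit(p / C),
  # so an OLS line gives (A, B); scan C and keep the best raw-scale SSR
  ssrAt <- function(C, A, B) sum((df$p - C / (1 + exp((A - df$x) / B)))^2)
  gridStart <- NULL; gridBest <- Inf
  Cgrid <- if (is.null(fixC)) seq(max(df$p) + 1e-4, 1, length.out = 40)
           else fixC
  for (Cg in Cgrid) {
    if (any(df$p <= 0 | df$p >= Cg)) next
    z <- log(df$p / (Cg - df$p))
    ab <- tryCatch(coef(stats::lm(z ~ df$x)), error = function(e) NULL)
    if (is.null(ab) || !all(is.finite(ab)) || ab[2] == 0) next
    Bg <- unname(1 / ab[2]); Ag <- unname(-ab[1] * Bg)
    v <- ssrAt(Cg, Ag, Bg)
    if (is.finite(v) && v < gridBest) {
      gridBest <- v
      gridStart <- if (is.null(fixC)) list(C = Cg, A = Ag, B = Bg)
                   else list(A = Ag, B = Bg)
    }
  }
  if (!is.null(gridStart)) starts <- c(list(gridStart), starts)
  form <- if (is.null(fixC)) p ~ C / (1 + exp((A - x) / B))
          else substitute(p ~ CFIX / (1 + exp((A - x) / B)),
                          list(CFIX = fixC))
  best <- NULL; errs <- character()
  for (st in starts) {
    lowerB <- if (is.null(fixC)) c(C = 1e-6, A = -Inf, B = -Inf)
              else c(A = -Inf, B = -Inf)
    upperB <- if (is.null(fixC)) c(C = 1, A = Inf, B = Inf)
              else c(A = Inf, B = Inf)
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = st,
                        lower = lowerB, upper = upperB,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) { errs <- c(errs, conditionMessage(fit)); next }
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
  }
  if (is.null(best))
    stop(paste0("logistic fit failed to converge from every start:\n  ",
                paste(unique(errs), collapse = "\n  ")), call. = FALSE)
  cf <- coef(best)
  sm <- summary(best)
  ssr <- deviance(best)
  dfree <- nrow(df) - nFree
  diag <- list(
    ssr = ssr,
    rse = sqrt(ssr / dfree),
    df = dfree,
    nBins = nrow(df),
    coefTable = sm$coefficients,
    converged = TRUE,
    monotoneIncreasing = !is.unsorted(df$p[order(df$x)]) && nrow(df) > 1)
  DecayModel(C = if (is.null(fixC)) cf[["C"]] else fixC,
             A = cf[["A"]], B = cf[["B"]],
             transform = transform, tFloor = tFloor, diagnostics = diag)
}

#' Predicted probability of facility attendance
#'
#' Evaluates the decay model at travel times in minutes. Infinite travel
#' time (unreached cells) yields the model's long-distance limit: 0 when B
#' is negative (decreasing utilisation), C when B is positive.
#'
#' @param model a [DecayModel-class]
#' @param t travel time in minutes
#' @return probabilities in `[0, C]`
#' @examples
#' m <- DecayModel(C = 0.766, A = 3.736, B = -0.609)
#' predictProbability(m, 180) # ~0.704: attendance still high at 3 hours
#' @export
predictProbability <- function(model, t) {
  x <- transformTime(t, model@transform, model@tFloor)
  p <- model@C / (1 + exp((model@A - x) / model@B))
  limit <- if (model@B < 0) 0 else model@C
  p[is.infinite(t)] <- limit
  p
}

#' Map attendance probability over a travel-time surface
#'
#' @param model a [DecayModel-class]
#' @param tt a [TravelTimeSurface-class]
#' @return a [GridRaster-class] of probabilities (0 on unreached cells for
#'   a decreasing model)
#' @export
probabilitySurface <- function(model, tt) {
  GridRaster(matrix(predictProbability(model, tt@values),
                    tt@spec@nrows, tt@spec@ncols), tt@spec)
}

#' Serialize or restore a decay model as JSON
#'
#' @param model a [DecayModel-class]
#' @param path file path
#' @return `readDecayModel` returns the [DecayModel-class]
#' @export
writeDecayModel <- function(model, path) {
  x <- list(C = model@C, A = model@A, B = model@B,
            transform = model@transform, tFloor = model@tFloor,
            diagnostics = model@diagnostics)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeDecayModel
#' @export
readDecayModel <- function(path) {
  x <- jsonlite::fromJSON(path)
  d <- if (is.null(x$diagnostics)) list() else as.list(x$diagnostics)
  if (!is.null(d$coefTable)) d$coefTable <- as.matrix(d$coefTable)
  DecayModel(C = x$C, A = x$A, B = x$B, transform = x$transform,
             tFloor = x$tFloor, diagnostics = d)
}
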