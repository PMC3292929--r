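#' Delineate facility catchments under a travel-time threshold
#'
#' A cell belongs to the catchment of its allocated (least-cost nearest)
#' facility exactly when its travel time does not exceed the threshold;
#' all other cells are outside every catchment. The default 3-hour rule
#' reflects the point beyond which modelled utilisation falls away, and
#' deliberately leaves some populations outside the reach of any facility.
#'
#' @param tt a [TravelTimeSurface-class]
#' @param alloc the matching [AllocationSurface-class]
#' @param threshold minutes (default 180)
#' @return a [CatchmentSet-class]
#' @export
delineateCatchments <- function(tt, alloc, threshold = 180) {
  stop_if_grid_mismatch(tt@spec, alloc@spec,
                        what = "travel-time and allocation surfaces")
  member <- alloc@values
  member[!(is.finite(tt@values) & tt@values <= threshold)] <- NA_integer_
  new("CatchmentSet", membership = member, threshold = threshold,
      spec = tt@spec)
}

#' Under-five population surface
#'
#' Scales a total-population raster to children aged 0-4 by multiplying
#' each cell by its region's under-five fraction.
#'
#' @param population a [GridRaster-class] of person counts
#' @param regions a [GridRaster-class] of region ids
#' @param regionTable data.frame with columns `region_id` and
#'   `under5_fraction` (and, for [feverSurface()], `prevalence`)
#' @return a [GridRaster-class] of expected child counts (real-valued)
#' @export
childrenSurface <- function(population, regions, regionTable) {
  stop_if_grid_mismatch(population@spec, regions@spec,
                        what = "population and region rasters")
  frac <- region_lookup(regions, regionTable, "under5_fraction")
  GridRaster(population@values * frac, population@spec)
}

#' Expected fever-case surface
#'
#' Applies each region's fever prevalence uniformly to the under-five
#' population of its cells, one episode per child per period.
#'
#' @param children a [GridRaster-class] from [childrenSurface()]
#' @param regions region-id raster
#' @param regionTable see [childrenSurface()]
#' @return a [GridRaster-class] of expected fever cases
#' @export
feverSurface <- function(children, regions, regionTable) {
  stop_if_grid_mismatch(children@spec, regions@spec,
                        what = "children and region rasters")
  prev <- region_lookup(regions, regionTable, "prevalence")
  GridRaster(children@values * prev, children@spec)
}

region_lookup <- function(regions, regionTable, column) {
  if (!all(c("region_id", column) %in% names(regionTable)))
    stop(sprintf("region table needs columns region_id and %s", column),
         call. = FALSE)
  ids <- regions@values
  m <- match(ids, regionTable$region_id)
  if (any(is.na(m) & !is.na(ids)))
    stop("region raster contains ids missing from the region table",
         call. = FALSE)
  matrix(regionTable[[column]][m], nrow(ids), ncol(ids))
}

#' Split fever cases into expected attendees and non-attendees
#'
#' Per cell, attendees = fever cases x attendance probability and
#' non-attendees = fever cases x (1 - probability); the two add back to
#' the fever surface exactly.
#'
#' @param fever a [GridRaster-class] of expected fever cases
#' @param probability a [GridRaster-class] of attendance probabilities
#' @return list with [GridRaster-class] elements `attendees` and
#'   `nonAttendees`
#' @export
expectedAttendance <- function(fever, probability) {
  stop_if_grid_mismatch(fever@spec, probability@spec,
                        what = "fever and probability rasters")
  p <- probability@values
  list(attendees = GridRaster(fever@values * p, fever@spec),
       nonAttendees = GridRaster(fever@values * (1 - p), fever@spec))
}

#' Round half away from zero
#'
#' The rounding convention of the reported tables: 0.05 at one decimal
#' rounds up in magnitude.
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
roundHalfUp <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Stratified burden summary
#'
#' Aggregates children, fever cases and expected attendees over a chosen
#' stratification: `region` (per region id), `time` (travel-time bands),
#' `probability` (attendance-probability bands), `catchment` (per
#' facility), or `total`. Time bands may be cumulative (children within 30
#' minutes, within 1 hour, ...) or exclusive; the ">= last edge" stratum is
#' always appended for exclusive bands, covering the cells beyond the final
#' edge (including unreached cells). `children_in_catchment` counts only
#' cells inside the threshold catchments, while fever cases and attendance
#' are evaluated everywhere, so populations beyond the threshold still
#' contribute expected cases.
#'
#' @param children,fever,attendees [GridRaster-class] layers on one grid
#' @param strata one of "region", "time", "probability", "catchment",
#'   "total"
#' @param regions region-id raster (for `strata = "region"`)
#' @param tt travel-time surface (for `strata = "time"`)
#' @param probability probability raster (for `strata = "probability"`)
#' @param catchments a [CatchmentSet-class] (used for
#'   `children_in_catchment` in all stratifications and as the grouping for
#'   `strata = "catchment"`)
#' @param bandEdges numeric edges for time (minutes) or probability bands
#' @param cumulative logical; cumulative bands ("within x") instead of
#'   exclusive intervals (time and probability strata)
#' @return data.frame with columns `stratum`, `children_u5`,
#'   `children_in_catchment`, `fever_cases`, `expected_attendees`,
#'   `expected_non_attendees`, `pct_attendees`, `pct_non_attendees`
#' @export
summarizeBurden <- function(children, fever, attendees,
                            strata = c("total", "region", "time",
                                       "probability", "catchment"),
                            regions = NULL, tt = NULL, probability = NULL,
                            catchments = NULL,
                            bandEdges = c(30, 60, 120, 180),
                            cumulative = FALSE) {
  strata <- match.arg(strata)
  ch <- children@values; fv <- fever@values; at <- attendees@values
  inCatch <- if (is.null(catchments)) matrix(TRUE, nrow(ch), ncol(ch))
             else !is.na(catchments@membership)

  sum_stratum <- function(mask, label) {
    mask[is.na(mask)] <- FALSE
    data.frame(stratum = label,
               children_u5 = sum(ch[mask], na.rm = TRUE),
               children_in_catchment = sum(ch[mask & inCatch], na.rm = TRUE),
               fever_cases = sum(fv[mask], na.rm = TRUE),
               expected_attendees = sum(at[mask], na.rm = TRUE),
               expected_non_attendees = sum(fv[mask] - at[mask], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }

  rows <- switch(strata,
    total = list(sum_stratum(matrix(TRUE, nrow(ch), ncol(ch)), "total")),
    region = {
      if (is.null(regions)) stop("region stratification needs a region raster")
      ids <- sort(unique(as.vector(regions@values)))
      lapply(ids, function(i) sum_stratum(regions@values == i,
                                          paste0("region_", i)))
    },
    time = {
      if (is.null(tt)) stop("time stratification needs a travel-time surface")
      v <- tt@values
      if (cumulative) {
        lapply(bandEdges, function(e)
          sum_stratum(is.finite(v) & v <= e, sprintf("<= %g min", e)))
      } else {
        lo <- c(0, bandEdges); hi <- c(bandEdges, Inf)
        lab <- c(sprintf("%g - %g min", lo[-length(lo)], hi[-length(hi)]),
                 sprintf("> %g min", bandEdges[length(bandEdges)]))
        lapply(seq_along(lo), function(i) {
          m <- if (is.infinite(hi[i])) v > lo[i] | !is.finite(v)
               else is.finite(v) & v > lo[i] & v <= hi[i]
          if (i == 1) m <- m | (is.finite(v) & v == 0)
          sum_stratum(m, lab[i])
        })
      }
    },
    probability = {
      if (is.null(probability))
        stop("probability stratification needs a probability raster")
      v <- probability@values
      if (cumulative) {
        lapply(bandEdges, function(e)
          sum_stratum(v <= e, sprintf("<= %g", e)))
      } else {
        lo <- c(-Inf, bandEdges); hi <- c(bandEdges, Inf)
        lab <- c(sprintf("< %g", bandEdges[1]),
                 if (length(bandEdges) > 1)
                   sprintf("%g - %g", bandEdges[-length(bandEdges)],
                           bandEdges[-1]),
                 sprintf("> %g", bandEdges[length(bandEdges)]))
        lapply(seq_along(lo), function(i)
          sum_stratum(v > lo[i] & v <= c(bandEdges, Inf)[i], lab[i]))
      }
    },
    catchment = {
      if (is.null(catchments))
        stop("catchment stratification needs a CatchmentSet")
      ids <- sort(unique(catchments@membership[!is.na(catchments@membership)]))
      out <- lapply(ids, function(i)
        sum_stratum(catchments@membership == i, paste0("facility_", i)))
      c(out, list(sum_stratum(is.na(catchments@membership), "outside")))
    })
  out <- do.call(rbind, rows)
  out$pct_attendees <- roundHalfUp(
    100 * out$expected_attendees / pmax(out$fever_cases, .Machine$double.eps))
  out$pct_non_attendees <- roundHalfUp(
    100 * out$expected_non_attendees /
      pmax(out$fever_cases, .Machine$double.eps))
  rownames(out) <- NULL
  out
}

#' Binomial proportion with a Wald confidence interval
#'
#' Point estimate and normal-approximation interval for a survey
#' proportion, reported as percentages rounded half-away-from-zero to one
#' decimal (the convention of the survey tables).
#'
#' @param successes,n counts
#' @param level confidence level (default 0.95)
#' @return named numeric: `pct`, `lower`, `upper` (percent, 1 dp)
#' @examples
#' proportionCI(401, 2283) # 17.6 [16.0, 19.1]
#' @export
proportionCI <- function(successes, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  p <- successes / n
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(p * (1 - p) / n)
  c(pct = roundHalfUp(100 * p),
    lower = roundHalfUp(100 * max(p - z * se, 0)),
    upper = roundHalfUp(100 * min(p + z * se, 1)))
}
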