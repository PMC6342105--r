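#' Realized thermal range of a species
#'
#' Minimum and maximum temperature over the catchments a species occupies;
#' the maximum is the critical temperature (CT), and the thermal range is
#' CT minus the minimum temperature of occurrence.
#'
#' @param t_occupied Temperatures at the occupied catchments, degC.
#' @return List: `t_min_occ`, `ct`, `thermal_range`.
#' @export
thermal_range <- function(t_occupied) {
  t_occupied <- t_occupied[is.finite(t_occupied)]
  if (length(t_occupied) < 1)
    stopf("thermal_range: species has no presences")
  list(t_min_occ = min(t_occupied), ct = max(t_occupied),
       thermal_range = max(t_occupied) - min(t_occupied))
}

#' Preferred temperature of a unimodal response curve
#'
#' The temperature maximising the fitted probability of occurrence, found
#' by a coarse grid argmax refined with [stats::optimize()] (golden-section
#' with parabolic interpolation) to the requested tolerance.  Defined only
#' for unimodal curves (types I--III); a near-flat plateau around the
#' maximum is flagged, in which case the returned value sits within the
#' plateau.
#'
#' @param object A `trc` object or a function of temperature.
#' @param range Temperature range when `object` is a function.
#' @param classification Optional `trc_classification`; when supplied, a
#'   non-unimodal type raises an error.
#' @param tol Optimisation tolerance, degC.
#' @return List: `t_pref`, `p_at_pref`, `plateau` (flag).
#' @export
find_tpref <- function(object, range = NULL, classification = NULL,
                       tol = 1e-4) {
  if (!is.null(classification) &&
      !classification$trc_type %in% c("I", "II", "III"))
    stopf("find_tpref: preferred temperature is defined only for unimodal types I-III (got %s)",
          classification$trc_type)
  if (inherits(object, "trc")) {
    f <- function(tt) predict(object, temperature = tt)
    rng <- object$range
  } else {
    if (is.null(range)) stopf("find_tpref: range required for a function")
    f <- object; rng <- sort(range)
  }
  gp <- 256
  Tg <- seq(rng[1], rng[2], length.out = gp)
  p <- f(Tg)
  i <- which.max(p)
  lo <- Tg[max(1, i - 1)]; hi <- Tg[min(gp, i + 1)]
  if (lo == hi) {
    t_pref <- lo; p_pref <- p[i]
  } else {
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
    t_pref <- opt$maximum; p_pref <- opt$objective
    if (p[i] > p_pref) { t_pref <- Tg[i]; p_pref <- p[i] }
  }
  plateau <- sum(p >= p_pref - 1e-9 * max(p_pref, 1)) > 3
  list(t_pref = t_pref, p_at_pref = p_pref, plateau = plateau)
}

#' Warming tolerance
#'
#' WT = CT - T_pref: how much warming the species' occupied range could
#' absorb before its preferred temperature reaches the current maximum
#' temperature of occurrence.
#'
#' @param ct Critical temperature (max temperature of occurrence), degC.
#' @param t_pref Preferred temperature, degC.
#' @return WT in degC (non-negative when t_pref lies in the observed range).
#' @export
warming_tolerance <- function(ct, t_pref) ct - t_pref

#' Safety margin
#'
#' SM = T_pref - T_av, the preferred temperature minus the average
#' temperature over the species' current range.  A negative safety margin
#' means the preferred temperature is already exceeded on average.
#'
#' @param t_pref Preferred temperature, degC.
#' @param t_av Average temperature of the current range, degC.
#' @return SM in degC.
#' @export
safety_margin <- function(t_pref, t_av) t_pref - t_av

#' Thermal properties of one species for one temperature variable
#'
#' Combines the realized range statistics with the curve-derived preferred
#' temperature (types I--III only): `t_min_occ`, CT, thermal range, T_av
#' (mean temperature over occupied catchments, or the range midpoint),
#' T_pref, WT = CT - T_pref, SM = T_pref - T_av, and the mean latitude of
#' the occupied catchments (restricted to `region` when given).
#'
#' @param object A `trc` fit for the species and variable.
#' @param classification Its `trc_classification`.
#' @param t_occupied Temperatures of occupied catchments, degC.
#' @param lat_occupied Latitudes of occupied catchments (optional).
#' @param region Optional list with `lat` (and optionally `lon`) bounds;
#'   requires `lon_occupied` when a longitude box is given.
#' @param lon_occupied Longitudes of occupied catchments (optional).
#' @param t_av_method `"occupied_mean"` (default) or `"midpoint"`.
#' @return One-row data.frame of class `trc_properties`.
#' @export
thermal_properties <- function(object, classification, t_occupied,
                               lat_occupied = NULL, region = NULL,
                               lon_occupied = NULL,
                               t_av_method = c("occupied_mean", "midpoint")) {
  t_av_method <- match.arg(t_av_method)
  tr <- thermal_range(t_occupied)
  t_av <- if (t_av_method == "occupied_mean") mean(t_occupied)
          else (tr$t_min_occ + tr$ct) / 2
  unimodal <- classification$trc_type %in% c("I", "II", "III")
  if (unimodal) {
    tp <- find_tpref(object, classification = classification)
    t_pref <- tp$t_pref
    wt <- warming_tolerance(tr$ct, t_pref)
    sm <- safety_margin(t_pref, t_av)
  } else {
    t_pref <- wt <- sm <- NA_real_
  }
  mean_lat <- NA_real_
  if (!is.null(lat_occupied)) {
    keep <- rep(TRUE, length(lat_occupied))
    if (!is.null(region)) {
      if (!is.null(region$lat))
        keep <- keep & lat_occupied >= region$lat[1] &
          lat_occupied <= region$lat[2]
      if (!is.null(region$lon) && !is.null(lon_occupied))
        keep <- keep & lon_occupied >= region$lon[1] &
          lon_occupied <= region$lon[2]
    }
    if (any(keep)) mean_lat <- mean(lat_occupied[keep])
  }
  out <- data.frame(
    species_id = object$species_id %||% NA_character_,
    variable = object$variable %||% NA_character_,
    trc_type = classification$trc_type,
    t_min_occ = tr$t_min_occ, ct = tr$ct,
    thermal_range = tr$thermal_range, t_av = t_av,
    t_pref = t_pref, wt = wt, sm = sm, mean_latitude = mean_lat,
    stringsAsFactors = FALSE)
  class(out) <- c("trc_properties", "data.frame")
  out
}

#' Latitudinal summary of warming tolerance or safety margin
#'
#' Averages a per-species thermal statistic in 1-degree latitude bins and
#' adds a local-regression trend over the species-level points.  Bins
#' supported by few species are flagged low-confidence: values at high
#' latitudes rest on few species and should be treated with caution.
#'
#' @param props data.frame with `mean_latitude` and the statistic column.
#' @param statistic Column to summarise, `"wt"` or `"sm"`.
#' @param bin_width Latitude bin width, degrees.
#' @param span Local-regression span.
#' @param min_count Bin count below which the bin is flagged.
#' @return data.frame: `lat_bin` (centre), `mean`, `count`,
#'   `low_confidence`, `trend`.
#' @export
latitudinal_summary <- function(props, statistic = c("wt", "sm"),
                                bin_width = 1, span = 0.75, min_count = 5) {
  statistic <- match.arg(statistic)
  x <- props[[statistic]]
  keep <- !is.na(x) & !is.na(props$mean_latitude)
  x <- x[keep]; lat <- props$mean_latitude[keep]
  if (!length(x))
    return(data.frame(lat_bin = numeric(0), mean = numeric(0),
                      count = integer(0), low_confidence = logical(0),
                      trend = numeric(0)))
  bin <- floor(lat / bin_width) * bin_width + bin_width / 2
  agg <- stats::aggregate(x, by = list(lat_bin = bin), FUN = mean)
  cnt <- stats::aggregate(x, by = list(lat_bin = bin), FUN = length)
  out <- data.frame(lat_bin = agg$lat_bin, mean = agg$x,
                    count = as.integer(cnt$x))
  out$low_confidence <- out$count < min_count
  out$trend <- NA_real_
  if (length(x) >= 10 && length(unique(lat)) >= 5) {
    lo <- stats::loess(x ~ lat, span = span, degree = 1)
    out$trend <- stats::predict(lo, newdata = data.frame(lat = out$lat_bin))
  }
  out
}
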