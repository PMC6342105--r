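#' The four temperature variables
#'
#' Every per-species analysis is run once per variable: annual mean and
#' warmest-month maximum of air temperature, and the same two after the
#' monthly air-to-water transform.
#'
#' @return Character vector of the four variable names.
#' @export
temperature_variables <- function() {
  c("Tmean_air", "Tmax_air", "Tmean_water", "Tmax_water")
}

#' Logistic air-to-water temperature model
#'
#' Coefficients of the S-shaped global regression relating monthly mean air
#' temperature to stream water temperature,
#' `Tw = upper_bound / (1 + exp(-steepness * (Ta - inflection)))`.
#' The transform is monotone increasing and bounded in (0, upper_bound);
#' at the inflection point it returns half the upper bound.  Defaults are
#' representative coefficients of the global model family; all three are
#' configuration.
#'
#' @param upper_bound Asymptotic maximum water temperature, degC (> 0).
#' @param steepness Logistic steepness, per degC (> 0).
#' @param inflection Air temperature at the curve midpoint, degC.
#' @return A list of class `air_water_model`.
#' @export
air_water_model <- function(upper_bound = 32.0, steepness = 0.13,
                            inflection = 13.3) {
  if (upper_bound <= 0 || steepness <= 0)
    stopf("invalid air-water model: upper_bound and steepness must be > 0")
  structure(list(upper_bound = upper_bound, steepness = steepness,
                 inflection = inflection),
            class = "air_water_model")
}

#' Transform air temperature to stream water temperature
#'
#' @param t_air Air temperature(s), degC; must be finite.
#' @param model An [air_water_model()].
#' @return Water temperature(s), degC, in (0, upper_bound).
#' @export
air_to_water <- function(t_air, model = air_water_model()) {
  stopifnot(inherits(model, "air_water_model"))
  if (any(!is.finite(t_air))) stopf("air_to_water: non-finite air temperature")
  model$upper_bound /
    (1 + exp(-model$steepness * (t_air - model$inflection)))
}

#' Derive water temperature variables from monthly air temperatures
#'
#' Applies the logistic transform to each of the 12 monthly mean air
#' temperatures and averages the transformed values (transform-then-average,
#' never average-then-transform) to obtain `Tmean_water`.  `Tmax_water` is
#' the transform of the warmest-month value, taken from the `Tmax_air`
#' column when present (so the monthly-mean-to-maximum offset carries
#' through) and from the warmest monthly mean otherwise; because the
#' transform is monotone this equals the maximum of the transformed months.
#'
#' @param catchments Catchment table with `month_01`..`month_12` columns.
#' @param model An [air_water_model()].
#' @return `catchments` with `Tmean_water` and `Tmax_water` columns appended.
#' @export
derive_water_variables <- function(catchments, model = air_water_model()) {
  mcols <- sprintf("month_%02d", 1:12)
  missing <- setdiff(mcols, names(catchments))
  if (length(missing))
    stopf("missing monthly columns (%s) in catchment table",
          paste(missing, collapse = ", "))
  m <- as.matrix(catchments[mcols])
  bad <- which(!stats::complete.cases(m))
  if (length(bad))
    stopf("missing monthly values for catchment(s): %s",
          paste(catchments$catchment_id[bad], collapse = ", "))
  tw <- air_to_water(m, model)
  catchments$Tmean_water <- rowMeans(matrix(tw, nrow = nrow(m)))
  tmax_src <- if (!is.null(catchments$Tmax_air)) catchments$Tmax_air
              else apply(m, 1, max)
  catchments$Tmax_water <- air_to_water(tmax_src, model)
  catchments
}

#' Mean of gridded cell values per catchment
#'
#' Tabular stand-in for raster zonal statistics: the arithmetic mean of the
#' member cells of each catchment.  Catchments in the universe with no cells
#' are reported as `NA`, never as zero.
#'
#' @param cell_values Numeric vector of cell values, degC.
#' @param cell_catchment Catchment id of each cell.
#' @param universe Character vector of all catchment ids.
#' @return data.frame `catchment_id`, `mean_value`, `n_cells`.
#' @export
zonal_mean <- function(cell_values, cell_catchment, universe) {
  stopifnot(length(cell_values) == length(cell_catchment))
  unknown <- setdiff(unique(cell_catchment), universe)
  if (length(unknown))
    stopf("cells assigned to unknown catchment id(s): %s",
          paste(unknown, collapse = ", "))
  f <- factor(cell_catchment, levels = universe)
  sums <- tapply(cell_values, f, sum)
  n <- tabulate(f, nbins = length(universe))
  data.frame(catchment_id = universe,
             mean_value = as.numeric(sums) / ifelse(n == 0, NA, n),
             n_cells = n, stringsAsFactors = FALSE)
}

#' Ensemble mean across climate-model projections
#'
#' @param projections data.frame or matrix, one column per climate model,
#'   rows aligned on catchments; or a list of named vectors keyed by
#'   catchment id.
#' @return Numeric vector of per-catchment means across models.
#' @export
ensemble_mean <- function(projections) {
  if (is.list(projections) && !is.data.frame(projections)) {
    ids <- lapply(projections, names)
    ref <- ids[[1]]
    for (k in seq_along(ids)) {
      miss <- union(setdiff(ref, ids[[k]]), setdiff(ids[[k]], ref))
      if (length(miss))
        stopf("misaligned catchment sets across models; offending ids: %s",
              paste(miss, collapse = ", "))
    }
    projections <- do.call(cbind, lapply(projections, function(v) v[ref]))
    rownames(projections) <- ref
  }
  m <- as.matrix(projections)
  if (ncol(m) < 1) stopf("ensemble_mean: need at least one model")
  rowMeans(m)
}
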