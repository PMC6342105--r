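#' Eight canonical thermal response shapes
#'
#' Names of the generating response shapes used by the virtual-species
#' simulator.  Each maps one-to-one onto a response curve type of the
#' classifier: gaussian = Type I (unimodal symmetric), right_skewed = II,
#' left_skewed = III, flat = IV, rise_plateau = V, plateau_fall = VI,
#' increasing = VII, decreasing = VIII.
#'
#' @return Character vector of length 8.
#' @export
trc_shapes <- function() {
  c("gaussian", "right_skewed", "left_skewed", "flat",
    "rise_plateau", "plateau_fall", "increasing", "decreasing")
}

shape_to_type <- function(shape) {
  map <- c(gaussian = "I", right_skewed = "II", left_skewed = "III",
           flat = "IV", rise_plateau = "V", plateau_fall = "VI",
           increasing = "VII", decreasing = "VIII")
  unname(map[shape])
}

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic landscape and
#' virtual-species generators.  Defaults describe a mid-latitude gradient
#' (35--70 degrees N) with a 0.6 degC per degree-latitude lapse in annual mean
#' air temperature, an 8 degC seasonal half-amplitude, and virtual species
#' with peak occurrence probability 0.6 and thermal breadths of 3--6 degC.
#'
#' @param n_catchments Number of catchments in the landscape.
#' @param lat_range Latitude span, degrees N (length 2, within -90..90).
#' @param lapse_rate Decline of annual mean air temperature per degree
#'   latitude, degC.
#' @param base_temp Annual mean air temperature at the southern edge, degC.
#' @param spatial_noise_sd SD of catchment-level temperature noise, degC.
#' @param seasonal_amplitude Half-amplitude of the sinusoidal annual cycle,
#'   degC (the value at the latitudinal midpoint).
#' @param amplitude_lat_gain Fractional south-to-north increase of the
#'   seasonal amplitude (continentality); 0 gives a uniform amplitude.
#' @param tmax_offset Offset of warmest-month maximum over the warmest monthly
#'   mean, degC.
#' @param n_species_per_type Virtual species simulated per response shape.
#' @param max_prob Peak occurrence probability of simulated species, in (0,1].
#' @param breadth_range Range of thermal breadths (Gaussian SD), degC.
#' @param skew_range Range of right/left breadth ratios for skewed shapes
#'   (values > 1; the left-skewed shape uses the reciprocal).
#' @param warming_offset Projected warming added to baseline, degC.
#' @param n_climate_models Number of climate models in the projection ensemble.
#' @param model_spread_sd SD of model-specific spatially correlated
#'   perturbations, degC.
#' @param min_occurrences Minimum presences required per simulated species.
#' @param seed Integer seed; identical seeds give bit-identical tables.
#' @return A list of class `trc_sim_config`.
#' @export
trc_sim_config <- function(n_catchments = 2000,
                           lat_range = c(35, 70),
                           lapse_rate = 0.6,
                           base_temp = 16,
                           spatial_noise_sd = 1,
                           seasonal_amplitude = 8,
                           amplitude_lat_gain = 0.6,
                           tmax_offset = 5,
                           n_species_per_type = 5,
                           max_prob = 0.6,
                           breadth_range = c(3, 6),
                           skew_range = c(2.5, 3.5),
                           warming_offset = 2,
                           n_climate_models = 3,
                           model_spread_sd = 0.3,
                           min_occurrences = 50,
                           seed = 1) {
  cfg <- list(n_catchments = n_catchments, lat_range = sort(lat_range),
              lapse_rate = lapse_rate, base_temp = base_temp,
              spatial_noise_sd = spatial_noise_sd,
              seasonal_amplitude = seasonal_amplitude,
              amplitude_lat_gain = amplitude_lat_gain,
              tmax_offset = tmax_offset,
              n_species_per_type = n_species_per_type,
              max_prob = max_prob, breadth_range = sort(breadth_range),
              skew_range = sort(skew_range),
              warming_offset = warming_offset,
              n_climate_models = n_climate_models,
              model_spread_sd = model_spread_sd,
              min_occurrences = min_occurrences, seed = seed)
  if (!is.numeric(cfg$n_catchments) || cfg$n_catchments < 2)
    stopf("invalid config: n_catchments must be >= 2")
  if (any(abs(cfg$lat_range) > 90) || length(cfg$lat_range) != 2)
    stopf("invalid config: lat_range must lie within [-90, 90]")
  if (cfg$max_prob <= 0 || cfg$max_prob > 1)
    stopf("invalid config: max_prob must be in (0, 1]")
  if (any(cfg$breadth_range <= 0))
    stopf("invalid config: breadths must be strictly positive")
  if (cfg$n_climate_models < 1)
    stopf("invalid config: n_climate_models must be >= 1")
  class(cfg) <- "trc_sim_config"
  cfg
}

#' Simulate a catchment landscape with a latitudinal temperature gradient
#'
#' Draws catchment positions uniformly over the configured latitude band and
#' builds 12 monthly mean air temperatures per catchment as a sinusoidal
#' annual cycle (warmest in July) around a latitude-declining annual mean
#' plus catchment-level Gaussian noise.  The derived variables follow:
#' `Tmean_air` is the mean of the 12 monthlies and `Tmax_air` the warmest
#' monthly mean plus the configured monthly-mean-to-maximum offset.
#'
#' @param cfg A [trc_sim_config()] object.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A data.frame with columns `catchment_id`, `latitude`, `longitude`,
#'   `month_01`..`month_12`, `Tmean_air`, `Tmax_air`, `excluded`.
#' @export
sim_catchments <- function(cfg = trc_sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "trc_sim_config"))
  n <- cfg$n_catchments
  with_seed(seed %||% cfg$seed, {
    lat <- runif(n, cfg$lat_range[1], cfg$lat_range[2])
    lon <- runif(n, -10, 40)
    tmean_true <- cfg$base_temp - cfg$lapse_rate * (lat - cfg$lat_range[1]) +
      rnorm(n, 0, cfg$spatial_noise_sd)
    # seasonal amplitude grows with latitude (continentality), so the
    # warmest-month variable is not a deterministic shift of the annual mean
    rel_lat <- if (diff(cfg$lat_range) > 0)
      (lat - cfg$lat_range[1]) / diff(cfg$lat_range) else lat * 0
    amp <- cfg$seasonal_amplitude *
      (1 + cfg$amplitude_lat_gain * (rel_lat - 0.5))
    months <- tmean_true + amp %o% cos(2 * pi * (1:12 - 7) / 12) +
      matrix(rnorm(n * 12, 0, cfg$spatial_noise_sd / 3), n, 12)
    colnames(months) <- sprintf("month_%02d", 1:12)
    out <- data.frame(catchment_id = sprintf("c%05d", seq_len(n)),
                      latitude = lat, longitude = lon,
                      months,
                      Tmean_air = rowMeans(months),
                      Tmax_air = apply(months, 1, max) + cfg$tmax_offset,
                      excluded = FALSE,
                      stringsAsFactors = FALSE)
    out
  })
}

#' Evaluate a generating thermal response curve
#'
#' The true probability-of-occurrence curve of a virtual species.  Unimodal
#' shapes use a (two-sided) Gaussian kernel: skewed shapes split the
#' breadth as `b / sqrt(skew)` on the short flank and `b * sqrt(skew)` on
#' the long flank (warm flank long for `right_skewed`, cold flank long for
#' `left_skewed`), so the flank ratio is `skew` while the overall width
#' stays on the scale of `breadth`.  `flat` is a constant at half the peak
#' probability.  Plateau shapes are scaled logistic curves with steepness
#' `breadth / 4`, saturating inside the gradient.  Monotone shapes are a
#' single Gaussian flank (flat at `p_max` beyond `t_opt`): placed with
#' `t_opt` at or past the edge of the observed gradient they are the
#' canonical range-truncated response of a species whose optimum lies
#' outside the sampled temperatures.
#'
#' @param temperature Numeric vector of temperatures, degC.
#' @param shape One of [trc_shapes()].
#' @param t_opt Curve centre: peak for unimodal shapes, logistic midpoint for
#'   plateau/monotone shapes, degC.
#' @param breadth Thermal breadth (Gaussian SD or 4x logistic scale), degC.
#' @param skew Right/left breadth ratio (> 1) used by skewed shapes.
#' @param p_max Peak probability in [0, 1].
#' @return Vector of probabilities, bounded by `p_max`.
#' @export
trc_response_prob <- function(temperature, shape, t_opt, breadth,
                              skew = 3, p_max = 0.6) {
  shape <- match.arg(shape, trc_shapes())
  d <- temperature - t_opt
  s <- breadth / 4
  switch(shape,
    gaussian = p_max * exp(-d^2 / (2 * breadth^2)),
    right_skewed = {
      b <- ifelse(d > 0, breadth * sqrt(skew), breadth / sqrt(skew))
      p_max * exp(-d^2 / (2 * b^2))
    },
    left_skewed = {
      b <- ifelse(d < 0, breadth * sqrt(skew), breadth / sqrt(skew))
      p_max * exp(-d^2 / (2 * b^2))
    },
    flat = rep(p_max / 2, length(temperature)),
    rise_plateau = p_max * stats::plogis(d / s),
    plateau_fall = p_max * stats::plogis(-d / s),
    increasing = p_max * exp(-pmin(d, 0)^2 / (2 * breadth^2)),
    decreasing = p_max * exp(-pmax(d, 0)^2 / (2 * breadth^2))
  )
}

#' Simulate virtual species with known response shapes
#'
#' Draws `n_species_per_type` species per shape.  Curve centres are placed
#' inside the realized temperature range so the structure each shape carries
#' is observable: unimodal peaks in the central band (skewed shapes offset
#' so the long flank has room), plateau midpoints in the outer thirds, and
#' monotone optima just beyond the gradient edge (the range-truncated
#' response of a species whose optimum is outside the sampled gradient).
#'
#' @param catchments Catchment table from [sim_catchments()].
#' @param cfg A [trc_sim_config()].
#' @param variable Temperature variable the responses are defined on.
#' @param seed Optional seed overriding `cfg$seed + 1`.
#' @return data.frame: `species_id`, `taxon_group`, `shape`, `true_type`,
#'   `t_opt`, `breadth`, `skew`, `p_max`.
#' @export
sim_responses <- function(catchments, cfg = trc_sim_config(),
                          variable = "Tmean_air", seed = NULL) {
  tv <- catchments[[variable]]
  q <- function(p) stats::quantile(tv, p, names = FALSE)
  rng <- diff(range(tv))
  groups <- c("fish", "molluscs", "plants", "odonates")
  with_seed(seed %||% (cfg$seed + 1), {
    rows <- lapply(trc_shapes(), function(shape) {
      k <- cfg$n_species_per_type
      breadth <- runif(k, cfg$breadth_range[1], cfg$breadth_range[2])
      skew <- runif(k, cfg$skew_range[1], cfg$skew_range[2])
      t_opt <- switch(shape,
        gaussian = runif(k, q(.35), q(.65)),
        right_skewed = runif(k, q(.3), q(.5)),
        left_skewed = runif(k, q(.5), q(.7)),
        flat = rep(q(.5), k),
        rise_plateau = runif(k, q(.2), q(.35)),
        plateau_fall = runif(k, q(.65), q(.8)),
        increasing = max(tv) + runif(k, 0.02, 0.15) * rng,
        decreasing = min(tv) - runif(k, 0.02, 0.15) * rng)
      if (shape %in% c("increasing", "decreasing"))
        breadth <- runif(k, 0.3 * rng, 0.45 * rng)
      data.frame(shape = shape, true_type = shape_to_type(shape),
                 t_opt = t_opt, breadth = breadth, skew = skew,
                 p_max = cfg$max_prob, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- cbind(species_id = sprintf("sp%03d", seq_len(nrow(out))),
                 taxon_group = rep_len(groups, nrow(out)), out)
    out$species_id <- as.character(out$species_id)
    out$taxon_group <- as.character(out$taxon_group)
    rownames(out) <- NULL
    out
  })
}

#' Simulate species occurrences from their generating curves
#'
#' Presence at each catchment is a Bernoulli draw with probability given by
#' the species' true response curve evaluated at the catchment's temperature.
#' Species falling short of `min_occurrences` presences are redrawn up to
#' `max_attempts` times and flagged if still short.  The study universe is
#' the full catchment table: absences are all catchments without a presence.
#'
#' @param catchments Catchment table.
#' @param responses Ground-truth table from [sim_responses()].
#' @param variable Temperature variable driving occurrence.
#' @param min_occurrences Minimum presences per species.
#' @param max_attempts Redraw cap before flagging a species.
#' @param seed Integer seed.
#' @return List with `occurrences` (long data.frame: `species_id`,
#'   `catchment_id`, `taxon_group`), `responses` (ground truth with an
#'   `n_presence` and `ok` column appended), and `variable`.
#' @export
sim_occurrences <- function(catchments, responses, variable = "Tmean_air",
                            min_occurrences = 50, max_attempts = 10,
                            seed = 1) {
  tv <- catchments[[variable]]
  lo <- min(tv); hi <- max(tv)
  out_edge <- responses$t_opt < lo | responses$t_opt > hi
  if (any(out_edge & !responses$shape %in%
            c("flat", "increasing", "decreasing")))
    warnf("t_opt outside realized temperature range for: %s (edge-truncated)",
          paste(responses$species_id[out_edge], collapse = ", "))
  with_seed(mix_seed(seed, 101), {
    pres_list <- vector("list", nrow(responses))
    n_pres <- integer(nrow(responses))
    ok <- logical(nrow(responses))
    for (i in seq_len(nrow(responses))) {
      r <- responses[i, ]
      p <- trc_response_prob(tv, r$shape, r$t_opt, r$breadth, r$skew, r$p_max)
      for (attempt in seq_len(max_attempts)) {
        y <- stats::rbinom(length(p), 1, p) == 1
        if (sum(y) >= min_occurrences) break
      }
      pres_list[[i]] <- catchments$catchment_id[y]
      n_pres[i] <- sum(y)
      ok[i] <- sum(y) >= min_occurrences
    }
    occ <- data.frame(
      species_id = rep(responses$species_id, lengths(pres_list)),
      catchment_id = unlist(pres_list),
      taxon_group = rep(responses$taxon_group, lengths(pres_list)),
      stringsAsFactors = FALSE)
    truth <- responses
    truth$n_presence <- n_pres
    truth$ok <- ok
    list(occurrences = occ, responses = truth, variable = variable)
  })
}

#' Simulate a projection ensemble
#'
#' Each climate model's projection is the baseline value plus the common
#' warming offset plus a model-specific spatially correlated perturbation
#' (a model-level constant and a latitude-linear component, each with SD
#' `model_spread_sd / sqrt(2)`).  The ensemble mean across models is
#' reported alongside the per-model columns.
#'
#' @param catchments Catchment table.
#' @param variables Baseline temperature columns to project.
#' @param warming_offset Common warming, degC.
#' @param n_models Number of models (>= 1).
#' @param model_spread_sd Total SD of a model's perturbation field, degC.
#' @param seed Integer seed.
#' @return `catchments` with, per variable `v`, columns `proj_<v>_m<k>` and
#'   `proj_<v>_mean` appended.
#' @export
sim_projections <- function(catchments,
                            variables = c("Tmean_air", "Tmax_air"),
                            warming_offset = 2, n_models = 3,
                            model_spread_sd = 0.3, seed = 1) {
  if (n_models < 1) stopf("invalid config: n_models must be >= 1")
  lat <- catchments$latitude
  z <- if (stats::sd(lat) > 0) (lat - mean(lat)) / stats::sd(lat) else lat * 0
  with_seed(mix_seed(seed, 211), {
    a <- stats::rnorm(n_models, 0, model_spread_sd / sqrt(2))
    b <- stats::rnorm(n_models, 0, model_spread_sd / sqrt(2))
    for (v in variables) {
      if (is.null(catchments[[v]])) stopf("unknown baseline variable '%s'", v)
      proj <- sapply(seq_len(n_models), function(m)
        catchments[[v]] + warming_offset + a[m] + b[m] * z)
      proj <- matrix(proj, ncol = n_models)
      colnames(proj) <- sprintf("proj_%s_m%d", v, seq_len(n_models))
      catchments[colnames(proj)] <- proj
      catchments[[sprintf("proj_%s_mean", v)]] <- rowMeans(proj)
    }
    catchments
  })
}
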