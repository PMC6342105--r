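#' Project all four temperature variables under warming
#'
#' Builds the projection ensemble consistently across variables: each
#' climate model shifts every monthly air temperature (and hence the
#' warmest-month maximum) by the warming offset plus its own spatially
#' correlated perturbation, and the water variables are re-derived from
#' the shifted values through the monthly logistic transform
#' (transform-then-average).  The per-model projections and their ensemble
#' means are appended as `proj_<variable>_m<k>` / `proj_<variable>_mean`.
#'
#' @param catchments Catchment table with monthly columns and `Tmax_air`.
#' @param water_model An [air_water_model()].
#' @param warming_offset Common warming, degC.
#' @param n_models Ensemble size.
#' @param model_spread_sd SD of model perturbation fields, degC.
#' @param seed Integer seed.
#' @return `catchments` with projection columns for all four variables.
#' @export
project_temperatures <- function(catchments,
                                 water_model = air_water_model(),
                                 warming_offset = 2, n_models = 3,
                                 model_spread_sd = 0.3, seed = 1) {
  if (n_models < 1) stopf("invalid config: n_models must be >= 1")
  mcols <- sprintf("month_%02d", 1:12)
  months <- as.matrix(catchments[mcols])
  lat <- catchments$latitude
  z <- if (stats::sd(lat) > 0) (lat - mean(lat)) / stats::sd(lat) else lat * 0
  vars <- temperature_variables()
  proj <- stats::setNames(
    lapply(vars, function(v) matrix(NA_real_, nrow(catchments), n_models)),
    vars)
  with_seed(mix_seed(seed, 211), {
    a <- stats::rnorm(n_models, 0, model_spread_sd / sqrt(2))
    b <- stats::rnorm(n_models, 0, model_spread_sd / sqrt(2))
    for (m in seq_len(n_models)) {
      delta <- warming_offset + a[m] + b[m] * z
      months_m <- months + delta
      tmax_air_m <- catchments$Tmax_air + delta
      proj$Tmean_air[, m] <- rowMeans(months_m)
      proj$Tmax_air[, m] <- tmax_air_m
      proj$Tmean_water[, m] <-
        rowMeans(matrix(air_to_water(months_m, water_model), nrow(months)))
      proj$Tmax_water[, m] <- air_to_water(tmax_air_m, water_model)
    }
  })
  for (v in vars) {
    colnames(proj[[v]]) <- sprintf("proj_%s_m%d", v, seq_len(n_models))
    catchments[colnames(proj[[v]])] <- proj[[v]]
    catchments[[sprintf("proj_%s_mean", v)]] <- ensemble_mean(proj[[v]])
  }
  catchments
}

#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end run.
#'
#' @param sim A [trc_sim_config()].
#' @param water_model An [air_water_model()].
#' @param classifier A [classifier_config()].
#' @param df Spline degrees of freedom for curve fits.
#' @param n_reps Validation repetitions.
#' @param train_frac Training fraction for validation splits.
#' @param auc_limit,tss_limit Retention limits.
#' @param min_occurrences Occurrence minimum for retention.
#' @param t_av_method `"occupied_mean"` or `"midpoint"`.
#' @param region Optional reporting-region box: list(lat = c(lo, hi),
#'   lon = c(lo, hi)).
#' @param seed Master seed.
#' @return List of class `trc_pipeline_config`.
#' @export
trc_pipeline_config <- function(sim = trc_sim_config(),
                                water_model = air_water_model(),
                                classifier = classifier_config(),
                                df = 3, n_reps = 100, train_frac = 0.8,
                                auc_limit = 0.7, tss_limit = 0.4,
                                min_occurrences = 50,
                                t_av_method = "occupied_mean",
                                region = NULL, seed = 1) {
  structure(list(sim = sim, water_model = water_model,
                 classifier = classifier, df = df, n_reps = n_reps,
                 train_frac = train_frac, auc_limit = auc_limit,
                 tss_limit = tss_limit, min_occurrences = min_occurrences,
                 t_av_method = t_av_method, region = region, seed = seed),
            class = "trc_pipeline_config")
}

#' Run the full thermal-response-curve pipeline
#'
#' Executes the stages in order on a synthetic landscape: climate
#' derivation (water variables, projection ensemble), virtual-species
#' occurrences, per-species curve fits and split-sample validation for all
#' four temperature variables, the occurrence/performance filter, curve
#' classification, thermal properties with latitudinal summaries, and
#' warming exposure.  Every intermediate table is written to `out_dir`
#' with a provenance header; runs are idempotent under a fixed seed.
#'
#' @param config A [trc_pipeline_config()].
#' @param out_dir Output directory (created if needed).  `NULL` skips
#'   writing.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all stage results.
#' @export
run_trc_pipeline <- function(config = trc_pipeline_config(),
                             out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "trc_pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  hash <- config_hash(unclass(config))
  meta <- list(config_hash = hash, seed = config$seed,
               slope_tol = config$classifier$slope_tol,
               skew_tol = config$classifier$skew_tol,
               p_floor = config$classifier$p_floor)
  emit <- function(x, name, extra = list()) {
    if (!is.null(out_dir))
      write_trc_csv(x, file.path(out_dir, paste0(name, ".csv")),
                    c(meta, extra))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!is.null(out_dir))
    writeLines(yaml::as.yaml(unclass_deep(config)),
               file.path(out_dir, "config.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  say("stage climate: simulating landscape and deriving variables")
  catchments <- stage("climate", {
    cat0 <- sim_catchments(config$sim)
    cat0 <- derive_water_variables(cat0, config$water_model)
    project_temperatures(cat0, config$water_model,
                         warming_offset = config$sim$warming_offset,
                         n_models = config$sim$n_climate_models,
                         model_spread_sd = config$sim$model_spread_sd,
                         seed = config$seed + 11)
  })
  emit(catchments, "catchments")

  say("stage occurrences: simulating virtual species")
  occ_sim <- stage("occurrences", {
    responses <- sim_responses(catchments, config$sim)
    sim_occurrences(catchments, responses,
                    min_occurrences = config$sim$min_occurrences,
                    seed = config$seed + 23)
  })
  emit(occ_sim$occurrences, "occurrences")
  emit(occ_sim$responses, "true_responses")

  vars <- temperature_variables()
  species <- unique(occ_sim$occurrences$species_id)
  occ_by_sp <- split(occ_sim$occurrences$catchment_id,
                     occ_sim$occurrences$species_id)

  say("stage fit: fitting and validating %d species x %d variables",
      length(species), length(vars))
  fits <- list()
  score_rows <- list()
  rep_rows <- list()
  for (sp in species) {
    pres <- catchments$catchment_id %in% occ_by_sp[[sp]]
    for (v in vars) {
      tv <- catchments[[v]]
      fit <- stage("fit", fit_trc.default(pres, tv, df = config$df,
                                          species_id = sp, variable = v))
      fits[[paste(sp, v, sep = ".")]] <- fit
      cv <- stage("validate",
                  cross_validate(pres, tv, df = config$df,
                                 n_reps = config$n_reps,
                                 train_frac = config$train_frac,
                                 auc_limit = config$auc_limit,
                                 tss_limit = config$tss_limit,
                                 seed = config$seed + 31, species_id = sp))
      score_rows[[paste(sp, v)]] <- data.frame(
        species_id = sp, variable = v, auc_mean = cv$auc_mean,
        tss_mean = cv$tss_mean, passed = cv$passed,
        stringsAsFactors = FALSE)
      rep_rows[[paste(sp, v)]] <- data.frame(
        species_id = sp, variable = v, rep = seq_len(cv$n_reps),
        auc = cv$auc_reps, tss = cv$tss_reps, stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, c(score_rows, list(make.row.names = FALSE)))
  emit(scores, "validation_scores")
  emit(do.call(rbind, c(rep_rows, list(make.row.names = FALSE))),
       "validation_reps")

  say("stage filter: applying occurrence and performance limits")
  filt <- stage("filter",
                filter_species(occ_sim$occurrences, scores,
                               min_occ = config$min_occurrences,
                               auc_limit = config$auc_limit,
                               tss_limit = config$tss_limit))
  emit(filt$audit, "filter_audit")

  say("stage classify: %d retained species", length(filt$retained))
  class_rows <- list()
  for (sp in filt$retained) for (v in vars) {
    cl <- stage("classify",
                classify_trc(fits[[paste(sp, v, sep = ".")]],
                             config$classifier))
    class_rows[[paste(sp, v)]] <- data.frame(
      species_id = sp, variable = v, trc_type = cl$trc_type,
      max_prob = cl$max_prob, sign_sequence = cl$sign_sequence,
      asymmetry = cl$asymmetry, t_peak = cl$t_peak,
      warnings = paste(cl$warnings, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  classifications <- do.call(rbind, c(class_rows, list(make.row.names = FALSE)))
  emit(classifications, "classifications")

  say("stage properties: thermal statistics")
  prop_rows <- list()
  for (sp in filt$retained) for (v in vars) {
    idx <- catchments$catchment_id %in% occ_by_sp[[sp]]
    cl_row <- classifications[classifications$species_id == sp &
                                classifications$variable == v, ]
    cl <- list(trc_type = cl_row$trc_type)
    pr <- stage("properties",
                thermal_properties(fits[[paste(sp, v, sep = ".")]], cl,
                                   t_occupied = catchments[[v]][idx],
                                   lat_occupied = catchments$latitude[idx],
                                   lon_occupied = catchments$longitude[idx],
                                   region = config$region,
                                   t_av_method = config$t_av_method))
    prop_rows[[paste(sp, v)]] <- pr
  }
  properties <- do.call(rbind, c(prop_rows, list(make.row.names = FALSE)))
  emit(properties, "thermal_properties")

  lat_sums <- list()
  for (v in vars) for (st in c("wt", "sm")) {
    ls <- latitudinal_summary(properties[properties$variable == v, ], st)
    if (nrow(ls)) {
      ls <- cbind(variable = v, statistic = st, ls)
      lat_sums[[paste(v, st)]] <- ls
    }
  }
  lat_summary <- do.call(rbind, c(lat_sums, list(make.row.names = FALSE)))
  emit(lat_summary, "latitudinal_summary")

  say("stage exposure: projected warming vs critical temperatures")
  occ_ret <- occ_sim$occurrences[
    occ_sim$occurrences$species_id %in% filt$retained, ]
  exposures <- list()
  for (v in vars) {
    ct_tab <- properties[properties$variable == v, c("species_id", "ct")]
    proj <- stats::setNames(catchments[[sprintf("proj_%s_mean", v)]],
                            catchments$catchment_id)
    cd <- stage("exposure", critical_difference(proj, ct_tab, occ_ret))
    ex <- exposure_map(cd, universe = catchments$catchment_id)
    exposures[[v]] <- cbind(variable = v, ex)
  }
  exposure <- do.call(rbind, c(exposures, list(make.row.names = FALSE)))
  emit(exposure, "exposure")

  type_summary <- spatial_type_summary(
    classifications[classifications$variable == "Tmean_air", ],
    occ_ret, catchments)
  emit(type_summary, "type_summary")

  say("pipeline complete%s",
      if (!is.null(out_dir)) paste0("; outputs in ", out_dir) else "")
  invisible(list(config = config, catchments = catchments,
                 occurrences = occ_sim$occurrences,
                 true_responses = occ_sim$responses, fits = fits,
                 scores = scores, filter = filt,
                 classifications = classifications,
                 properties = properties, lat_summary = lat_summary,
                 exposure = exposure, type_summary = type_summary,
                 out_dir = out_dir))
}

# recursively drop S3 classes so yaml::as.yaml can serialise the config
unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
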