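#' Critical difference between projected temperature and species CT
#'
#' For each species x occupied catchment, the difference between the
#' projected ensemble-mean temperature and the species' critical
#' temperature (CT, the current maximum temperature of occurrence).
#' The exceedance is strict: a projection exactly at CT is not critical.
#' With zero warming no occupied catchment can be critical, because every
#' occupied catchment's baseline temperature is at most CT by definition.
#'
#' @param projected Named numeric vector of projected ensemble-mean
#'   temperatures keyed by catchment id (or a data.frame with
#'   `catchment_id` and `projected`).
#' @param ct_table data.frame with `species_id` and `ct`.
#' @param occurrences Long occurrence table (`species_id`, `catchment_id`);
#'   exposure is evaluated at occupied catchments.
#' @return data.frame: `species_id`, `catchment_id`, `projected`, `ct`,
#'   `difference`, `critical`; species without a CT are dropped with an
#'   attached `audit` attribute naming them.
#' @export
critical_difference <- function(projected, ct_table, occurrences) {
  if (is.data.frame(projected))
    projected <- stats::setNames(projected$projected, projected$catchment_id)
  missing_ct <- setdiff(unique(occurrences$species_id), ct_table$species_id)
  occ <- occurrences[!occurrences$species_id %in% missing_ct, , drop = FALSE]
  unknown <- setdiff(unique(occ$catchment_id), names(projected))
  if (length(unknown))
    stopf("critical_difference: no projection for catchment(s): %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  ct <- stats::setNames(ct_table$ct, ct_table$species_id)[occ$species_id]
  proj <- projected[occ$catchment_id]
  out <- data.frame(species_id = occ$species_id,
                    catchment_id = occ$catchment_id,
                    projected = as.numeric(proj), ct = as.numeric(ct),
                    difference = as.numeric(proj - ct),
                    critical = as.numeric(proj) > as.numeric(ct),
                    stringsAsFactors = FALSE)
  if ("taxon_group" %in% names(occ)) out$taxon_group <- occ$taxon_group
  attr(out, "audit") <- missing_ct
  out
}

#' Per-catchment exposure map
#'
#' Relative frequency, per catchment (and taxon group, plus an `"all"`
#' aggregate), of the retained species present whose critical temperature
#' is exceeded by the projected temperature.  Catchments with no retained
#' species present get `NA` relative frequency (no occurrence), which is
#' distinguishable from a present-but-unaffected 0.
#'
#' @param criticals Output of [critical_difference()].
#' @param universe Optional character vector of all catchment ids to report
#'   (defaults to the catchments appearing in `criticals`).
#' @return data.frame: `catchment_id`, `group`, `n_present`, `n_critical`,
#'   `rel_freq`.
#' @export
exposure_map <- function(criticals, universe = NULL) {
  if (is.null(universe)) universe <- sort(unique(criticals$catchment_id))
  groups <- if ("taxon_group" %in% names(criticals))
    sort(unique(criticals$taxon_group)) else character(0)
  one <- function(dat, label) {
    f <- factor(dat$catchment_id, levels = universe)
    n_present <- tabulate(f, nbins = length(universe))
    n_critical <- tabulate(f[dat$critical], nbins = length(universe))
    data.frame(catchment_id = universe, group = label,
               n_present = n_present, n_critical = n_critical,
               rel_freq = ifelse(n_present > 0, n_critical / n_present, NA),
               stringsAsFactors = FALSE)
  }
  out <- one(criticals, "all")
  for (g in groups)
    out <- rbind(out, one(criticals[criticals$taxon_group == g, ], g))
  rownames(out) <- NULL
  out
}

#' Plot an exposure map
#'
#' Simple choropleth-style scatter: catchment positions coloured by the
#' relative frequency of species with exceeded CT.  Catchments without
#' retained species are drawn grey.
#'
#' @param exposure Output of [exposure_map()] (one group).
#' @param catchments Catchment table with `latitude` and `longitude`.
#' @param main Title.
#' @export
plot_exposure <- function(exposure, catchments, main = "Warming exposure") {
  m <- merge(catchments[c("catchment_id", "latitude", "longitude")],
             exposure, by = "catchment_id")
  pal <- grDevices::colorRampPalette(c("lightyellow", "orange", "darkred"))(100)
  col <- ifelse(is.na(m$rel_freq), "grey80",
                pal[pmax(1, ceiling(m$rel_freq * 99 + 1e-9))])
  graphics::plot(m$longitude, m$latitude, col = col, pch = 16, cex = 0.6,
                 xlab = "Longitude", ylab = "Latitude", main = main)
  invisible(m)
}
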