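#' Classifier configuration
#'
#' Tolerances of the slope-pattern classifier.  A local slope counts as
#' zero when it falls below both of two bands: a relative floor of
#' `slope_tol` times the curve's mean slope scale (maximum probability
#' divided by the temperature range), and -- for fitted curves, which carry
#' sampling uncertainty -- `z_slope` standard errors of the local slope.
#' The standard-error band is what keeps sampling wiggle in a genuinely
#' structureless curve from being read as shape; the relative floor is
#' what remains in the infinite-data (analytic-curve) limit.
#'
#' Zero-slope runs shorter than `plateau_min_frac` of the temperature
#' range are absorbed into the adjacent trend (a plateau must have
#' structural length to count); zero runs at the domain edges whose level
#' is below `plateau_level` times the maximum are treated as
#' uninformative low tails and dropped.
#'
#' @param grid_points Uniform evaluation grid size.
#' @param slope_tol Zero-slope relative floor, as a fraction of
#'   max(p)/range.
#' @param z_slope Standard-error multiple below which a fitted slope
#'   counts as zero.
#' @param z_run Standard-error multiple for the run-level retest: a
#'   zero-slope run whose total change across the run is significant is
#'   reassigned the sign of that change (a steady rise can be pointwise
#'   insignificant yet clearly non-flat in aggregate).
#' @param skew_tol Symmetric-vs-skewed half-max asymmetry threshold.
#' @param p_floor Maximum-probability floor for the no-response rule.
#' @param plateau_min_frac Minimum structural plateau length, fraction of
#'   the temperature range.
#' @param plateau_level Fraction of max(p) separating high plateaus from
#'   low tails.
#' @return List of class `trc_classifier_config`.
#' @export
classifier_config <- function(grid_points = 512, slope_tol = 0.05,
                              z_slope = 3, z_run = 2, skew_tol = 0.12,
                              p_floor = 0.01, plateau_min_frac = 0.25,
                              plateau_level = 0.5) {
  if (slope_tol <= 0 || skew_tol <= 0 || p_floor <= 0 || grid_points < 8 ||
        z_slope < 0 || plateau_min_frac < 0)
    stopf("invalid classifier config: tolerances must be strictly positive")
  structure(list(grid_points = grid_points, slope_tol = slope_tol,
                 z_slope = z_slope, z_run = z_run, skew_tol = skew_tol,
                 p_floor = p_floor, plateau_min_frac = plateau_min_frac,
                 plateau_level = plateau_level),
            class = "trc_classifier_config")
}

# Standard error of the fitted slope (probability scale) on each interval
# of the evaluation grid, by the delta method on link-scale differences.
trc_slope_se <- function(object, Tg) {
  B <- stats::predict(object$basis, Tg)
  X <- cbind(1, B)
  D <- X[-1, , drop = FALSE] - X[-nrow(X), , drop = FALSE]
  se_d <- sqrt(pmax(rowSums((D %*% object$vcov) * D), 0))
  eta <- drop(X %*% object$coefficients)
  pbar <- stats::plogis((eta[-1] + eta[-length(eta)]) / 2)
  dT <- diff(Tg)
  pbar * (1 - pbar) * se_d / dT
}

#' Classify a thermal response curve into one of eight types
#'
#' Assigns the fitted curve to one of the response types I--VIII:
#' I unimodal symmetric, II unimodal right-skewed (tendency toward warmer
#' regions), III unimodal left-skewed (tendency toward colder regions),
#' IV no response, V rise then plateau, VI plateau then decline,
#' VII monotonic increase, VIII monotonic decrease.
#'
#' The algorithm evaluates the curve on a uniform grid and types it IV
#' outright when the maximum probability falls below `p_floor` (no
#' reliability assumed).  Otherwise it maps first differences to slope
#' signs {+, 0, -} using the tolerance bands of [classifier_config()],
#' collapses runs, absorbs sub-structural zero runs, drops low tails at
#' the edges, and pattern-matches: all zero = IV; rising only = VII
#' (V when ending in a high plateau); declining only = VIII (VI when
#' starting from a high plateau); a single rise-then-decline = unimodal.
#' Unimodal curves are split by half-maximum width asymmetry
#' `A = (R - L) / (R + L)` (domain edge when the half-maximum is not
#' reached): |A| <= `skew_tol` gives Type I, a warm-side excess Type II,
#' a cold-side excess Type III.  Multimodal or irregular sign patterns
#' are classified by the dominant peak and flagged with a warning.
#'
#' @param object A `trc` object, or a function of temperature (analytic
#'   curves carry no sampling uncertainty, so only the relative slope
#'   floor applies).
#' @param cfg A [classifier_config()].
#' @param range Temperature range (length 2) when `object` is a function.
#' @param ... Unused.
#' @return Object of class `trc_classification`: `species_id`, `variable`,
#'   `trc_type`, `max_prob`, `sign_sequence`, `asymmetry`, `t_peak`,
#'   `warnings`.
#' @export
classify_trc <- function(object, cfg = classifier_config(), range = NULL,
                         ...) {
  is_fit <- inherits(object, "trc")
  if (is_fit) {
    f <- function(tt) predict(object, temperature = tt)
    rng <- object$range
    sp <- object$species_id; va <- object$variable
  } else if (is.function(object)) {
    if (is.null(range)) stopf("classify_trc: range required for a function")
    f <- object; rng <- sort(range)
    sp <- NULL; va <- NULL
  } else stopf("classify_trc: object must be a 'trc' fit or a function")

  gp <- cfg$grid_points
  Tg <- seq(rng[1], rng[2], length.out = gp)
  p <- pmin(pmax(f(Tg), 0), 1)
  maxp <- max(p)
  warnings <- character(0)

  res <- function(type, sign_seq = "", asym = NA_real_, t_peak = NA_real_)
    structure(list(species_id = sp, variable = va, trc_type = type,
                   max_prob = maxp, sign_sequence = sign_seq,
                   asymmetry = asym, t_peak = t_peak, warnings = warnings),
              class = "trc_classification")

  if (maxp < cfg$p_floor) return(res("IV"))

  dT <- (rng[2] - rng[1]) / (gp - 1)
  slope <- diff(p) / dT
  tol <- rep(cfg$slope_tol * maxp / (rng[2] - rng[1]), gp - 1)
  if (is_fit && cfg$z_slope > 0)
    tol <- pmax(tol, cfg$z_slope * trc_slope_se(object, Tg))
  sg <- ifelse(slope > tol, 1L, ifelse(slope < -tol, -1L, 0L))

  # run-level retest (fitted curves only): a zero run whose aggregate
  # change is significant carries the sign of that change
  if (is_fit && cfg$z_run > 0) {
    B <- stats::predict(object$basis, Tg)
    X <- cbind(1, B)
    w <- p * (1 - p)
    runs <- rle(sg)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    for (r in which(runs$values == 0L)) {
      s <- starts[r]; e <- ends[r] + 1L  # grid indices spanning the run
      dp <- p[e] - p[s]
      d <- w[e] * X[e, ] - w[s] * X[s, ]
      se <- sqrt(max(drop(d %*% object$vcov %*% d), 0))
      if (abs(dp) > cfg$z_run * se &&
            abs(dp) / (Tg[e] - Tg[s]) > cfg$slope_tol * maxp /
              (rng[2] - rng[1]))
        sg[s:(e - 1L)] <- sign(dp)
    }
  }

  # collapse to runs; iteratively absorb sub-structural zero runs
  min_len <- cfg$plateau_min_frac * (gp - 1)
  repeat {
    runs <- rle(sg)
    k <- length(runs$values)
    if (k <= 1) break
    short0 <- which(runs$values == 0 & runs$lengths < min_len)
    if (!length(short0)) break
    # absorb simultaneously (keeps the rule mirror-symmetric): an edge zero
    # run joins its single neighbour; an interior one between equal signs
    # joins them; between opposite signs it is the turnaround -- kept.
    newvals <- runs$values
    for (i in short0) {
      if (i == 1) newvals[i] <- runs$values[2]
      else if (i == k) newvals[i] <- runs$values[k - 1]
      else if (runs$values[i - 1] == runs$values[i + 1])
        newvals[i] <- runs$values[i - 1]
    }
    if (identical(newvals, runs$values)) break
    sg <- rep(newvals, runs$lengths)
  }
  runs <- rle(sg)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lev <- mapply(function(s, e) mean(p[s:(e + 1)]), starts, ends)

  # drop uninformative low tails: zero runs at the edges well below max
  keep <- rep(TRUE, length(runs$values))
  repeat {
    idx <- which(keep)
    if (length(idx) <= 1) break
    changed <- FALSE
    first <- idx[1]; last <- idx[length(idx)]
    if (runs$values[first] == 0 && lev[first] < cfg$plateau_level * maxp) {
      keep[first] <- FALSE; changed <- TRUE
    }
    idx <- which(keep)
    if (length(idx) > 1) {
      last <- idx[length(idx)]
      if (runs$values[last] == 0 && lev[last] < cfg$plateau_level * maxp) {
        keep[last] <- FALSE; changed <- TRUE
      }
    }
    if (!changed) break
  }
  vals <- runs$values[keep]
  sign_seq <- paste(c("-", "0", "+")[vals + 2L], collapse = "")
  nz <- vals[vals != 0]

  peak_stats <- function() {
    i_pk <- which.max(p)
    t_pk <- Tg[i_pk]
    h <- maxp / 2
    left <- rng[1]
    if (i_pk > 1) {
      below <- which(p[1:(i_pk - 1)] < h)
      if (length(below)) {
        j <- max(below)  # half-max crossing between j and j+1
        left <- Tg[j] + (h - p[j]) / (p[j + 1] - p[j]) * dT
      }
    }
    right <- rng[2]
    if (i_pk < gp) {
      below <- which(p[(i_pk + 1):gp] < h) + i_pk
      if (length(below)) {
        j <- min(below)
        right <- Tg[j - 1] + (p[j - 1] - h) / (p[j - 1] - p[j]) * dT
      }
    }
    L <- t_pk - left; R <- right - t_pk
    A <- if (L + R > 0) (R - L) / (R + L) else 0
    list(t_peak = t_pk, A = A)
  }
  unimodal <- function() {
    ps <- peak_stats()
    type <- if (abs(ps$A) <= cfg$skew_tol) "I"
            else if (ps$A > cfg$skew_tol) "II" else "III"
    res(type, sign_seq, ps$A, ps$t_peak)
  }

  if (length(nz) == 0) return(res("IV", sign_seq))
  if (all(nz == 1L)) {
    if (vals[length(vals)] == 0L) return(res("V", sign_seq))
    return(res("VII", sign_seq))
  }
  if (all(nz == -1L)) {
    if (vals[1] == 0L) return(res("VI", sign_seq))
    return(res("VIII", sign_seq))
  }
  if (length(nz) == 2 && nz[1] == 1L && nz[2] == -1L) return(unimodal())

  # multimodal or irregular pattern: dominant-peak fallback with warning
  warnings <- c(warnings, paste0("irregular slope pattern '", sign_seq,
                                 "'; dominant-peak fallback"))
  i_pk <- which.max(p)
  edge <- max(2, ceiling(0.02 * gp))
  if (i_pk <= edge) return(res("VIII", sign_seq))
  if (i_pk >= gp - edge + 1) return(res("VII", sign_seq))
  unimodal()
}

#' @export
print.trc_classification <- function(x, ...) {
  cat(sprintf("TRC type %s%s%s  (max p = %.4f)\n", x$trc_type,
              if (!is.null(x$species_id)) paste0("  ", x$species_id) else "",
              if (!is.null(x$variable)) paste0(" ~ ", x$variable) else "",
              x$max_prob))
  cat("  slope pattern:", if (nzchar(x$sign_sequence)) x$sign_sequence
      else "(not evaluated: below probability floor)", "\n")
  if (!is.na(x$asymmetry))
    cat(sprintf("  half-max asymmetry %.3f, peak at %.2f degC\n",
                x$asymmetry, x$t_peak))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Per-catchment summary of response-type composition
#'
#' For each catchment, counts the retained species present and the subset
#' with a unimodal response (types I--III), reporting the unimodal
#' fraction.  Catchments where no retained species occurs are reported
#' with `NA` (absence of evidence, not zero).
#'
#' @param classifications data.frame with `species_id` and `trc_type`.
#' @param occurrences Long occurrence table (`species_id`, `catchment_id`).
#' @param catchments Catchment table (defines the reported universe).
#' @return data.frame: `catchment_id`, `n_present`, `n_unimodal`,
#'   `frac_unimodal`.
#' @export
spatial_type_summary <- function(classifications, occurrences, catchments) {
  uni <- classifications$species_id[
    classifications$trc_type %in% c("I", "II", "III")]
  occ <- occurrences[occurrences$species_id %in%
                       classifications$species_id, ]
  f <- factor(occ$catchment_id, levels = catchments$catchment_id)
  n_present <- tabulate(f, nbins = nlevels(f))
  n_uni <- tabulate(f[occ$species_id %in% uni], nbins = nlevels(f))
  data.frame(catchment_id = catchments$catchment_id,
             n_present = n_present, n_unimodal = n_uni,
             frac_unimodal = ifelse(n_present > 0, n_uni / n_present, NA),
             stringsAsFactors = FALSE)
}
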