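#' Rank-based AUC (area under the ROC curve)
#'
#' Mann--Whitney formulation: the probability that a randomly chosen
#' presence is scored above a randomly chosen absence, with ties counted
#' as one half.  An AUC of 0.5 indicates a random prediction.
#'
#' @param scores Predicted probabilities (or any monotone scores).
#' @param labels Binary presence labels.
#' @return AUC in [0, 1].
#' @export
compute_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2)
    stopf("compute_auc: AUC undefined with a single class")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic
#'
#' TSS = sensitivity + specificity - 1.  Values of 0 or below indicate
#' random performance, +1 a perfect prediction.
#'
#' @param sensitivity,specificity Rates in [0, 1].
#' @return TSS in [-1, 1].
#' @export
compute_tss <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1 |
            specificity < 0 | specificity > 1, na.rm = TRUE))
    stopf("compute_tss: sensitivity/specificity must lie in [0, 1]")
  sensitivity + specificity - 1
}

#' Select the presence/absence probability threshold
#'
#' Chooses, from the midpoints between consecutive sorted unique predicted
#' probabilities (plus endpoints below the smallest and above the largest
#' score), the threshold minimising |sensitivity - specificity|.  Ties are
#' broken toward the lower threshold (favouring sensitivity).  Predicted
#' presence is `score >= threshold`.
#'
#' @param scores Predicted probabilities.
#' @param labels Binary presence labels (both classes required).
#' @return List: `threshold`, `sensitivity`, `specificity`, `degenerate`
#'   (TRUE when all scores coincide and any threshold is equivalent).
#' @export
select_threshold <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2)
    stopf("select_threshold: need both classes")
  u <- sort(unique(scores))
  if (length(u) == 1) {
    thr <- min(max(u, 1e-12), 1 - 1e-12)
    pred <- scores >= thr
    return(list(threshold = thr, sensitivity = mean(pred[y == 1]),
                specificity = mean(!pred[y == 0]), degenerate = TRUE))
  }
  k <- length(u)
  cand <- c(u[1] / 2, (u[-1] + u[-k]) / 2, (u[k] + 1) / 2)
  cand <- pmin(pmax(cand, 1e-12), 1 - 1e-12)
  se <- vapply(cand, function(t) mean(scores[y == 1] >= t), 0)
  sp <- vapply(cand, function(t) mean(scores[y == 0] < t), 0)
  i <- which.min(abs(se - sp))   # candidates ascending: first = lowest
  list(threshold = cand[i], sensitivity = se[i], specificity = sp[i],
       degenerate = FALSE)
}

#' Repeated split-sample validation of a thermal response curve
#'
#' Repeats `n_reps` times: split the data into training (80%) and
#' validation (20%) partitions, stratified by class so both partitions
#' contain presences and absences; fit the curve on the training part;
#' select the probability threshold on training predictions; score AUC and
#' TSS on the validation part.  The per-repetition values are averaged and
#' compared against the performance limits.
#'
#' @param presence Binary presence vector.
#' @param temperature Temperature per catchment, degC.
#' @param df Spline degrees of freedom.
#' @param n_reps Number of random splits.
#' @param train_frac Training fraction.
#' @param auc_limit,tss_limit Retention limits on the validation means.
#' @param seed Integer seed; fixed seed gives identical results.
#' @param species_id Optional label used in messages.
#' @return Object of class `trc_cv`: `auc_reps`, `tss_reps`, `auc_mean`,
#'   `tss_mean`, `passed`, plus the settings used.
#' @export
cross_validate <- function(presence, temperature, df = 3, n_reps = 100,
                           train_frac = 0.8, auc_limit = 0.7,
                           tss_limit = 0.4, seed = 1, species_id = NULL) {
  y <- as.integer(as.logical(presence))
  i1 <- which(y == 1); i0 <- which(y == 0)
  n1_tr <- round(length(i1) * train_frac)
  n0_tr <- round(length(i0) * train_frac)
  if (n1_tr < 1 || n0_tr < 1 || n1_tr >= length(i1) || n0_tr >= length(i0))
    stopf("cross_validate: stratified %.0f/%.0f split infeasible for %s (%d presences, %d absences)",
          100 * train_frac, 100 * (1 - train_frac),
          species_id %||% "species", length(i1), length(i0))
  auc_reps <- tss_reps <- numeric(n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      tr <- c(sample(i1, n1_tr), sample(i0, n0_tr))
      va <- setdiff(seq_along(y), tr)
      fit <- fit_trc.default(y[tr], temperature[tr], df = df,
                             grid_points = 2)
      p_va <- predict(fit, temperature = temperature[va])
      p_va[is.na(p_va)] <- 0  # beyond training range: curve undefined, score 0
      auc_reps[r] <- compute_auc(p_va, y[va])
      pred <- p_va >= fit$threshold
      se <- mean(pred[y[va] == 1])
      sp <- mean(!pred[y[va] == 0])
      tss_reps[r] <- compute_tss(se, sp)
    }
  })
  out <- list(auc_reps = auc_reps, tss_reps = tss_reps,
              auc_mean = mean(auc_reps), tss_mean = mean(tss_reps),
              passed = mean(auc_reps) >= auc_limit &&
                mean(tss_reps) >= tss_limit,
              n_reps = n_reps, train_frac = train_frac,
              auc_limit = auc_limit, tss_limit = tss_limit,
              species_id = species_id)
  class(out) <- "trc_cv"
  out
}

#' @export
print.trc_cv <- function(x, ...) {
  cat(sprintf("Split-sample validation (%d reps, %.0f%% training)%s\n",
              x$n_reps, 100 * x$train_frac,
              if (!is.null(x$species_id)) paste0(" - ", x$species_id) else ""))
  cat(sprintf("  AUC %.3f (limit %.2f), TSS %.3f (limit %.2f) -> %s\n",
              x$auc_mean, x$auc_limit, x$tss_mean, x$tss_limit,
              if (x$passed) "retained" else "excluded"))
  invisible(x)
}

#' Filter species on occurrence count and predictive performance
#'
#' Retains species that occur in at least `min_occ` catchments and whose
#' validation means satisfy AUC >= `auc_limit` and TSS >= `tss_limit` for
#' all four temperature variables.  Every exclusion is recorded with its
#' reason in the audit table.
#'
#' @param occurrences Long occurrence table (`species_id`, `catchment_id`).
#' @param scores data.frame with `species_id`, `variable`, `auc_mean`,
#'   `tss_mean` covering all four variables per candidate.
#' @param min_occ Minimum occupied catchments.
#' @param auc_limit,tss_limit Performance limits.
#' @return List: `retained` (character vector) and `audit` (data.frame:
#'   `species_id`, `n_occurrences`, `n_variables_passed`, `reason`).
#' @export
filter_species <- function(occurrences, scores, min_occ = 50,
                           auc_limit = 0.7, tss_limit = 0.4) {
  n_occ <- table(occurrences$species_id)
  species <- names(n_occ)
  n_var <- integer(length(species))
  reason <- character(length(species))
  for (i in seq_along(species)) {
    sp <- species[i]
    if (n_occ[[sp]] < min_occ) {
      reason[i] <- "min_occurrences"
      next
    }
    sc <- scores[scores$species_id == sp, ]
    miss <- setdiff(temperature_variables(), sc$variable)
    if (length(miss))
      stopf("filter_species: %s lacks scores for %s", sp,
            paste(miss, collapse = ", "))
    ok <- sc$auc_mean >= auc_limit & sc$tss_mean >= tss_limit
    n_var[i] <- sum(ok)
    reason[i] <- if (all(ok)) "retained" else "performance"
  }
  audit <- data.frame(species_id = species,
                      n_occurrences = as.integer(n_occ),
                      n_variables_passed = n_var, reason = reason,
                      stringsAsFactors = FALSE)
  list(retained = species[reason == "retained"], audit = audit)
}
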