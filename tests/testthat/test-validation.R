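test_that("AUC matches the brute-force pairwise concordance oracle", {
  set.seed(61)
  for (rep in 1:5) {
    n <- sample(20:100, 1)
    scores <- round(stats::runif(n), 2)   # rounding forces ties
    labels <- stats::rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(compute_auc(scores, labels),
                 oracle_auc(scores, labels), tolerance = 1e-12)
  }
  expect_equal(compute_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_error(compute_auc(1:5, rep(1, 5)), "single class")
})

test_that("AUC of a random prediction approaches one half", {
  set.seed(62)
  scores <- stats::runif(20000)
  labels <- stats::rbinom(20000, 1, 0.3)
  expect_equal(compute_auc(scores, labels), 0.5, tolerance = 0.02)
})

test_that("TSS is exactly sensitivity + specificity - 1", {
  expect_equal(compute_tss(1, 1), 1)
  expect_equal(compute_tss(0.5, 0.5), 0)
  expect_equal(compute_tss(0.77, 0.84), 0.61)
  expect_error(compute_tss(1.2, 0.5), "\\[0, 1\\]")
})

test_that("threshold selection equals exhaustive candidate search", {
  set.seed(63)
  for (rep in 1:10) {
    scores <- round(stats::runif(200), 2)
    labels <- stats::rbinom(200, 1, 0.35)
    if (length(unique(labels)) < 2) next
    got <- select_threshold(scores, labels)
    want <- oracle_threshold(scores, labels)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
    # returned rates are recomputable from (scores, labels, threshold)
    pred <- scores >= got$threshold
    expect_equal(got$sensitivity, mean(pred[labels == 1]))
    expect_equal(got$specificity, mean(!pred[labels == 0]))
  }
})

test_that("threshold handles perfect separation and degenerate scores", {
  got <- select_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(got$sensitivity, 1)
  expect_equal(got$specificity, 1)
  deg <- select_threshold(rep(0.4, 10), rep(c(0, 1), 5))
  expect_true(deg$degenerate)
  expect_error(select_threshold(1:4 / 5, rep(0, 4)), "both classes")
})

test_that("adding a presence at the curve peak never lowers training AUC", {
  set.seed(64)
  for (rep in 1:5) {
    tv <- stats::runif(300, 0, 20)
    y <- draw_presence(tv, "gaussian", 10, 4, p_max = 0.8, seed = 64 + rep)
    if (length(unique(y)) < 2) next
    fit <- fit_trc(y, tv)
    scores <- fitted(fit)
    auc0 <- oracle_auc(scores, y)
    absences <- which(y == 0)
    flip <- absences[which.max(scores[absences])]
    y2 <- y; y2[flip] <- 1
    expect_gte(oracle_auc(scores, y2), auc0 - 1e-12)
  }
})

test_that("cross-validation separates strong-signal from no-signal species", {
  set.seed(65)
  tv <- stats::runif(1200, -5, 16)
  strong <- draw_presence(tv, "gaussian", 8, 3, p_max = 0.95, seed = 65)
  cv_strong <- cross_validate(strong, tv, n_reps = 25, seed = 1)
  expect_gt(cv_strong$auc_mean, 0.9)
  expect_true(cv_strong$passed)

  null <- stats::rbinom(1200, 1, 0.3)
  cv_null <- cross_validate(null, tv, n_reps = 25, seed = 1)
  expect_lt(abs(cv_null$tss_mean), 0.15)
  expect_false(cv_null$passed)
})

test_that("cross-validation is deterministic under a fixed seed", {
  set.seed(66)
  tv <- stats::runif(400, 0, 20)
  y <- draw_presence(tv, "gaussian", 10, 4, p_max = 0.8, seed = 66)
  cv1 <- cross_validate(y, tv, n_reps = 10, seed = 99)
  cv2 <- cross_validate(y, tv, n_reps = 10, seed = 99)
  expect_identical(cv1$auc_reps, cv2$auc_reps)
  expect_identical(cv1$tss_reps, cv2$tss_reps)
  expect_output(print(cv1), "Split-sample validation")
})

test_that("infeasible stratification is an error naming the species", {
  expect_error(cross_validate(c(1, rep(0, 99)), stats::runif(100),
                              species_id = "sp_tiny"),
               "sp_tiny")
})

test_that("species filtering applies both gates and records reasons", {
  # constructed bookkeeping fixture: 3 retained, 1 rare, 1 weak on one var
  occ <- data.frame(
    species_id = rep(c("a", "b", "c", "d", "e"),
                     times = c(60, 70, 49, 80, 90)),
    catchment_id = sprintf("c%03d", c(1:60, 1:70, 1:49, 1:80, 1:90)))
  scores <- expand.grid(species_id = c("a", "b", "c", "d", "e"),
                        variable = temperature_variables(),
                        stringsAsFactors = FALSE)
  scores$auc_mean <- 0.85
  scores$tss_mean <- 0.55
  scores$tss_mean[scores$species_id == "d" &
                    scores$variable == "Tmax_water"] <- 0.39
  filt <- filter_species(occ, scores, min_occ = 50)
  expect_setequal(filt$retained, c("a", "b", "e"))
  audit <- filt$audit
  expect_equal(audit$reason[audit$species_id == "c"], "min_occurrences")
  expect_equal(audit$reason[audit$species_id == "d"], "performance")
  expect_equal(audit$n_variables_passed[audit$species_id == "d"], 3)
  scores2 <- scores[scores$variable != "Tmax_water", ]
  expect_error(filter_species(occ, scores2), "lacks scores")
})
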