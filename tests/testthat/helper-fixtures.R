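# Shared fixtures and independent brute-force oracles.

small_landscape <- function(n = 800, seed = 42, ...) {
  cfg <- trc_sim_config(n_catchments = n, seed = seed, ...)
  sim_catchments(cfg)
}

# Presence draws from an arbitrary response curve at given temperatures.
draw_presence <- function(tv, shape, t_opt, breadth, skew = 3, p_max = 0.6,
                          seed = 1) {
  p <- trc_response_prob(tv, shape, t_opt, breadth, skew, p_max)
  set.seed((seed * 7919 + 13) %% 2147483647)  # decouple from caller streams
  stats::rbinom(length(p), 1, p)
}

# O(n1 * n0) pairwise-concordance AUC, independent of the rank formula.
oracle_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  s1 <- scores[y == 1]; s0 <- scores[y == 0]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

# Exhaustive threshold search over the same candidate set contract:
# midpoints of sorted unique scores plus endpoints; lowest threshold wins.
oracle_threshold <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  u <- sort(unique(scores))
  k <- length(u)
  cand <- c(u[1] / 2, (u[-1] + u[-k]) / 2, (u[k] + 1) / 2)
  cand <- pmin(pmax(cand, 1e-12), 1 - 1e-12)
  best <- NULL
  for (t in cand) {
    pred <- scores >= t
    se <- mean(pred[y == 1]); sp <- mean(!pred[y == 0])
    if (is.null(best) || abs(se - sp) < best$gap - 1e-15) {
      best <- list(threshold = t, sensitivity = se, specificity = sp,
                   gap = abs(se - sp))
    }
  }
  best
}

# Grouped mean by explicit loop, independent of tapply.
oracle_zonal <- function(values, ids, universe) {
  out <- rep(NA_real_, length(universe))
  for (i in seq_along(universe)) {
    v <- values[ids == universe[i]]
    if (length(v)) out[i] <- sum(v) / length(v)
  }
  out
}

# Analytic two-sided Gaussian used by classifier tests.
two_sided_gaussian <- function(t_opt, b_left, b_right, p_max = 0.6) {
  function(tt) {
    d <- tt - t_opt
    b <- ifelse(d > 0, b_right, b_left)
    p_max * exp(-d^2 / (2 * b^2))
  }
}
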