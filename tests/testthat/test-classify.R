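an_range <- c(0, 25)
cc <- classifier_config()

test_that("analytic curves of each archetype get their expected type", {
  gauss <- function(tt) 0.6 * exp(-(tt - 12)^2 / (2 * 3^2))
  expect_equal(classify_trc(gauss, cc, range = an_range)$trc_type, "I")

  right <- two_sided_gaussian(10, 2, 6)
  expect_equal(classify_trc(right, cc, range = an_range)$trc_type, "II")
  left <- two_sided_gaussian(15, 6, 2)
  expect_equal(classify_trc(left, cc, range = an_range)$trc_type, "III")

  flat <- function(tt) rep(0.3, length(tt))
  expect_equal(classify_trc(flat, cc, range = an_range)$trc_type, "IV")

  rise <- function(tt) 0.6 * stats::plogis((tt - 6) / 1)
  expect_equal(classify_trc(rise, cc, range = an_range)$trc_type, "V")
  fall <- function(tt) 0.6 * stats::plogis(-(tt - 19) / 1)
  expect_equal(classify_trc(fall, cc, range = an_range)$trc_type, "VI")

  up <- function(tt) 0.6 * exp(-pmin(tt - 27, 0)^2 / (2 * 9^2))
  expect_equal(classify_trc(up, cc, range = an_range)$trc_type, "VII")
  down <- function(tt) 0.6 * exp(-pmax(tt + 2, 0)^2 / (2 * 9^2))
  expect_equal(classify_trc(down, cc, range = an_range)$trc_type, "VIII")
})

test_that("the probability floor forces type IV regardless of shape", {
  for (f in list(
    function(tt) 0.009 * exp(-(tt - 12)^2 / 18),
    function(tt) 0.0099 * stats::plogis(tt - 10),
    function(tt) rep(0.005, length(tt)))) {
    cl <- classify_trc(f, cc, range = an_range)
    expect_equal(cl$trc_type, "IV")
    expect_equal(cl$sign_sequence, "")
  }
  # scaling any archetype below the floor collapses it to IV
  gauss <- function(tt) 0.6 * exp(-(tt - 12)^2 / 18)
  scaled <- function(tt) gauss(tt) * 0.009 / 0.6
  expect_equal(classify_trc(scaled, cc, range = an_range)$trc_type, "IV")
})

test_that("asymmetry follows the flank-width ratio", {
  # right flank 3x left: A = (3 - 1) / (3 + 1) = 0.5
  f <- two_sided_gaussian(9, 2, 6)
  cl <- classify_trc(f, cc, range = an_range)
  expect_equal(cl$trc_type, "II")
  expect_equal(cl$asymmetry, 0.5, tolerance = 0.02)
  expect_equal(cl$t_peak, 9, tolerance = 0.1)
  sym <- classify_trc(two_sided_gaussian(12, 4, 4), cc, range = an_range)
  expect_equal(sym$asymmetry, 0, tolerance = 0.02)
})

test_that("classification is invariant to temperature-axis translation", {
  shapes <- list(
    function(tt) 0.6 * exp(-(tt - 12)^2 / (2 * 9)),
    two_sided_gaussian(10, 2, 6),
    function(tt) 0.6 * stats::plogis((tt - 6) / 1),
    function(tt) rep(0.3, length(tt)))
  for (f in shapes) {
    base <- classify_trc(f, cc, range = an_range)
    shifted <- classify_trc(function(tt) f(tt - 100), cc,
                            range = an_range + 100)
    expect_equal(shifted$trc_type, base$trc_type)
    expect_equal(shifted$asymmetry, base$asymmetry, tolerance = 1e-8)
  }
})

test_that("mirror symmetry maps II<->III, V<->VI, VII<->VIII, fixes I and IV", {
  battery <- list(
    I    = function(tt) 0.6 * exp(-(tt - 12)^2 / (2 * 3^2)),
    II   = two_sided_gaussian(10, 2, 6),
    III  = two_sided_gaussian(15, 6, 2),
    IV   = function(tt) rep(0.25, length(tt)),
    V    = function(tt) 0.6 * stats::plogis((tt - 6) / 1),
    VI   = function(tt) 0.6 * stats::plogis(-(tt - 19) / 1),
    VII  = function(tt) 0.6 * exp(-pmin(tt - 27, 0)^2 / (2 * 9^2)),
    VIII = function(tt) 0.6 * exp(-pmax(tt + 2, 0)^2 / (2 * 9^2)))
  mirror_of <- c(I = "I", II = "III", III = "II", IV = "IV",
                 V = "VI", VI = "V", VII = "VIII", VIII = "VII")
  mid <- sum(an_range)
  for (nm in names(battery)) {
    f <- battery[[nm]]
    fwd <- classify_trc(f, cc, range = an_range)
    expect_equal(fwd$trc_type, nm, info = nm)
    refl <- classify_trc(function(tt) f(mid - tt), cc, range = an_range)
    expect_equal(refl$trc_type, unname(mirror_of[nm]), info = nm)
    if (!is.na(fwd$asymmetry))
      expect_equal(refl$asymmetry, -fwd$asymmetry, tolerance = 1e-6,
                   info = nm)
  }
})

test_that("multimodal curves fall back to the dominant peak with a warning", {
  f <- function(tt) 0.5 * exp(-(tt - 8)^2 / 2) + 0.3 * exp(-(tt - 18)^2 / 2)
  cl <- classify_trc(f, cc, range = an_range)
  expect_match(cl$warnings, "irregular")
  expect_equal(cl$trc_type, "I")
  expect_equal(cl$t_peak, 8, tolerance = 0.2)
})

test_that("classifying a fitted curve works end to end", {
  set.seed(71)
  tv <- stats::runif(2000, 0, 22)
  y <- draw_presence(tv, "gaussian", 11, 4, p_max = 0.7, seed = 71)
  fit <- fit_trc(y, tv, species_id = "spA", variable = "Tmean_air")
  cl <- classify_trc(fit, cc)
  expect_equal(cl$trc_type, "I")
  expect_equal(cl$species_id, "spA")
  expect_output(print(cl), "TRC type I")
  expect_error(classify_trc(function(tt) tt), "range")
  expect_error(classifier_config(slope_tol = 0), "positive")
})

test_that("per-catchment type composition is bookkept correctly", {
  classifications <- data.frame(
    species_id = c("u1", "u2", "m1"),
    trc_type = c("I", "III", "VII"), stringsAsFactors = FALSE)
  occurrences <- data.frame(
    species_id = c("u1", "u2", "m1", "u1", "m1"),
    catchment_id = c("cA", "cA", "cA", "cB", "cB"),
    stringsAsFactors = FALSE)
  catchments <- data.frame(catchment_id = c("cA", "cB", "cC"),
                           stringsAsFactors = FALSE)
  ts <- spatial_type_summary(classifications, occurrences, catchments)
  expect_equal(ts$n_present, c(3, 2, 0))
  expect_equal(ts$n_unimodal, c(2, 1, 0))
  expect_equal(ts$frac_unimodal, c(2 / 3, 1 / 2, NA))
})
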