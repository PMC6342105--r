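test_that("landscape generation is deterministic under a fixed seed", {
  cfg <- trc_sim_config(n_catchments = 100, seed = 1)
  expect_identical(sim_catchments(cfg), sim_catchments(cfg))
  resp <- sim_responses(sim_catchments(cfg), cfg)
  expect_identical(resp, sim_responses(sim_catchments(cfg), cfg))
})

test_that("invalid simulation configs are rejected", {
  expect_error(trc_sim_config(n_catchments = 1), "n_catchments")
  expect_error(trc_sim_config(max_prob = 0), "max_prob")
  expect_error(trc_sim_config(max_prob = 1.2), "max_prob")
  expect_error(trc_sim_config(breadth_range = c(-1, 2)), "breadth")
  expect_error(trc_sim_config(lat_range = c(10, 95)), "lat_range")
})

test_that("degenerate gradient: no lapse, no noise, uniform seasonality", {
  cfg <- trc_sim_config(n_catchments = 50, lapse_rate = 0,
                        spatial_noise_sd = 0, amplitude_lat_gain = 0,
                        seed = 3)
  ct <- sim_catchments(cfg)
  expect_equal(diff(range(ct$Tmean_air)), 0, tolerance = 1e-12)
  expect_equal(diff(range(ct$Tmax_air)), 0, tolerance = 1e-12)
  for (m in sprintf("month_%02d", 1:12))
    expect_equal(diff(range(ct[[m]])), 0, tolerance = 1e-12)
})

test_that("latitudinal gradient matches the closed-form lapse expectation", {
  cfg <- trc_sim_config(n_catchments = 6000, lapse_rate = 0.6,
                        lat_range = c(35, 70), seed = 7)
  ct <- sim_catchments(cfg)
  south <- ct$Tmean_air[ct$latitude < 36]
  north <- ct$Tmean_air[ct$latitude > 69]
  # expected contrast ~ 0.6 * 34 between the band centres, noise sd 1
  expect_gt(length(south), 30)
  expect_gt(length(north), 30)
  expect_equal(mean(south) - mean(north), 0.6 * 34, tolerance = 1)
  expect_lt(stats::cor(ct$latitude, ct$Tmean_air), -0.95)
})

test_that("Tmean_air is the mean of the monthlies and Tmax_air tops them", {
  ct <- small_landscape(200, seed = 11)
  m <- as.matrix(ct[sprintf("month_%02d", 1:12)])
  expect_equal(ct$Tmean_air, rowMeans(m))
  expect_equal(ct$Tmax_air, apply(m, 1, max) + 5)
})

test_that("every response shape maps onto its curve type one-to-one", {
  resp <- sim_responses(small_landscape(300, seed = 2),
                        trc_sim_config(n_catchments = 300, seed = 2))
  tab <- unique(resp[c("shape", "true_type")])
  expect_equal(nrow(tab), 8)
  expect_setequal(tab$true_type,
                  c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"))
})

test_that("response curves are bounded by p_max and peak at t_opt", {
  tt <- seq(-10, 30, by = 0.05)
  for (shape in trc_shapes()) {
    p <- trc_response_prob(tt, shape, t_opt = 12, breadth = 4,
                           skew = 3, p_max = 0.6)
    expect_true(all(p >= 0 & p <= 0.6), info = shape)
  }
  p <- trc_response_prob(tt, "gaussian", 12, 4, p_max = 0.6)
  expect_equal(tt[which.max(p)], 12, tolerance = 0.1)
})

test_that("zero peak probability yields zero presences", {
  ct <- small_landscape(300, seed = 4)
  resp <- data.frame(species_id = "sp_null", taxon_group = "fish",
                     shape = "gaussian", true_type = "I", t_opt = 5,
                     breadth = 4, skew = 1, p_max = 0,
                     stringsAsFactors = FALSE)
  occ <- sim_occurrences(ct, resp, min_occurrences = 0, seed = 5)
  expect_equal(nrow(occ$occurrences), 0)
})

test_that("vanishing breadth confines presences to temperatures near t_opt", {
  ct <- small_landscape(2000, seed = 6)
  t_opt <- stats::median(ct$Tmean_air)
  resp <- data.frame(species_id = "sp_narrow", taxon_group = "fish",
                     shape = "gaussian", true_type = "I", t_opt = t_opt,
                     breadth = 0.05, skew = 1, p_max = 1,
                     stringsAsFactors = FALSE)
  occ <- sim_occurrences(ct, resp, min_occurrences = 0, seed = 7)
  t_occ <- ct$Tmean_air[ct$catchment_id %in% occ$occurrences$catchment_id]
  expect_true(all(abs(t_occ - t_opt) < 0.5))
})

test_that("binned presence frequencies match the generating curve", {
  ct <- small_landscape(2000, seed = 7)
  t_opt <- 12
  resp <- data.frame(species_id = "sp_bin", taxon_group = "fish",
                     shape = "gaussian", true_type = "I", t_opt = t_opt,
                     breadth = 4, skew = 1, p_max = 0.8,
                     stringsAsFactors = FALSE)
  occ <- sim_occurrences(ct, resp, min_occurrences = 0, seed = 7)
  pres <- ct$catchment_id %in% occ$occurrences$catchment_id
  bin <- floor(ct$Tmean_air)
  for (b in unique(bin)) {
    idx <- bin == b
    n <- sum(idx)
    if (n < 10) next
    p_true <- mean(trc_response_prob(ct$Tmean_air[idx], "gaussian",
                                     t_opt, 4, 1, 0.8))
    ci <- stats::binom.test(sum(pres[idx]), n)$conf.int
    # exact binomial 95% bounds, padded for within-bin curve variation
    expect_gte(p_true, ci[1] - 0.05)
    expect_lte(p_true, ci[2] + 0.05)
  }
})

test_that("species below the occurrence minimum are flagged", {
  ct <- small_landscape(300, seed = 8)
  resp <- data.frame(species_id = c("sp_rare", "sp_common"),
                     taxon_group = "fish", shape = "gaussian",
                     true_type = "I",
                     t_opt = stats::median(ct$Tmean_air),
                     breadth = c(0.01, 8), skew = 1, p_max = c(0.05, 0.9),
                     stringsAsFactors = FALSE)
  occ <- suppressWarnings(
    sim_occurrences(ct, resp, min_occurrences = 50, max_attempts = 3,
                    seed = 9))
  expect_false(occ$responses$ok[occ$responses$species_id == "sp_rare"])
  expect_true(occ$responses$ok[occ$responses$species_id == "sp_common"])
})

test_that("projections reduce to the baseline when offset and spread vanish", {
  ct <- small_landscape(150, seed = 10)
  pr <- sim_projections(ct, warming_offset = 0, model_spread_sd = 0,
                        n_models = 3, seed = 2)
  expect_equal(pr$proj_Tmean_air_mean, ct$Tmean_air)
  pr2 <- sim_projections(ct, warming_offset = 2, model_spread_sd = 0,
                         n_models = 3, seed = 2)
  expect_equal(pr2$proj_Tmean_air_mean, ct$Tmean_air + 2)
  expect_error(sim_projections(ct, n_models = 0), "n_models")
})

test_that("ensemble spread stays within the normal-theory bound", {
  ct <- small_landscape(1000, seed = 12)
  pr <- sim_projections(ct, warming_offset = 2, model_spread_sd = 0.3,
                        n_models = 3, seed = 13)
  dev <- abs(pr$proj_Tmean_air_mean - (ct$Tmean_air + 2))
  expect_gte(mean(dev <= 3 * 0.3 / sqrt(3)), 0.99)
})
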