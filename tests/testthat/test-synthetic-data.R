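test_that("site generation respects spacing, reproducibility and scale", {
  reg <- small_region(years = 2000:2004)
  sites <- generate_sites(reg, n_per_year = 50, seed = 1)
  expect_equal(nrow(sites), 250)
  # minimum 500 m spacing holds within every year
  for (yr in unique(sites$year)) {
    s <- sites[sites$year == yr, ]
    expect_gte(min(dist(s[, c("x", "y")])), 500)
  }
  # land-cover fractions are proper and sum below 1
  lc <- as.matrix(sites[, avitrend:::LAND_COVER_CLASSES])
  expect_true(all(lc >= 0 & lc <= 1))
  expect_true(all(rowSums(lc) <= 1))
  expect_equal(sites$aspect_sin^2 + sites$aspect_cos^2, rep(1, nrow(sites)))
  # bit-reproducible from the seed
  again <- generate_sites(reg, n_per_year = 50, seed = 1)
  expect_identical(sites[names(sites)], again[names(again)])
})

test_that("infeasible spacing is refused by the packing-capacity check", {
  reg <- region_spec(0, 10000, 0, 10000, survey_years = 2000:2001,
                     snapshot_years = c(2000, 2001))
  expect_error(generate_sites(reg, n_per_year = 500, seed = 1),
               "infeasible spacing")
})

test_that("epoch bias shifts the covariate distribution of surveyed sites", {
  reg <- small_region(years = 2000:2009, snaps = c(2000, 2009))
  bias <- list(list(years = 2000:2004, covariate = "forest_2500", strength = 0),
               list(years = 2005:2009, covariate = "forest_2500", strength = 2.5))
  sites <- generate_sites(reg, n_per_year = 80, bias = bias, seed = 3)
  m1 <- mean(sites$forest_2500[sites$year <= 2004])
  m2 <- mean(sites$forest_2500[sites$year >= 2005])
  expect_gt(m2, m1)
})

test_that("count families reduce to Poisson in their limiting cases", {
  set.seed(10)
  sites <- flat_sites(10000)
  # ZIP with zero-inflation switched off is Poisson: chi-square dispersion
  # test at alpha = 0.01
  zip0 <- species_sim_spec("zip0", "ZIP", baseline_log_mean = log(3),
                           zi_coefficients = c(intercept = -40))
  y <- simulate_counts(sites, list(zip0), seed = 11)$counts$pairs
  disp <- (length(y) - 1) * var(y) / mean(y)
  p <- pchisq(disp, length(y) - 1)
  expect_gt(min(p, 1 - p), 0.005)
  # NB with huge dispersion parameter: variance/mean near 1
  nb0 <- species_sim_spec("nb0", "NB", baseline_log_mean = log(3),
                          nb_dispersion = 1e6)
  y2 <- simulate_counts(sites, list(nb0), seed = 12)$counts$pairs
  expect_lt(abs(var(y2) / mean(y2) - 1), 0.05)
})

test_that("ZINB zero mass matches the closed form", {
  set.seed(13)
  sites <- flat_sites(10000)
  pi_ <- plogis(-0.3); mu <- 2.5; k <- 1.2
  sp <- species_sim_spec("z", "ZINB", baseline_log_mean = log(mu),
                         nb_dispersion = k,
                         zi_coefficients = c(intercept = -0.3))
  y <- simulate_counts(sites, list(sp), seed = 14)$counts$pairs
  p0 <- pi_ + (1 - pi_) * (k / (k + mu))^k
  mc_se <- sqrt(p0 * (1 - p0) / length(y))
  expect_lt(abs(mean(y == 0) - p0), 4 * mc_se)
})

test_that("gregarious species emit individuals that invert to pairs", {
  set.seed(15)
  sites <- flat_sites(2000)
  sp <- species_sim_spec("greg", "P", baseline_log_mean = log(4), cf = 11L)
  cc <- simulate_counts(sites, list(sp), seed = 16)$counts
  expect_true(any(cc$individuals > cc$pairs))
  back <- apply_conversion_factors(
    cc[, c("site_id", "year", "species_id", "individuals")],
    c(greg = 11))
  expect_identical(back$pairs, cc$pairs)
})

test_that("trait tables pass raw values through and record group structure", {
  tr <- data.frame(wing_length = 100, body_mass = 27, clutch_size = 5,
                   broods_per_year = 2, incubation_days = 14)
  specs <- list(
    species_sim_spec("a", "P", traits = tr, true_log_trend = -0.02),
    species_sim_spec("b", "P", traits = tr, true_log_trend = -0.02),
    species_sim_spec("c", "P", traits = tr, true_log_trend = 0.01))
  tab <- generate_trait_table(specs)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$wing_length, rep(100, 3))
  expect_equal(tab$body_mass, rep(27, 3))
  # configured group slopes are the recorded truth
  sim <- simulate_counts(flat_sites(50), specs, seed = 2)
  slopes <- vapply(sim$truth, `[[`, numeric(1), "true_log_trend")
  expect_equal(unname(slopes), c(-0.02, -0.02, 0.01))
  expect_error(generate_trait_table(list(species_sim_spec("d", "P"))),
               "no trait values")
})

test_that("truth records track the configured expected index", {
  sites <- flat_sites(500, years = 2000:2004)
  sp <- species_sim_spec("t", "ZIP", baseline_log_mean = log(2),
                         true_log_trend = 0.05,
                         zi_coefficients = c(intercept = qlogis(0.3)))
  truth <- simulate_counts(sites, list(sp), seed = 5)$truth$t
  expect_equal(truth$true_index$index,
               0.7 * 2 * exp(0.05 * (0:4)), tolerance = 1e-12)
})
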