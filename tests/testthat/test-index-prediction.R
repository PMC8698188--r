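test_that("range masks follow the hull-area rule", {
  reg <- region_spec(0, 10000, 0, 10000, survey_years = 2000:2001,
                     snapshot_years = c(2000, 2001))
  # square hull covering 1% of the region (1000 m x 1000 m)
  sq <- data.frame(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000))
  m <- compute_range_mask(sq, reg)
  expect_equal(m$area_ratio, 0.01)
  expect_true(m$use_hull)
  expect_equal(unname(m$centroid), c(500, 500))
  # presences spanning the region: hull ratio >= 0.8 -> whole region
  wide <- data.frame(x = c(0, 10000, 10000, 0, 5000),
                     y = c(0, 0, 10000, 10000, 5000))
  expect_false(compute_range_mask(wide, reg)$use_hull)
  # collinear points degenerate: whole-region fallback with warning
  lin <- data.frame(x = c(0, 100, 200), y = c(0, 100, 200))
  expect_warning(m3 <- compute_range_mask(lin, reg), "degenerate")
  expect_false(m3$use_hull)
  expect_error(compute_range_mask(data.frame(x = numeric(), y = numeric()), reg),
               "no presence points")
  # membership: inside vs outside the 1% hull
  pts <- data.frame(x = c(500, 5000), y = c(500, 5000))
  expect_equal(mask_contains(pts, m), c(TRUE, FALSE))
})

test_that("covariate standardization reproduces smooth snapshot structure", {
  snaps <- data.frame(year = c(1990, 2000, 2010, 2020),
                      a = c(0.10, 0.20, 0.30, 0.40),  # linear in year
                      b = c(0.5, 0.5, 0.5, 0.5))
  sites <- data.frame(x = 1:10 * 100, y = 1:10 * 100,
                      elevation = 101:110, slope = rep(5, 10),
                      aspect_sin = rep(0, 10), aspect_cos = rep(1, 10))
  std <- standardize_covariates(snaps, c(1995, 2005, 2015), sites,
                                topo_cols = c("elevation", "slope"))
  expect_equal(std$a, c(0.15, 0.25, 0.35), tolerance = 1e-8)
  expect_equal(std$b, rep(0.5, 3), tolerance = 1e-8)
  expect_equal(std$elevation, rep(105.5, 3))
  # two snapshots force a straight-line (df 1) fit
  std2 <- standardize_covariates(snaps[c(1, 4), ], 2005, sites,
                                 topo_cols = "elevation")
  expect_equal(std2$a, 0.25, tolerance = 1e-8)
  # clamping of overshoot with warning
  snaps_neg <- data.frame(year = c(2000, 2010), a = c(0.05, 0.01))
  expect_warning(
    std3 <- standardize_covariates(snaps_neg, c(2000, 2015), sites,
                                   topo_cols = "elevation"),
    "clamped")
  expect_gte(min(std3$a), 0)
  # extrapolation beyond 5 years of the snapshot range is refused
  expect_error(standardize_covariates(snaps, 2030, sites), "extrapolate")
})

make_year_fit <- function(n_per_year = 60, years = 2000:2005, b0 = 0.6,
                          slope = 0.08, seed = 30) {
  set.seed(seed)
  d <- data.frame(year = rep(years, each = n_per_year))
  y <- rpois(nrow(d), exp(b0 + slope * (d$year - years[1])))
  des <- build_design(d, year_col = "year")
  list(fit = fit_count_model(des, y, "P"),
       newdata = data.frame(year = years))
}

test_that("bootstrap indices match the closed-form point prediction", {
  mf <- make_year_fit()
  fit <- mf$fit
  # degenerate bootstrap: zero covariance -> point prediction, zero width
  fit0 <- fit
  fit0$vcov[] <- 0
  s0 <- bootstrap_indices(fit0, mf$newdata, B = 50, seed = 1)
  point <- exp(fit$coef[1] + c(0, fit$coef[-1]))
  expect_equal(s0$median, unname(point), tolerance = 1e-12)
  expect_equal(s0$ci_width, rep(0, 6))
  # real bootstrap medians near the point prediction: the per-draw index is
  # lognormal with log-scale SD from the fitted covariance, whose median is
  # exactly the point prediction; bound each of the 6 years at 3 MC SEs of a
  # sample median (a joint check across years)
  s <- bootstrap_indices(fit, mf$newdata, B = 1000, seed = 2)
  Xp <- design_matrix(fit$design, mf$newdata)
  s_log <- sqrt(diag(Xp %*% fit$vcov %*% t(Xp)))
  mc_se <- sqrt(pi / 2) * s_log * point / sqrt(1000)
  expect_true(all(abs(s$median - point) < 3 * mc_se + 1e-9))
  expect_true(all(s$lo <= s$median & s$median <= s$hi))
  expect_true(all(s$lo >= 0))
  # fixed seed reproduces the series bit-for-bit
  expect_identical(s, bootstrap_indices(fit, mf$newdata, B = 1000, seed = 2))
})

test_that("bootstrap refuses non-converged fits and repairs mild asymmetry", {
  mf <- make_year_fit(seed = 31)
  bad <- mf$fit
  bad$converged <- FALSE
  expect_error(bootstrap_indices(bad, mf$newdata, B = 10), "non-converged")
  tweak <- mf$fit
  eps <- 1e-12
  tweak$vcov[1, 2] <- tweak$vcov[1, 2] + eps  # break symmetry harmlessly
  expect_silent(bootstrap_indices(tweak, mf$newdata, B = 10, seed = 3))
  # prediction outside the surveyed years is refused (year is a factor)
  expect_error(bootstrap_indices(mf$fit, data.frame(year = 1990), B = 10),
               "surveyed years")
})
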