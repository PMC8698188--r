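test_that("design bases have the expected structure and reproduce polynomials", {
  set.seed(20)
  d <- data.frame(year = rep(2000:2004, each = 20), elev = runif(100, 0, 100),
                  aspect_sin = runif(100, -1, 1), aspect_cos = runif(100, -1, 1),
                  x = runif(100), y = runif(100))
  des <- build_design(d, smooth_terms = "elev",
                      linear_terms = c("aspect_sin", "aspect_cos"),
                      spatial = c("x", "y"))
  # 1 intercept + 4 year indicators + 4 spline + 2 linear + 9 spatial
  expect_equal(ncol(des$X), 20)
  expect_equal(sum(grepl("^year", colnames(des$X))), 4)
  expect_equal(sum(grepl("^elev_s", colnames(des$X))), 4)
  expect_equal(sum(grepl("^spat_", colnames(des$X))), 9)
  expect_true(all(c("aspect_sin", "aspect_cos") %in% colnames(des$X)))
  # a df-4 cubic basis spans all cubics: regression reproduces one exactly
  z <- d$elev
  target <- 1 + 2 * z - 0.03 * z^2 + 4e-4 * z^3
  B <- des$X[, c("(Intercept)", paste0("elev_s", 1:4))]
  fitted <- B %*% qr.solve(B, target)
  expect_equal(unname(drop(fitted)), target, tolerance = 1e-8)
  # rebuilt design at the training data equals the stored matrix
  expect_equal(design_matrix(des, d), des$X, tolerance = 1e-12)
  # constant covariate: smooth dropped with warning
  d$flat <- 1
  expect_warning(build_design(d, smooth_terms = "flat"), "constant")
})

test_that("intercept-only Poisson recovers the closed-form MLE", {
  set.seed(21)
  y <- rpois(500, 4.2)
  d <- data.frame(year = rep(2000:2001, each = 250))
  des <- build_design(d, year_col = NULL)
  fit <- fit_count_model(des, y, "P")
  expect_equal(unname(exp(fit$coef[1])), mean(y), tolerance = 1e-10)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$npar)
  expect_equal(explained_deviance(fit)[["count"]], 0)
})

test_that("ZIP maximum likelihood recovers simulated parameters", {
  set.seed(22)
  n <- 10000
  pi_true <- 0.4; mu_true <- 3
  y <- ifelse(rbinom(n, 1, pi_true) == 1, 0, rpois(n, mu_true))
  d <- data.frame(year = rep(2000:2001, each = n / 2))
  des <- build_design(d, year_col = NULL, zero_smooth_terms = character())
  fit <- fit_count_model(des, y, "ZIP")
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coef[1] - log(mu_true)), 3 * se[1])
  expect_lt(abs(fit$coef[2] - qlogis(pi_true)), 3 * se[2])
  # deterministic refit
  fit2 <- fit_count_model(des, y, "ZIP")
  expect_identical(fit$coef, fit2$coef)
})

test_that("AIC does not prefer NB over Poisson by more than its 2-point cost", {
  set.seed(23)
  d <- data.frame(year = rep(2000:2001, each = 250))
  des <- build_design(d, year_col = NULL)
  ok <- replicate(200, {
    y <- rpois(500, 3)
    p <- fit_count_model(des, y, "P")
    nb <- fit_count_model(des, y, "NB")
    !nb$converged || nb$aic >= p$aic - 2
  })
  expect_gte(mean(ok), 0.95)
})

test_that("model selection takes the AIC argmin with simplicity tie-break", {
  mock <- function(family, aic, converged = TRUE) {
    structure(list(family = family, label = paste0("C-", family, "-GAM"),
                   aic = aic, converged = converged),
              class = "avitrend_fit")
  }
  fits <- list(mock("P", 100), mock("NB", 102), mock("ZIP", 95), mock("ZINB", 97))
  expect_equal(select_best_model(fits)$family, "ZIP")
  # exact tie resolves to the simpler family
  expect_equal(select_best_model(list(mock("ZIP", 100), mock("P", 100)))$family,
               "P")
  # non-converged fits are excluded
  expect_equal(select_best_model(list(mock("ZIP", 90, FALSE), mock("P", 100)))$family,
               "P")
  expect_error(select_best_model(list(mock("P", 100, FALSE))), "no converged")
})

test_that("explained deviance grows with a real covariate effect", {
  set.seed(24)
  n <- 600
  d <- data.frame(year = rep(2000:2002, each = n / 3), z = runif(n, -2, 2))
  des <- build_design(d, smooth_terms = "z", year_col = NULL)
  y_eff <- rpois(n, exp(0.5 + 0.8 * d$z))
  y_flat <- rpois(n, exp(0.5))
  ed_eff <- explained_deviance(fit_count_model(des, y_eff, "P"))[["count"]]
  ed_flat <- explained_deviance(fit_count_model(des, y_flat, "P"))[["count"]]
  expect_gt(ed_eff, ed_flat)
  expect_gt(ed_eff, 0.2)
  # ZI families also report the zero component
  y_zi <- ifelse(rbinom(n, 1, plogis(1.2 * d$z)) == 1, 0,
                 rpois(n, exp(0.5 + 0.5 * d$z)))
  des_zi <- build_design(d, smooth_terms = "z", year_col = NULL,
                         zero_smooth_terms = "z")
  ed <- explained_deviance(fit_count_model(des_zi, y_zi, "ZIP"))
  expect_named(ed, c("count", "zero"))
  expect_true(all(ed <= 1 + 1e-12))
})
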