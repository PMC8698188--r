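test_that("numeric trait derivation matches the closed forms", {
  tr <- data.frame(wing_length = 100, body_mass = 27, clutch_size = 5,
                   broods_per_year = 2, incubation_days = 14)
  d <- derive_numeric_traits(tr)
  expect_equal(d$dispersal_ratio, 100 / 3)  # cube root of 27 is 3
  expect_equal(d$annual_fecundity, 10)
  expect_equal(d$incubation_period, 14)
  # brood parasites contribute a single brood regardless of the recorded value
  tr$brood_parasite <- TRUE
  tr$broods_per_year <- 3
  expect_equal(derive_numeric_traits(tr)$annual_fecundity, 5)
  tr$body_mass <- -1
  expect_error(derive_numeric_traits(tr), "positive")
})

test_that("quartile categorization is boundary-inclusive with type-7 quantiles", {
  x <- 1:100
  cls <- categorize_by_quartiles(x)
  expect_equal(as.vector(table(cls)), c(25, 50, 25))
  # values exactly at Q1/Q3 fall in the outer classes
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  v <- c(q[1], q[1] + 0.01, q[2] - 0.01, q[2])
  got <- as.character(categorize_by_quartiles(c(x, v)))[101:104]
  expect_equal(got, c("low", "intermediate", "intermediate", "high"))
  expect_warning(categorize_by_quartiles(rep(2, 5)), "identical")
  expect_error(categorize_by_quartiles(1:3), "at least 4")
})

test_that("diet assignment applies the 70% dominance rule", {
  diet <- data.frame(vertebrates = c(0.1, 0.6, 0.05, 0),
                     plants = c(0.1, 0.3, 0.05, 0.75),
                     invertebrates = c(0.75, 0.1, 0.2, 0.25),
                     other = c(0.05, 0, 0, 0))
  diet$scavenger <- c(0, 0, 0.7, 0)
  got <- assign_diet(diet)
  expect_equal(as.character(got),
               c("invertebrates", "omnivores", "vertebrates", "plant-eaters"))
  bad <- data.frame(vertebrates = 0.5, plants = 0.1, invertebrates = 0.1,
                    other = 0.1)
  expect_error(assign_diet(bad), "sum to 1")
})

test_that("nest and landscape classes follow the reclassification rules", {
  expect_equal(as.character(assign_nest_type(
    c("open-arboreal", "closed-arboreal", "ground", "ground-closer", "hole"))),
    c("elevated-nesters", "elevated-nesters", "ground-nesters",
      "ground-nesters", "hole-nesters"))
  expect_error(assign_nest_type("burrow"), "unknown nest")
  cov <- data.frame(urban = c(0.1, 0.1, 0.2, 0.1),
                    agricultural = c(0.2, 0.5, 0.1, 0.1),
                    forest = c(0.6, 0.2, 0.1, 0.2),
                    natural_open = c(0.05, 0.1, 0.55, 0.2),
                    wetland = c(0.05, 0.1, 0.05, 0.3))
  got <- assign_landscape_type(cov)
  # forest 0.6 -> woodland; agricultural exactly 0.50 -> several (strict);
  # natural open 0.55 -> natural open-habitat; nothing dominant -> several
  expect_equal(as.character(got),
               c("woodland", "several", "natural open-habitat", "several"))
  expect_error(assign_landscape_type(
    data.frame(urban = 0.6, agricultural = 0.6, forest = 0,
               natural_open = 0, wetland = 0)), "impossible")
})

test_that("specialization indices match the binary closed forms", {
  # 4-category axis: full generalist 0; single-category user sqrt(K-1)
  u1 <- rbind(rep(1, 4), c(1, 0, 0, 0), c(1, 1, 0, 0))
  s <- compute_specialization(list(food = u1, substrate = u1))
  expect_equal(s$ssi_food, c(0, sqrt(3), 1))
  expect_equal(s$si, s$ssi_food)  # mean of two identical axes
  # permutation of categories leaves the index unchanged
  s2 <- compute_specialization(list(food = u1[, c(3, 1, 4, 2)], substrate = u1))
  expect_equal(s2$ssi_food, s$ssi_food)
  # SI is the plain mean across axes
  u_gen <- matrix(1, 1, 6); u_spec <- matrix(c(1, rep(0, 5)), 1)
  s3 <- compute_specialization(list(a = u_gen, b = u_gen, c = u_gen,
                                    d = u_gen, e = u_spec))
  expect_equal(s3$si, sqrt(5) / 5)
  expect_error(compute_specialization(list(a = matrix(0, 1, 3))), "zero usage")
})

test_that("trait association screening flags strong significant pairs", {
  set.seed(50)
  n <- 500
  a <- factor(sample(letters[1:3], n, replace = TRUE))
  b <- factor(sample(LETTERS[1:3], n, replace = TRUE))  # independent of a
  dup <- a  # perfectly associated with a
  scr <- screen_trait_associations(data.frame(a = a, b = b, dup = dup))
  expect_equal(scr$v_matrix["a", "dup"], 1, tolerance = 1e-12)
  expect_lt(scr$v_matrix["a", "b"], 0.15)
  flagged <- scr$report[scr$report$flagged, ]
  expect_true(all(sort(c(flagged$trait_a, flagged$trait_b)) == c("a", "dup")))
  expect_true("b" %in% scr$retained)
  expect_length(scr$dropped, 1)
  # Fisher fallback on small expected counts
  small <- data.frame(x = factor(c("a", "a", "a", "b", "b", "b")),
                      y = factor(c("u", "u", "v", "v", "v", "u")))
  scr2 <- screen_trait_associations(small)
  expect_equal(scr2$report$test, "fisher")
  expect_warning(
    screen_trait_associations(data.frame(a = a, b = b, single = factor("z"))),
    "single-level")
})

test_that("the full trait derivation yields one level per trait per species", {
  set.seed(51)
  n <- 24
  raw <- data.frame(
    species_id = sprintf("sp%02d", 1:n),
    wing_length = runif(n, 50, 200), body_mass = runif(n, 10, 500),
    clutch_size = runif(n, 2, 8), broods_per_year = sample(1:3, n, TRUE),
    incubation_days = runif(n, 11, 30),
    migration = sample(c("sedentary", "short-distance", "long-distance"), n, TRUE),
    nest_raw = sample(c("open-arboreal", "ground", "hole"), n, TRUE))
  diet <- t(sapply(1:n, function(i) {
    p <- rexp(4); p / sum(p)
  }))
  raw$diet_vertebrates <- diet[, 1]; raw$diet_plants <- diet[, 2]
  raw$diet_invertebrates <- diet[, 3]; raw$diet_other <- diet[, 4]
  cov <- t(sapply(1:n, function(i) {
    p <- rexp(5); p / sum(p)
  }))
  raw$cover_urban <- cov[, 1]; raw$cover_agricultural <- cov[, 2]
  raw$cover_forest <- cov[, 3]; raw$cover_natural_open <- cov[, 4]
  raw$cover_wetland <- cov[, 5]
  usage <- lapply(setNames(1:5, c("food", "behavior", "substrate",
                                  "foraging", "nesting")), function(i) {
    m <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
    m[rowSums(m) == 0, 1] <- 1
    m
  })
  d <- derive_traits(raw, usage)
  expect_equal(nrow(d), n)
  cat_cols <- c("migration", "dr_class", "af_class", "ip_class", "diet_class",
                "nest_class", "landscape_class", "si_class")
  for (cc in cat_cols) expect_true(all(!is.na(d[[cc]])))
  expect_identical(
    trait_quartile_reference$dispersal_ratio, c(q1 = 28.278, q3 = 33.737))
})
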