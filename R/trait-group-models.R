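# Functional-group trend models.
#
# Species index series are first normalized so the median index of each
# species' first surveyed year equals 1 (indices, and the percentile bounds
# used for the weights, are divided by that base median), which makes series
# comparable across species of very different absolute abundance. All
# species-year records of a trait are then pooled into one weighted linear
# model, normalized index ~ group + year + year:group, weighted by the
# reciprocal of the normalized CI width; the year:group interactions carry
# the group-specific trends, tested with finite-sample F statistics.

#' Normalize yearly index series to a first-year median of 1
#'
#' @param series data frame with columns `species_id`, `year`, `median`,
#'   `lo`, `hi` (stacked series of several species are fine). Each species'
#'   base year is its own first recorded year, covering species that entered
#'   the survey late.
#' @return data frame with the same columns plus `ci_width`, `weight`
#'   (1 / normalized CI width) and `base_year`; `median`, `lo`, `hi` are
#'   divided by the species' base-year median.
#' @export
normalize_index_series <- function(series) {
  need <- c("species_id", "year", "median", "lo", "hi")
  stopifnot(all(need %in% names(series)))
  out <- lapply(split(series, series$species_id), function(s) {
    s <- s[order(s$year), , drop = FALSE]
    base <- s$median[1]
    if (!is.finite(base) || base <= 0) {
      stop("base-year median must be positive for species ", s$species_id[1])
    }
    s$median <- s$median / base
    s$lo <- s$lo / base
    s$hi <- s$hi / base
    s$ci_width <- s$hi - s$lo
    s$weight <- wls_weights(s$ci_width)
    s$base_year <- s$year[1]
    s
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Weighted year-by-group trend model for one trait
#'
#' Pools all species-year records, attaches the trait level of each species,
#' and fits `median ~ group + year + year:group` by weighted least squares
#' with the normalized-CI weights. The fitted slope of a group is the `year`
#' coefficient plus that group's interaction coefficient.
#'
#' @param normalized output of [normalize_index_series()].
#' @param groups named vector or factor mapping `species_id` to a trait
#'   level; every level must have at least 2 species.
#' @param reference reference level (default: first level alphabetically).
#' @return object of class `avitrend_group_fit`: the `lm` fit, the
#'   coefficient table, per-group slopes, `reference`, `adj_r2` and the
#'   level/species bookkeeping.
#' @export
fit_group_trend_model <- function(normalized, groups, reference = NULL) {
  stopifnot(all(c("species_id", "year", "median", "weight") %in%
                  names(normalized)))
  g <- groups[match(normalized$species_id, names(groups))]
  if (any(is.na(g))) {
    stop("species without a group level: ",
         paste(head(unique(normalized$species_id[is.na(g)]), 3), collapse = ", "))
  }
  g <- factor(as.character(g))
  if (!is.null(reference)) g <- stats::relevel(g, ref = reference)
  n_species <- tapply(normalized$species_id, g, function(s) length(unique(s)))
  if (any(n_species < 2)) {
    stop("group level(s) with fewer than 2 species: ",
         paste(names(n_species)[n_species < 2], collapse = ", "))
  }
  d <- data.frame(index = normalized$median, year = normalized$year,
                  group = g, w = normalized$weight)
  fit <- lm(index ~ group + year + year:group, data = d, weights = w)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("singular group design (level with too few years?): ",
         paste(bad, collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  levels_ <- levels(g)
  slopes <- setNames(numeric(length(levels_)), levels_)
  for (lv in levels_) {
    slopes[lv] <- coef(fit)["year"] +
      if (lv == levels_[1]) 0 else coef(fit)[paste0("group", lv, ":year")]
  }
  structure(list(lm = fit, coef_table = cf, slopes = slopes,
                 reference = levels_[1], levels = levels_,
                 n_species = n_species,
                 adj_r2 = max(0, summary(fit)$adj.r.squared)),
            class = "avitrend_group_fit")
}

#' Finite-sample F tests of group slopes
#'
#' For every trait level, tests whether its fitted slope (year coefficient
#' plus the level's interaction) is zero, and for every pair of levels
#' whether their slopes are equal; all tests are finite-sample F tests on the
#' fitted weighted model (via `car::linearHypothesis`), with one numerator
#' degree of freedom each, so F equals the square of the matching t
#' statistic for single constraints.
#'
#' @param fit an `avitrend_group_fit`.
#' @return data frame with columns `hypothesis`, `F`, `df1`, `df2`, `p`.
#' @export
test_group_hypotheses <- function(fit) {
  stopifnot(inherits(fit, "avitrend_group_fit"))
  lvls <- fit$levels
  ref <- fit$reference
  slope_term <- function(lv) {
    if (lv == ref) "year" else sprintf("year + group%s:year", lv)
  }
  rows <- list()
  run <- function(label, hyp) {
    lh <- car::linearHypothesis(fit$lm, hyp)
    data.frame(hypothesis = label, F = lh$F[2], df1 = lh$Df[2],
               df2 = lh$Res.Df[2], p = lh$`Pr(>F)`[2])
  }
  for (lv in lvls) {
    rows[[paste0("slope0_", lv)]] <-
      run(sprintf("slope(%s) = 0", lv), sprintf("%s = 0", slope_term(lv)))
  }
  for (pair in combn(lvls, 2, simplify = FALSE)) {
    a <- pair[1]; b <- pair[2]
    hyp <- if (a == ref) {
      sprintf("group%s:year = 0", b)
    } else {
      sprintf("group%s:year = group%s:year", a, b)
    }
    rows[[paste0("eq_", a, "_", b)]] <-
      run(sprintf("slope(%s) = slope(%s)", a, b), hyp)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.avitrend_group_fit <- function(x, ...) {
  cat("group trend model (reference:", x$reference, ")\n")
  cat("per-group slopes (index units per year):\n")
  print(round(x$slopes, 4))
  cat("adj R^2:", round(x$adj_r2, 3), "\n")
  invisible(x)
}
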