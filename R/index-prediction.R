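# Standardized prediction covariates and parametric-bootstrap yearly indices.
#
# The yearly population index is the model's expected number of breeding
# pairs per sampling site at a standardized covariate profile: land-cover
# values follow a smooth-in-year fit to land-cover snapshot averages,
# topography is fixed at its overall mean and the coordinates at the area
# centroid. For species with a localized range (minimum convex hull covering
# less than 80% of the region) the profile is extracted within the hull only.

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x[j] + x) * cr), sum((y[j] + y) * cr)) / (6 * a)
}

#' Range mask from presence points (minimum convex hull)
#'
#' Builds the minimum convex hull of the point counts where the species was
#' recorded over the whole period and compares its area with the region area.
#' When the hull covers less than `ratio_cutoff` (default 0.80) of the region,
#' covariate standardization is restricted to the hull; otherwise the whole
#' region is used. Fewer than three distinct non-collinear presence points
#' give a degenerate hull: the whole region is used, with a warning.
#'
#' @param presence matrix or data frame with columns `x`, `y` of presence
#'   coordinates (meters, planar).
#' @param region a [region_spec()] or any list with `xmin`, `xmax`, `ymin`,
#'   `ymax` elements.
#' @param ratio_cutoff hull/region area ratio below which the hull is used.
#' @return object of class `avitrend_mask`: `hull` (closed polygon matrix),
#'   `area`, `area_ratio`, `use_hull`, `centroid`.
#' @export
compute_range_mask <- function(presence, region, ratio_cutoff = 0.80) {
  xy <- as.matrix(as.data.frame(presence)[, c("x", "y")])
  if (nrow(xy) == 0) stop("no presence points: cannot build a range mask")
  region_area <- (region$xmax - region$xmin) * (region$ymax - region$ymin)
  region_poly <- cbind(x = c(region$xmin, region$xmax, region$xmax, region$xmin),
                       y = c(region$ymin, region$ymin, region$ymax, region$ymax))
  xy <- unique(xy)
  hull <- if (nrow(xy) >= 3) xy[chull(xy), , drop = FALSE] else xy
  area <- if (nrow(hull) >= 3) polygon_area(hull) else 0
  if (area <= 0) {
    warning("degenerate presence hull (collinear or too few points); ",
            "using the whole region")
    return(structure(list(hull = region_poly, area = region_area,
                          area_ratio = 1, use_hull = FALSE,
                          centroid = polygon_centroid(region_poly)),
                     class = "avitrend_mask"))
  }
  ratio <- area / region_area
  structure(list(hull = hull, area = area, area_ratio = ratio,
                 use_hull = ratio < ratio_cutoff,
                 centroid = polygon_centroid(if (ratio < ratio_cutoff) hull
                                             else region_poly)),
            class = "avitrend_mask")
}

#' Restrict sites to a range mask
#'
#' @param sites data frame with `x`, `y` columns.
#' @param mask an `avitrend_mask`; when `use_hull` is `FALSE` all sites pass.
#' @return logical vector marking sites inside the mask.
#' @export
mask_contains <- function(sites, mask) {
  stopifnot(inherits(mask, "avitrend_mask"))
  if (!mask$use_hull) return(rep(TRUE, nrow(sites)))
  bnd <- rbind(mask$hull, mask$hull[1, ])
  inside <- mgcv::in.out(bnd, as.matrix(sites[, c("x", "y")]))
  # hull vertices themselves count as inside
  on_vertex <- paste(sites$x, sites$y) %in% paste(mask$hull[, 1], mask$hull[, 2])
  inside | on_vertex
}

#' Standardized per-year prediction covariates
#'
#' Fits each land-cover class as a smooth function of year over the snapshot
#' years (df = min(4, number of snapshots - 1)) and evaluates it at the
#' survey years, clamping predictions to [0, 1]; the topographic covariates
#' are fixed at their mean over the (masked) sites and the coordinates at the
#' mask centroid. Survey years more than 5 years outside the snapshot range
#' are refused as extrapolation.
#'
#' @param snapshots data frame with a `year` column and one column per
#'   land-cover class, holding the class's average fractional cover within
#'   the mask at that snapshot year.
#' @param survey_years integer vector of years to predict.
#' @param sites data frame of survey sites (for topographic means); only rows
#'   inside `mask` are used when a mask is supplied.
#' @param mask optional `avitrend_mask`.
#' @param topo_cols names of the time-invariant columns held at their mean
#'   (topography and the broader-buffer zero-part covariates).
#' @param df_max maximum smooth df for the year fits.
#' @return data frame with one row per survey year: `year`, the land-cover
#'   columns, the topographic columns and `x`, `y` at the centroid.
#' @export
standardize_covariates <- function(snapshots, survey_years, sites, mask = NULL,
                                   topo_cols = c("elevation", "slope",
                                                 "aspect_sin", "aspect_cos",
                                                 "urban_2500", "forest_2500"),
                                   df_max = 4) {
  stopifnot("year" %in% names(snapshots), nrow(snapshots) >= 2)
  snap_years <- snapshots$year
  if (any(survey_years < min(snap_years) - 5 | survey_years > max(snap_years) + 5)) {
    stop("survey years extrapolate more than 5 years beyond the snapshot range")
  }
  lc_cols <- setdiff(names(snapshots), "year")
  df <- min(df_max, nrow(snapshots) - 1)
  out <- data.frame(year = survey_years)
  for (v in lc_cols) {
    yr <- snapshots$year; val <- snapshots[[v]]
    fit <- if (df >= 3) {
      lm(val ~ splines::bs(yr, df = df))
    } else if (df == 2) {
      lm(val ~ poly(yr, 2, raw = TRUE))
    } else {
      lm(val ~ yr)
    }
    pred <- predict(fit, newdata = data.frame(yr = survey_years))
    if (any(pred < 0 | pred > 1)) {
      warning("predicted cover for `", v, "` outside [0,1]; clamped")
      pred <- pmin(pmax(pred, 0), 1)
    }
    out[[v]] <- pred
  }
  keep <- if (!is.null(mask)) mask_contains(sites, mask) else rep(TRUE, nrow(sites))
  if (!any(keep)) stop("no sites inside the range mask")
  s <- sites[keep, , drop = FALSE]
  for (v in intersect(topo_cols, names(sites))) out[[v]] <- mean(s[[v]])
  ctr <- if (!is.null(mask)) mask$centroid else colMeans(s[, c("x", "y")])
  out$x <- ctr[1]; out$y <- ctr[2]
  out
}

nearest_psd <- function(V, warn_label = "coefficient covariance") {
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) >= -1e-8 * max(abs(e$values), 1)) {
    return(list(V = V, repaired = FALSE))
  }
  lam <- pmax(e$values, 0)
  V2 <- e$vectors %*% (lam * t(e$vectors))
  V2 <- (V2 + t(V2)) / 2
  dist <- sqrt(sum((V - V2)^2)) / max(sqrt(sum(V^2)), 1e-12)
  if (dist > 0.05) {
    stop(warn_label, " is far from positive semidefinite (relative repair ",
         "distance ", format(dist, digits = 3), ")")
  }
  warning(warn_label, " repaired to nearest positive semidefinite matrix")
  list(V = V2, repaired = TRUE)
}

#' Yearly population indices by parametric bootstrap
#'
#' Draws `B` coefficient vectors from the asymptotic multivariate normal
#' centered at the estimates with the fitted coefficient covariance, computes
#' for each draw and each survey year the unconditional expected breeding
#' pairs per site at the standardized covariates (for zero-inflated families,
#' `(1 - pi) * mu`), and summarizes each year by the median and the 2.5th and
#' 97.5th percentiles (type-7 interpolation). The NB/ZINB dispersion does not
#' enter the mean, so it is held at its estimate throughout.
#'
#' @param fit a converged `avitrend_fit`.
#' @param std_cov standardized covariates from [standardize_covariates()]
#'   (one row per survey year, including the `year` column).
#' @param B number of bootstrap draws.
#' @param seed optional integer seed; fixed seed gives bit-identical series.
#' @param level confidence level of the percentile interval.
#' @param species_id optional label stored in the output.
#' @return data frame of class `avitrend_index_series` with columns
#'   `species_id`, `year`, `median`, `lo`, `hi`, `ci_width`.
#' @export
bootstrap_indices <- function(fit, std_cov, B = 1000, seed = NULL,
                              level = 0.95, species_id = NA_character_) {
  stopifnot(inherits(fit, "avitrend_fit"))
  if (!isTRUE(fit$converged)) stop("cannot bootstrap a non-converged fit")
  if (!is.null(seed)) set.seed(seed)
  design <- fit$design
  Xp <- design_matrix(design, std_cov, "count")
  Zp <- if (fit$family %in% c("ZIP", "ZINB")) design_matrix(design, std_cov, "zero")
  theta <- fit$coef
  V <- nearest_psd(fit$vcov)$V
  draws <- MASS::mvrnorm(B, mu = theta, Sigma = V)
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = B)
  eta <- draws[, fit$idx$count, drop = FALSE] %*% t(Xp)       # B x nyear
  idx <- exp(pmin(eta, 40))
  if (!is.null(Zp)) {
    zeta <- draws[, fit$idx$zero, drop = FALSE] %*% t(Zp)
    idx <- (1 - plogis(zeta)) * idx
  }
  alpha <- (1 - level) / 2
  qs <- apply(idx, 2, quantile, probs = c(alpha, 0.5, 1 - alpha),
              names = FALSE, type = 7)
  out <- data.frame(species_id = species_id, year = std_cov$year,
                    median = qs[2, ], lo = qs[1, ], hi = qs[3, ])
  out$ci_width <- out$hi - out$lo
  class(out) <- c("avitrend_index_series", "data.frame")
  out
}
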