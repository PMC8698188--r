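# End-to-end species trend assessment.

#' Assess long-term population trends for all species in a survey
#'
#' Runs the full pipeline on a survey table: conversion of individuals to
#' breeding pairs, frequency filtering, per-species fitting of the candidate
#' count families on the shared covariate design, AIC selection, range-mask
#' construction from the species' presence points, standardized-covariate
#' prediction, parametric-bootstrap yearly indices and the CI-weighted trend
#' test.
#'
#' Counts are zero-filled: every site-year of `sites` contributes an
#' observation for every retained species, with zero pairs where the species
#' has no record.
#'
#' @param counts data frame with `site_id`, `year`, `species_id`,
#'   `individuals` (detections only or dense, both fine).
#' @param sites site table with coordinates and covariates.
#' @param cf_map optional named conversion-factor vector.
#' @param snapshots land-cover snapshot table (see [generate_snapshots()]);
#'   `NULL` builds per-species snapshots from the masked sites' land-cover
#'   averages at the snapshot years of `region`.
#' @param region a [region_spec()] (defaults to the attribute on `sites`).
#' @param smooth_terms,linear_terms,zero_smooth_terms,spatial design
#'   configuration passed to [build_design()]; defaults use every land-cover
#'   class present in `sites`, smooth elevation and slope, linear aspect, a
#'   tensor spatial trend and the broader-buffer zero-part covariates.
#' @param families candidate families.
#' @param frequency_threshold species inclusion threshold (share of point
#'   counts with presence; strict inequality).
#' @param B bootstrap draws per species.
#' @param seed integer seed; per-species bootstrap seeds are derived from it.
#' @return list with `trends` (data frame, one row per retained species,
#'   including the selected family label and explained deviances), `indices`
#'   (stacked yearly index series), `fits` (selected `avitrend_fit` per
#'   species) and `retained` (species passing the filter).
#' @export
assess_trends <- function(counts, sites, cf_map = NULL, snapshots = NULL,
                          region = attr(sites, "region"),
                          smooth_terms = NULL,
                          linear_terms = c("aspect_sin", "aspect_cos"),
                          zero_smooth_terms = c("elevation", "urban_2500",
                                                "forest_2500"),
                          spatial = c("x", "y"),
                          families = c("P", "NB", "ZIP", "ZINB"),
                          frequency_threshold = 0.02, B = 1000, seed = 1L) {
  counts <- apply_conversion_factors(counts, cf_map)
  site_total <- nrow(sites)
  retained <- filter_species_by_frequency(counts, site_total,
                                          frequency_threshold)
  if (!length(retained)) stop("no species passes the frequency filter")
  if (is.null(smooth_terms)) {
    smooth_terms <- c(intersect(LAND_COVER_CLASSES, names(sites)),
                      intersect(c("elevation", "slope"), names(sites)))
  }
  linear_terms <- intersect(linear_terms, names(sites))
  design <- build_design(sites, smooth_terms = smooth_terms,
                         linear_terms = linear_terms, spatial = spatial,
                         year_col = "year",
                         zero_smooth_terms =
                           if (any(families %in% c("ZIP", "ZINB")))
                             zero_smooth_terms)
  site_key <- paste(sites$site_id, sites$year)
  trends <- list(); series_all <- list(); sel_fits <- list()
  for (i in seq_along(retained)) {
    sp <- retained[i]
    rec <- counts[counts$species_id == sp, , drop = FALSE]
    y <- integer(nrow(sites))
    hit <- match(paste(rec$site_id, rec$year), site_key)
    ok <- !is.na(hit)
    y[hit[ok]] <- rec$pairs[ok]
    fits <- fit_count_models(design, y, families)
    best <- select_best_model(fits)
    pres <- sites[y > 0, c("x", "y")]
    mask <- if (!is.null(region)) compute_range_mask(pres, region)
    snap <- snapshots
    if (is.null(snap)) {
      if (is.null(region)) stop("need `snapshots` or a region attribute")
      keep <- if (!is.null(mask)) mask_contains(sites, mask)
              else rep(TRUE, nrow(sites))
      snap <- generate_snapshots(sites[keep, , drop = FALSE], region)
    }
    std <- standardize_covariates(snap, sort(unique(sites$year)), sites, mask)
    series <- bootstrap_indices(best, std, B = B,
                                seed = seed + i, species_id = sp)
    tr <- fit_wls_trend(series)
    tr$species_id <- sp
    dev <- explained_deviance(best)
    trends[[sp]] <- cbind(
      trend_table(list(tr)),
      data.frame(wls_model = best$label, aic = best$aic,
                 dev_expl_count = dev[["count"]],
                 dev_expl_zero = if ("zero" %in% names(dev)) dev[["zero"]]
                                 else NA_real_))
    series_all[[sp]] <- series
    sel_fits[[sp]] <- best
  }
  trends <- do.call(rbind, trends)
  rownames(trends) <- NULL
  indices <- do.call(rbind, series_all)
  rownames(indices) <- NULL
  list(trends = trends, indices = indices, fits = sel_fits,
       retained = retained)
}
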