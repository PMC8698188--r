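#' Conversion-factor map for gregarious species
#'
#' Gregarious species are often detected as family groups during the breeding
#' season; the count of individuals is converted to breeding pairs via an
#' integer conversion factor (CF): `pairs = ceiling(individuals / CF)`.
#' Species absent from the map use CF = 1 (one detected individual, one pair).
#'
#' @param species character vector of species identifiers.
#' @param cf integer vector of conversion factors (>= 1), recycled against
#'   `species` if of length 1.
#' @return A named integer vector usable as the `cf_map` argument of
#'   [apply_conversion_factors()].
#' @examples
#' conversion_factor_map(c("starling", "house_sparrow"), c(11, 14))
#' @export
conversion_factor_map <- function(species, cf) {
  cf <- as.integer(cf)
  if (any(is.na(cf)) || any(cf < 1L)) {
    stop("conversion factors must be integers >= 1")
  }
  setNames(rep_len(cf, length(species)), species)
}

#' Convert detected individuals to breeding pairs
#'
#' Applies species conversion factors to the raw individual counts of a survey
#' table. Pairs are `ceiling(individuals / CF)`; zero individuals always give
#' zero pairs, so the conversion is monotone and never manufactures presence.
#'
#' @param counts data frame with at least columns `species_id` and
#'   `individuals` (non-negative integers).
#' @param cf_map named integer vector mapping species to conversion factors
#'   (see [conversion_factor_map()]); species not listed use CF = 1.
#' @return `counts` with a `pairs` column added (or overwritten).
#' @examples
#' x <- data.frame(species_id = "starling", individuals = c(0, 11, 12, 22))
#' apply_conversion_factors(x, c(starling = 11))$pairs  # 0 1 2 2
#' @export
apply_conversion_factors <- function(counts, cf_map = NULL) {
  stopifnot(is.data.frame(counts), all(c("species_id", "individuals") %in% names(counts)))
  ind <- counts$individuals
  if (any(is.na(ind)) || any(ind < 0) || any(ind != round(ind))) {
    stop("`individuals` must be non-negative integers")
  }
  cf <- rep(1L, nrow(counts))
  if (!is.null(cf_map)) {
    if (is.null(names(cf_map))) stop("`cf_map` must be a named vector")
    if (any(cf_map < 1) || any(cf_map != round(cf_map))) {
      stop("conversion factors must be integers >= 1")
    }
    hit <- match(counts$species_id, names(cf_map))
    cf[!is.na(hit)] <- as.integer(cf_map[hit[!is.na(hit)]])
  }
  counts$pairs <- as.integer(ceiling(ind / cf))
  counts
}

#' Filter species by overall relative frequency
#'
#' A species is retained when the share of point counts at which it was
#' present (pairs > 0) exceeds `threshold` strictly. Presence/absence is used,
#' not abundance, so the filter is unaffected by conversion factors.
#'
#' @param counts data frame with columns `species_id` and `pairs` (or
#'   `individuals` when pairs are not yet derived); one row per
#'   species-by-point-count combination, zero rows simply count as absence.
#' @param site_total total number of distinct point counts in the dataset
#'   (the denominator of the relative frequency).
#' @param threshold frequency threshold in (0, 1); the default 0.02 keeps
#'   species recorded at more than 2% of point counts. `threshold = 0` keeps
#'   every species detected at least once.
#' @return character vector of retained species identifiers.
#' @export
filter_species_by_frequency <- function(counts, site_total, threshold = 0.02) {
  stopifnot(is.data.frame(counts))
  if (length(site_total) != 1L || is.na(site_total) || site_total <= 0) {
    stop("`site_total` must be a positive count of point counts")
  }
  if (threshold < 0 || threshold >= 1) stop("`threshold` must be in [0, 1)")
  y <- if ("pairs" %in% names(counts)) counts$pairs else counts$individuals
  if (is.null(y)) stop("`counts` needs a `pairs` or `individuals` column")
  present <- counts[y > 0, , drop = FALSE]
  # presence = distinct (site, year) point counts where the species was seen
  key_cols <- intersect(c("site_id", "year"), names(counts))
  freq <- if (length(key_cols)) {
    key <- interaction(present[key_cols], drop = TRUE)
    tapply(key, present$species_id, function(k) length(unique(k)))
  } else {
    table(present$species_id)
  }
  n_pres <- as.numeric(freq)
  names(n_pres) <- names(freq)
  sort(names(n_pres)[n_pres / site_total > threshold])
}

#' Validate a survey table against its site table
#'
#' Checks referential integrity (every count row must point at a known
#' site-year), reports survey years without data, and lists within-year site
#' pairs closer than the minimum spacing. Spacing violations are reported as
#' warnings in the returned object, not errors: real pooled datasets are
#' imperfect and the analysis should still run.
#'
#' @param counts data frame with `site_id`, `year` columns.
#' @param sites data frame with `site_id`, `year`, `x`, `y` columns
#'   (planar coordinates in meters).
#' @param species optional vector of known species identifiers; counts
#'   referencing a species outside it are an integrity failure.
#' @param min_spacing minimum within-year distance between sites in meters.
#' @return list with elements `spacing_violations` (data frame of offending
#'   pairs with their distance), `empty_years` (years listed in `sites` with
#'   no counts) and `n_checked`.
#' @export
validate_survey <- function(counts, sites, species = NULL, min_spacing = 500) {
  stopifnot(all(c("site_id", "year") %in% names(counts)),
            all(c("site_id", "year", "x", "y") %in% names(sites)))
  site_key <- paste(sites$site_id, sites$year)
  bad <- !(paste(counts$site_id, counts$year) %in% site_key)
  if (any(bad)) {
    stop("counts reference unknown site-years, e.g. ",
         paste(head(unique(paste(counts$site_id[bad], counts$year[bad])), 3),
               collapse = ", "))
  }
  if (!is.null(species) && "species_id" %in% names(counts)) {
    orphan <- setdiff(unique(counts$species_id), species)
    if (length(orphan)) {
      stop("counts reference unknown species: ",
           paste(head(orphan, 3), collapse = ", "))
    }
  }
  viol <- list()
  for (yr in sort(unique(sites$year))) {
    s <- sites[sites$year == yr, , drop = FALSE]
    if (nrow(s) < 2) next
    d <- as.matrix(dist(s[, c("x", "y")]))
    idx <- which(upper.tri(d) & d < min_spacing, arr.ind = TRUE)
    if (nrow(idx)) {
      viol[[as.character(yr)]] <- data.frame(
        year = yr, site_a = s$site_id[idx[, 1]], site_b = s$site_id[idx[, 2]],
        distance = d[idx])
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(year = integer(), site_a = character(),
               site_b = character(), distance = numeric())
  rownames(viol) <- NULL
  empty <- setdiff(sort(unique(sites$year)), unique(counts$year))
  structure(list(spacing_violations = viol, empty_years = empty,
                 n_checked = nrow(sites)),
            class = "avitrend_validation")
}

#' @export
print.avitrend_validation <- function(x, ...) {
  cat("survey validation:", nrow(x$spacing_violations), "spacing violation(s),",
      length(x$empty_years), "empty year(s) over", x$n_checked, "site-years\n")
  invisible(x)
}
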