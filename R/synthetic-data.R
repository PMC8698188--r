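# Synthetic point-count survey generator with known ground truth.
#
# Emulates the statistical structure the trend pipeline assumes: sites placed
# in a planar region with a minimum within-year spacing, spatially
# autocorrelated environmental covariates (17 land-cover fractions via a
# logistic-normal construction, topography, and two broader-buffer
# covariates driving zero inflation), survey-design bias that shifts the
# covariate distribution of sampled sites across project epochs, per-species
# counts from the Poisson / NB / ZIP / ZINB families with log-linear year
# trends, conversion-factor noise for gregarious species, and a trait table
# with configured group-level trend structure.

LAND_COVER_CLASSES <- c(
  "urban_cont", "urban_disc", "arable", "paddy", "vineyard", "orchard",
  "olive", "wood_plantation", "meadow", "broadleaved", "mixed_forest",
  "coniferous", "grassland", "shrub", "sparse_veg", "wetland_veg", "rivers")

#' Survey region specification
#'
#' @param xmin,xmax,ymin,ymax planar extent in meters (UTM-like coordinates).
#' @param survey_years integer years with surveys; gaps are allowed, matching
#'   monitoring programs with missing years. Default mirrors a 1992-2019
#'   program with no data in 1993-94 and 1997-98.
#' @param snapshot_years years with land-cover snapshot maps; must span the
#'   survey period.
#' @return list of class `avitrend_region`.
#' @export
region_spec <- function(xmin = 0, xmax = 40000, ymin = 0, ymax = 40000,
                        survey_years = setdiff(1992:2019,
                                               c(1993, 1994, 1997, 1998)),
                        snapshot_years = c(1992, 1999, 2007, 2012, 2015, 2019)) {
  stopifnot(xmax > xmin, ymax > ymin, length(survey_years) >= 2)
  if (min(snapshot_years) > min(survey_years) ||
      max(snapshot_years) < max(survey_years)) {
    stop("snapshot years must span the survey period")
  }
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 survey_years = sort(unique(survey_years)),
                 snapshot_years = sort(unique(snapshot_years))),
            class = "avitrend_region")
}

# low-rank Gaussian random field: sum of m Gaussian bumps with iid N(0,1)
# weights, normalized to roughly unit marginal variance
grf_factory <- function(region, correlation_length, m = 40) {
  cx <- runif(m, region$xmin, region$xmax)
  cy <- runif(m, region$ymin, region$ymax)
  w <- rnorm(m)
  ell2 <- 2 * correlation_length^2
  function(x, y) {
    K <- exp(-(outer(x, cx, "-")^2 + outer(y, cy, "-")^2) / ell2)
    drop(K %*% w) / sqrt(m / 4)
  }
}

# environmental model of the region: deterministic functions of location,
# drawn once per generate_sites() call from the seed
make_landscape <- function(region, correlation_length) {
  fields <- lapply(seq_len(length(LAND_COVER_CLASSES) + 4), function(i) {
    grf_factory(region, correlation_length)
  })
  lc_fields <- fields[seq_along(LAND_COVER_CLASSES)]
  extra <- fields[length(LAND_COVER_CLASSES) + 1:4]
  alpha <- rnorm(length(LAND_COVER_CLASSES), mean = -1.5, sd = 0.6)
  covariates_at <- function(x, y) {
    eta <- vapply(seq_along(lc_fields),
                  function(j) alpha[j] + lc_fields[[j]](x, y),
                  numeric(length(x)))
    eta <- matrix(eta, nrow = length(x))
    # logistic-normal: fractions in [0,1] summing to < 1 (remainder = other)
    expeta <- exp(eta)
    frac <- expeta / (1 + rowSums(expeta))
    colnames(frac) <- LAND_COVER_CLASSES
    elevation <- pmax(0, 600 + 500 * extra[[1]](x, y))
    slope <- pmin(45, pmax(0, 12 + 8 * extra[[2]](x, y)))
    theta <- pi * extra[[3]](x, y)
    urban_2500 <- plogis(-1.2 + 1.2 * (lc_fields[[1]](x, y) +
                                         lc_fields[[2]](x, y)) / 2)
    forest_2500 <- plogis(-0.5 + 1.2 * (lc_fields[[10]](x, y) +
                                          lc_fields[[11]](x, y) +
                                          lc_fields[[12]](x, y)) / 3)
    data.frame(frac, elevation = elevation, slope = slope,
               aspect_sin = sin(theta), aspect_cos = cos(theta),
               urban_2500 = urban_2500, forest_2500 = forest_2500)
  }
  list(covariates_at = covariates_at)
}

#' Generate survey sites with covariates and optional design bias
#'
#' Places `n_per_year` sites per survey year inside the region, enforcing a
#' minimum within-year spacing of 500 m, with covariates evaluated from
#' spatially autocorrelated fields drawn once from the seed (so a location
#' has the same environment in every year). A bias configuration emulates
#' the pooling of projects with different designs: within each epoch,
#' candidate sites are accepted with sampling weights that depend on a named
#' covariate, so the covariate distribution of surveyed sites drifts across
#' epochs.
#'
#' @param region a [region_spec()].
#' @param n_per_year sites per survey year; an error is raised when the
#'   extent cannot hold that many sites at the required spacing.
#' @param bias `NULL` for uniform sampling, or a list of epochs, each a list
#'   with `years` (integer vector), `covariate` (a covariate column name)
#'   and `strength` (log-weight per SD of the covariate; positive values
#'   oversample high-covariate sites).
#' @param seed integer seed; all output is reproducible from it.
#' @param correlation_length range of the spatial autocorrelation in meters.
#' @param min_spacing minimum within-year distance between sites (meters).
#' @return data frame of site-years (`site_id`, `year`, `x`, `y`, 17
#'   land-cover fractions, `elevation`, `slope`, `aspect_sin`, `aspect_cos`,
#'   `urban_2500`, `forest_2500`) with the landscape generator attached as
#'   attribute `landscape` and the region as attribute `region`.
#' @export
generate_sites <- function(region, n_per_year, bias = NULL, seed = NULL,
                           correlation_length = 5000, min_spacing = 500) {
  stopifnot(inherits(region, "avitrend_region"), n_per_year >= 1)
  capacity <- floor((region$xmax - region$xmin) / min_spacing + 1) *
    floor((region$ymax - region$ymin) / min_spacing + 1)
  if (n_per_year > capacity) {
    stop("infeasible spacing: ", n_per_year, " sites per year exceed the ",
         "packing capacity (~", capacity, ") of the extent at ",
         min_spacing, " m spacing")
  }
  if (!is.null(seed)) set.seed(seed)
  land <- make_landscape(region, correlation_length)
  epoch_of <- function(year) {
    if (is.null(bias)) return(NULL)
    for (ep in bias) if (year %in% ep$years) return(ep)
    NULL
  }
  rows <- list()
  id0 <- 0L
  for (yr in region$survey_years) {
    ep <- epoch_of(yr)
    # candidate pool, weighted acceptance, greedy spacing enforcement
    n_cand <- max(4000L, 30L * n_per_year)
    cx <- runif(n_cand, region$xmin, region$xmax)
    cy <- runif(n_cand, region$ymin, region$ymax)
    wt <- rep(1, n_cand)
    cov_cand <- NULL
    if (!is.null(ep)) {
      cov_cand <- land$covariates_at(cx, cy)
      v <- cov_cand[[ep$covariate]]
      if (is.null(v)) stop("unknown bias covariate: ", ep$covariate)
      wt <- exp(ep$strength * (v - mean(v)) / max(sd(v), 1e-8))
    }
    ord <- sample.int(n_cand, prob = wt)
    keep <- integer(0)
    for (i in ord) {
      if (length(keep) &&
          any((cx[keep] - cx[i])^2 + (cy[keep] - cy[i])^2 < min_spacing^2)) next
      keep <- c(keep, i)
      if (length(keep) == n_per_year) break
    }
    if (length(keep) < n_per_year) {
      stop("infeasible spacing: could only place ", length(keep), " of ",
           n_per_year, " sites in year ", yr)
    }
    covs <- if (!is.null(cov_cand)) cov_cand[keep, , drop = FALSE] else
      land$covariates_at(cx[keep], cy[keep])
    rows[[as.character(yr)]] <- data.frame(
      site_id = sprintf("s%05d", id0 + seq_len(n_per_year)), year = yr,
      x = cx[keep], y = cy[keep], covs)
    id0 <- id0 + n_per_year
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "landscape") <- land
  attr(out, "region") <- region
  out
}

#' Specification of one simulated species
#'
#' @param species_id species label.
#' @param family count family the species' data are generated from:
#'   `"P"`, `"NB"`, `"ZIP"` or `"ZINB"`.
#' @param baseline_log_mean log expected pairs per site at the mean covariate
#'   profile in the reference (first survey) year.
#' @param covariate_effects named list of per-covariate effects on the log
#'   mean; each element is either a single number (linear coefficient on the
#'   covariate standardized over the supplied sites) or a function of the
#'   raw covariate values.
#' @param true_log_trend per-year slope of the log mean.
#' @param nb_dispersion NB2 dispersion k (> 0) for the NB/ZINB families
#'   (variance mu + mu^2/k).
#' @param zi_coefficients named numeric vector with elements `intercept`,
#'   `elevation`, `urban_2500`, `forest_2500`: logit coefficients of the
#'   structural-zero probability on the standardized covariates (required for
#'   the ZI families).
#' @param cf conversion factor (integer >= 1); for `cf > 1` the emitted
#'   counts are individuals, constructed so that ceiling division by `cf`
#'   recovers the simulated pairs exactly.
#' @param traits optional one-row data frame of raw trait values (see
#'   [generate_trait_table()]).
#' @return list of class `avitrend_species_spec`.
#' @export
species_sim_spec <- function(species_id, family = c("P", "NB", "ZIP", "ZINB"),
                             baseline_log_mean = 0,
                             covariate_effects = list(),
                             true_log_trend = 0, nb_dispersion = NULL,
                             zi_coefficients = NULL, cf = 1L, traits = NULL) {
  family <- match.arg(family)
  if (family %in% c("NB", "ZINB")) {
    if (is.null(nb_dispersion) || nb_dispersion <= 0) {
      stop("NB/ZINB species need nb_dispersion > 0")
    }
  }
  if (family %in% c("ZIP", "ZINB")) {
    if (is.null(zi_coefficients) || is.null(names(zi_coefficients)) ||
        !"intercept" %in% names(zi_coefficients)) {
      stop("ZI species need named zi_coefficients including `intercept`")
    }
  }
  cf <- as.integer(cf)
  if (is.na(cf) || cf < 1L) stop("cf must be an integer >= 1")
  structure(list(species_id = species_id, family = family,
                 baseline_log_mean = baseline_log_mean,
                 covariate_effects = covariate_effects,
                 true_log_trend = true_log_trend,
                 nb_dispersion = nb_dispersion,
                 zi_coefficients = zi_coefficients, cf = cf, traits = traits),
            class = "avitrend_species_spec")
}

species_linear_predictor <- function(spec, sites, stats_) {
  eta <- rep(spec$baseline_log_mean, nrow(sites))
  for (v in names(spec$covariate_effects)) {
    eff <- spec$covariate_effects[[v]]
    x <- sites[[v]]
    if (is.null(x)) stop("species ", spec$species_id,
                         ": covariate `", v, "` not in sites")
    eta <- eta + if (is.function(eff)) eff(x) else
      eff * (x - stats_$mean[v]) / stats_$sd[v]
  }
  eta + spec$true_log_trend * (sites$year - stats_$year0)
}

species_zi_predictor <- function(spec, sites, stats_) {
  zc <- spec$zi_coefficients
  zeta <- rep(zc[["intercept"]], nrow(sites))
  for (v in setdiff(names(zc), "intercept")) {
    zeta <- zeta + zc[[v]] * (sites[[v]] - stats_$mean[v]) / stats_$sd[v]
  }
  zeta
}

covariate_stats <- function(sites) {
  num <- sites[setdiff(names(sites), c("site_id", "year"))]
  list(mean = vapply(num, mean, numeric(1)),
       sd = vapply(num, function(v) max(sd(v), 1e-8), numeric(1)),
       year0 = min(sites$year))
}

#' Simulate point counts for a set of species specifications
#'
#' Draws breeding-pair counts per site-year-species from each species'
#' family, with log link on the mean (baseline + covariate effects +
#' log-linear year trend) and, for the ZI families, a logit structural-zero
#' probability on the standardized broader-buffer covariates. For gregarious
#' species (cf > 1) the emitted raw count is individuals, `(pairs-1)*cf + u`
#' with `u` uniform on `1..cf`, so that downstream ceiling division by the
#' conversion factor recovers the pairs exactly.
#'
#' The recorded truth evaluates each species' expected index at the mean
#' covariate profile of the supplied sites (the profile the pipeline's
#' standardized prediction estimates): for year t,
#' `(1 - pi_bar) * exp(baseline + trend * (t - first_year))`.
#'
#' @param sites site table from [generate_sites()].
#' @param specs list of [species_sim_spec()] objects.
#' @param seed integer seed.
#' @return list with `counts` (data frame: `site_id`, `year`, `species_id`,
#'   `individuals`, plus the true `pairs` for reference) and `truth` (list
#'   per species: `true_index` data frame, `true_log_trend`, `family`, `cf`).
#' @export
simulate_counts <- function(sites, specs, seed = NULL) {
  stopifnot(is.data.frame(sites), length(specs) >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats_ <- covariate_stats(sites)
  years <- sort(unique(sites$year))
  counts <- list()
  truth <- list()
  for (spec in specs) {
    eta <- species_linear_predictor(spec, sites, stats_)
    if (any(!is.finite(eta)) || any(eta > 30)) {
      bad <- which(!is.finite(eta) | eta > 30)[1]
      stop("non-finite/overflowing linear predictor for species ",
           spec$species_id, " at site ", sites$site_id[bad])
    }
    mu <- exp(eta)
    pairs <- switch(spec$family,
      P = rpois(length(mu), mu),
      NB = rnbinom(length(mu), mu = mu, size = spec$nb_dispersion),
      ZIP = {
        z <- rbinom(length(mu), 1, plogis(species_zi_predictor(spec, sites, stats_)))
        ifelse(z == 1, 0L, rpois(length(mu), mu))
      },
      ZINB = {
        z <- rbinom(length(mu), 1, plogis(species_zi_predictor(spec, sites, stats_)))
        ifelse(z == 1, 0L,
               rnbinom(length(mu), mu = mu, size = spec$nb_dispersion))
      })
    individuals <- if (spec$cf > 1L) {
      ifelse(pairs > 0,
             (pairs - 1L) * spec$cf +
               sample.int(spec$cf, length(pairs), replace = TRUE), 0L)
    } else pairs
    counts[[spec$species_id]] <- data.frame(
      site_id = sites$site_id, year = sites$year,
      species_id = spec$species_id,
      individuals = as.integer(individuals), pairs = as.integer(pairs))
    pi_bar <- if (spec$family %in% c("ZIP", "ZINB")) {
      plogis(spec$zi_coefficients[["intercept"]])
    } else 0
    base_eta <- spec$baseline_log_mean  # covariates at their means contribute 0
    for (v in names(spec$covariate_effects)) {
      eff <- spec$covariate_effects[[v]]
      if (is.function(eff)) base_eta <- base_eta + eff(stats_$mean[[v]])
    }
    truth[[spec$species_id]] <- list(
      species_id = spec$species_id,
      true_index = data.frame(
        year = years,
        index = (1 - pi_bar) *
          exp(base_eta + spec$true_log_trend * (years - stats_$year0))),
      true_log_trend = spec$true_log_trend, family = spec$family,
      cf = spec$cf)
  }
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL
  list(counts = counts, truth = truth)
}

#' Land-cover snapshot table for a generated landscape
#'
#' Computes, for each snapshot year, the regional (or masked) average of the
#' 17 land-cover fractions over the supplied sites, optionally with a linear
#' per-year drift added to emulate land-use change between map editions.
#'
#' @param sites site table from [generate_sites()].
#' @param region the [region_spec()] (defaults to the attribute on `sites`).
#' @param drift optional named numeric vector of per-year drifts (fraction
#'   units per year) for a subset of land-cover classes.
#' @return data frame: `year` plus one column per land-cover class.
#' @export
generate_snapshots <- function(sites, region = attr(sites, "region"),
                               drift = NULL) {
  stopifnot(!is.null(region))
  base <- colMeans(sites[LAND_COVER_CLASSES])
  y0 <- min(region$snapshot_years)
  rows <- lapply(region$snapshot_years, function(yr) {
    v <- base
    if (!is.null(drift)) {
      v[names(drift)] <- pmin(pmax(v[names(drift)] + drift * (yr - y0), 0), 1)
    }
    data.frame(year = yr, as.list(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trait table of a set of species specifications
#'
#' Collects the raw trait rows carried by the specifications into one table;
#' group-level trend structure is whatever the specifications encode (e.g.
#' all "farmland" species sharing a common trend component), so the recorded
#' per-species `true_log_trend` doubles as the group truth.
#'
#' @param specs list of [species_sim_spec()] objects, each carrying a
#'   one-row `traits` data frame.
#' @return data frame with one row per species (`species_id` first).
#' @export
generate_trait_table <- function(specs) {
  rows <- lapply(specs, function(sp) {
    if (is.null(sp$traits)) {
      stop("species ", sp$species_id, " has no trait values")
    }
    cbind(data.frame(species_id = sp$species_id), sp$traits)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default species specifications for a synthetic community
#'
#' Builds a small community of species covering the four count families with
#' log-linear trends of configurable magnitude, mild land-cover effects and,
#' for the ZI families, elevation/urban/forest-driven zero inflation —
#' the structure the pipeline is designed to recover.
#'
#' @param n_species number of species.
#' @param trends vector of per-year log-linear trends, recycled.
#' @param families families to cycle through, recycled.
#' @param baseline log mean pairs per site at the covariate means.
#' @param zi_intercept logit of the baseline structural-zero probability for
#'   ZI species.
#' @param nb_dispersion NB2 dispersion for NB/ZINB species.
#' @return list of [species_sim_spec()] objects.
#' @export
default_species_specs <- function(n_species = 8,
                                  trends = c(-0.04, -0.02, 0, 0.02, 0.04),
                                  families = c("P", "NB", "ZIP", "ZINB"),
                                  baseline = 0.5, zi_intercept = -0.5,
                                  nb_dispersion = 2) {
  lapply(seq_len(n_species), function(i) {
    fam <- families[(i - 1) %% length(families) + 1]
    species_sim_spec(
      species_id = sprintf("sp%02d", i), family = fam,
      baseline_log_mean = baseline,
      covariate_effects = list(broadleaved = 0.3, arable = -0.2,
                               elevation = -0.2),
      true_log_trend = trends[(i - 1) %% length(trends) + 1],
      nb_dispersion = if (fam %in% c("NB", "ZINB")) nb_dispersion,
      zi_coefficients = if (fam %in% c("ZIP", "ZINB")) {
        c(intercept = zi_intercept, elevation = 0.5, urban_2500 = 0.4,
          forest_2500 = -0.3)
      },
      cf = 1L)
  })
}

#' Write a simulated survey to CSV files
#'
#' @param sim list with `counts` and `truth` from [simulate_counts()].
#' @param sites site table.
#' @param dir output directory (created if needed).
#' @param snapshots optional snapshot table.
#' @param traits optional trait table.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, sites, dir, snapshots = NULL, traits = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.csv"),
             sites = file.path(dir, "sites.csv"))
  write.csv(sim$counts, paths["counts"], row.names = FALSE)
  write.csv(sites, paths["sites"], row.names = FALSE)
  truth_df <- do.call(rbind, lapply(sim$truth, function(t) {
    data.frame(species_id = t$species_id, year = t$true_index$year,
               index = t$true_index$index, true_log_trend = t$true_log_trend,
               family = t$family, cf = t$cf)
  }))
  paths["truth"] <- file.path(dir, "truth.csv")
  write.csv(truth_df, paths["truth"], row.names = FALSE)
  if (!is.null(snapshots)) {
    paths["snapshots"] <- file.path(dir, "snapshots.csv")
    write.csv(snapshots, paths["snapshots"], row.names = FALSE)
  }
  if (!is.null(traits)) {
    paths["traits"] <- file.path(dir, "traits.csv")
    write.csv(traits, paths["traits"], row.names = FALSE)
  }
  invisible(paths)
}
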