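# shared small-scale synthetic fixtures, built in code at test time

small_region <- function(years = seq(1992, 2010, 2),
                         snaps = c(1992, 2000, 2010), extent = 20000) {
  region_spec(0, extent, 0, extent, survey_years = years,
              snapshot_years = snaps)
}

# minimal site table with constant-ish covariates, for family-level
# simulation tests that need fixed covariates
flat_sites <- function(n, years = 2000) {
  data.frame(site_id = sprintf("f%05d", seq_len(n * length(years))),
             year = rep(years, each = n),
             x = runif(n * length(years), 0, 1e4),
             y = runif(n * length(years), 0, 1e4))
}

# independent weighted-least-squares oracle via the centered normal equations
wls_oracle <- function(year, index, w) {
  n <- length(index)
  xw <- sum(w * year) / sum(w)
  yw <- sum(w * index) / sum(w)
  sxx <- sum(w * (year - xw)^2)
  slope <- sum(w * (year - xw) * (index - yw)) / sxx
  intercept <- yw - slope * xw
  e <- index - intercept - slope * year
  s2 <- sum(w * e^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept, se = se, t = t,
       p = 2 * pt(-abs(t), n - 2))
}

# yearly index series with exactly known structure
make_series <- function(years, medians, widths, species = "spA") {
  data.frame(species_id = species, year = years, median = medians,
             lo = medians - widths / 2, hi = medians + widths / 2,
             ci_width = widths)
}

# stacked log-linear index series for one functional group
make_group_series <- function(n_species, slope, years = 1992:2006,
                              base = 2, noise = 0.05, label = "g") {
  do.call(rbind, lapply(seq_len(n_species), function(i) {
    med <- base * exp(slope * (years - years[1])) *
      exp(rnorm(length(years), 0, noise))
    w <- runif(length(years), 0.2, 0.5) * med
    make_series(years, med, w, species = sprintf("%s%02d", label, i))
  }))
}
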