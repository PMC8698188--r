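# Life-history and ecological trait derivation.
#
# Eight categorical traits are derived per species: migration strategy
# (as recorded), dispersal ratio, annual fecundity and incubation period
# (quartile-categorized), diet (70% rule over food fractions), nest type
# (reclassified to elevated / ground / hole nesters), landscape type
# (50% rule over landscape-scale cover medians) and the overall
# specialization index (mean of five single-axis indices, then
# quartile-categorized). Pairwise trait associations are screened with
# Cramer's V backed by a chi-squared or Fisher exact test.

#' Published quartile thresholds for the numeric life-history traits
#'
#' Reference constants as printed in the source study: first and third
#' quartiles of dispersal ratio (28.278 / 33.737), annual fecundity
#' (5 / 10.625) and incubation period (13 / 17.25) over its 76 analyzed
#' species. Shipped for comparison and worked examples only; analyses on new
#' data recompute quartiles from the data via [categorize_by_quartiles()].
#' @export
trait_quartile_reference <- list(
  dispersal_ratio = c(q1 = 28.278, q3 = 33.737),
  annual_fecundity = c(q1 = 5, q3 = 10.625),
  incubation_period = c(q1 = 13, q3 = 17.25)
)

#' Derive the numeric life-history traits
#'
#' Dispersal ratio DR = wing length (mm) / cube root of body mass (g), a
#' mobility surrogate; annual fecundity AF = mean clutch size x mean broods
#' per year (brood parasites have broods forced to 1); incubation period
#' IP = mean incubation length in days.
#'
#' @param traits data frame with columns `wing_length`, `body_mass`,
#'   `clutch_size`, `broods_per_year`, `incubation_days` and optionally
#'   logical `brood_parasite`.
#' @return `traits` with `dispersal_ratio`, `annual_fecundity`,
#'   `incubation_period` columns added.
#' @examples
#' derive_numeric_traits(data.frame(wing_length = 100, body_mass = 27,
#'   clutch_size = 5, broods_per_year = 2, incubation_days = 14))
#' @export
derive_numeric_traits <- function(traits) {
  need <- c("wing_length", "body_mass", "clutch_size", "broods_per_year",
            "incubation_days")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("missing trait columns: ", paste(miss, collapse = ", "))
  num <- traits[need]
  if (any(!complete.cases(num)) || any(as.matrix(num) <= 0)) {
    stop("all numeric trait values must be present and positive")
  }
  broods <- traits$broods_per_year
  if (!is.null(traits$brood_parasite)) {
    broods[which(traits$brood_parasite)] <- 1
  }
  traits$dispersal_ratio <- traits$wing_length / traits$body_mass^(1 / 3)
  traits$annual_fecundity <- traits$clutch_size * broods
  traits$incubation_period <- traits$incubation_days
  traits
}

#' Categorize a numeric trait by its quartiles
#'
#' Values at or below the first quartile are "low", at or above the third
#' quartile "high", and "intermediate" in between. Quartiles are computed
#' over all analyzed species with linear-interpolation (type 7) quantiles.
#'
#' @param values numeric vector (one value per species, at least 4).
#' @param labels category labels, low to high.
#' @return factor with the three levels of `labels`.
#' @export
categorize_by_quartiles <- function(values,
                                    labels = c("low", "intermediate", "high")) {
  stopifnot(length(labels) == 3)
  if (length(values) < 4) stop("need at least 4 species to form quartiles")
  if (sd(values) < 1e-12) {
    warning("all trait values identical; every species categorized as `",
            labels[1], "`")
  }
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  out <- ifelse(values <= q[1], labels[1],
                ifelse(values >= q[2], labels[3], labels[2]))
  factor(out, levels = labels)
}

#' Assign the diet category by the 70% rule
#'
#' A species is classed by a food source covering at least 70% of its diet
#' ("vertebrates", "plant-eaters" or "invertebrates"); otherwise it is an
#' omnivore. An optional scavenger fraction counts toward vertebrates.
#'
#' @param diet data frame (one row per species) with columns `vertebrates`,
#'   `plants`, `invertebrates`, `other` and optionally `scavenger`; each
#'   row must sum to 1 within 1e-6.
#' @param threshold dominance threshold (default 0.70).
#' @return factor with levels vertebrates / plant-eaters / invertebrates /
#'   omnivores.
#' @export
assign_diet <- function(diet, threshold = 0.70) {
  need <- c("vertebrates", "plants", "invertebrates", "other")
  miss <- setdiff(need, names(diet))
  if (length(miss)) stop("missing diet columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(diet[intersect(c(need, "scavenger"), names(diet))])
  if (any(abs(rowSums(m) - 1) > 1e-6)) {
    stop("diet fractions must sum to 1 for every species")
  }
  vert <- diet$vertebrates + if ("scavenger" %in% names(diet)) diet$scavenger else 0
  out <- ifelse(vert >= threshold, "vertebrates",
         ifelse(diet$plants >= threshold, "plant-eaters",
         ifelse(diet$invertebrates >= threshold, "invertebrates", "omnivores")))
  factor(out, levels = c("vertebrates", "plant-eaters", "invertebrates",
                         "omnivores"))
}

#' Reclassify raw nest position into nest type
#'
#' @param nest_raw character/factor with levels among open-arboreal,
#'   closed-arboreal, ground, ground-closer, hole.
#' @return factor with levels elevated-nesters / ground-nesters / hole-nesters.
#' @export
assign_nest_type <- function(nest_raw) {
  map <- c(`open-arboreal` = "elevated-nesters",
           `closed-arboreal` = "elevated-nesters",
           ground = "ground-nesters", `ground-closer` = "ground-nesters",
           hole = "hole-nesters")
  v <- as.character(nest_raw)
  bad <- setdiff(unique(v), names(map))
  if (length(bad)) stop("unknown nest categories: ", paste(bad, collapse = ", "))
  factor(unname(map[v]),
         levels = c("elevated-nesters", "ground-nesters", "hole-nesters"))
}

#' Assign the landscape type by the 50% rule
#'
#' A species whose median fractional cover of one landscape level (around its
#' presence points) exceeds 50% is assigned that level: agricultural maps to
#' "farmland", forest to "woodland" and natural open cover to
#' "natural open-habitat". When no level exceeds 50% — including dominance of
#' a level with no named class, such as urban or wetland — the species is
#' "several". The inequality is strict, and two levels above 50% are
#' impossible for fractions summing to at most 1.
#'
#' @param covers data frame (one row per species) with columns `urban`,
#'   `agricultural`, `forest`, `natural_open`, `wetland`, medians in [0, 1].
#' @return factor with levels farmland / woodland / natural open-habitat /
#'   several.
#' @export
assign_landscape_type <- function(covers) {
  need <- c("urban", "agricultural", "forest", "natural_open", "wetland")
  miss <- setdiff(need, names(covers))
  if (length(miss)) stop("missing cover columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(covers[need])
  if (any(m < 0 | m > 1)) stop("cover medians must be in [0, 1]")
  if (any(rowSums(m > 0.5) > 1)) {
    stop("two landscape levels above 50%: impossible for fractional covers")
  }
  out <- rep("several", nrow(m))
  out[covers$agricultural > 0.5] <- "farmland"
  out[covers$forest > 0.5] <- "woodland"
  out[covers$natural_open > 0.5] <- "natural open-habitat"
  factor(out, levels = c("farmland", "woodland", "natural open-habitat",
                         "several"))
}

#' Single-axis and overall specialization indices
#'
#' For each resource axis, the single-axis specialization index of a species
#' is the coefficient of variation (population standard deviation over mean)
#' of its binary usage vector across the axis's categories: 0 for a species
#' using every category, and sqrt(K - 1) for a species using a single one of
#' K categories. The overall index SI is the mean of the five axis indices.
#'
#' @param usage named list of binary matrices (species x categories), one per
#'   axis (food type, acquisition behavior, substrate, foraging habitat,
#'   nesting habitat); every species must use at least one category per axis
#'   and every axis must have at least 2 categories.
#' @return data frame with one `ssi_<axis>` column per axis and the overall
#'   `si` column.
#' @export
compute_specialization <- function(usage) {
  stopifnot(is.list(usage), length(usage) >= 1)
  if (is.null(names(usage))) names(usage) <- paste0("axis", seq_along(usage))
  n <- nrow(usage[[1]])
  ssi <- sapply(names(usage), function(ax) {
    m <- as.matrix(usage[[ax]])
    if (ncol(m) < 2) stop("axis `", ax, "` needs at least 2 categories")
    if (nrow(m) != n) stop("usage matrices must have the same species rows")
    if (!all(m %in% c(0, 1))) stop("usage must be binary (axis `", ax, "`)")
    if (any(rowSums(m) == 0)) {
      stop("species with zero usage on axis `", ax, "`")
    }
    apply(m, 1, function(u) {
      mu <- mean(u)
      sqrt(mean((u - mu)^2)) / mu  # population SD / mean
    })
  })
  ssi <- matrix(ssi, nrow = n, dimnames = list(NULL, paste0("ssi_", names(usage))))
  out <- as.data.frame(ssi)
  out$si <- rowMeans(ssi)
  out
}

#' Cramer's V between two categorical variables
#'
#' @param x,y factors/vectors of equal length, or `x` a contingency table
#'   with `y` missing.
#' @return V in [0, 1], computed from the uncorrected chi-squared statistic
#'   as `sqrt(chi2 / (n * (min(r, c) - 1)))`.
#' @export
cramers_v <- function(x, y = NULL) {
  tab <- if (is.null(y)) as.table(as.matrix(x)) else table(x, y)
  chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
  n <- sum(tab)
  unname(sqrt(chi2 / (n * (min(dim(tab)) - 1))))
}

#' Screen pairwise trait associations with Cramer's V
#'
#' For every pair of categorical traits, tabulates the species and tests
#' independence with the chi-squared test (uncorrected), replaced by Fisher's
#' exact test when any expected cell count is below 5. Traits taking part in
#' a significant association with V at or above `v_cutoff` are flagged; by
#' default the member of each flagged pair with the higher mean V across all
#' pairs is proposed for removal (a configured drop list can override this).
#'
#' @param traits data frame of categorical traits (factors), one row per
#'   species; traits with a single observed level are excluded with a warning.
#' @param v_cutoff association strength above which a significant pair is
#'   flagged (default 0.5, i.e. only weak-to-moderate associations are kept).
#' @param alpha significance level of the independence test.
#' @param drop optional character vector naming the traits to drop among the
#'   flagged ones, overriding the mean-V heuristic.
#' @return list with `v_matrix`, `report` (one row per pair: V, test used,
#'   p, flagged), `retained` and `dropped`.
#' @export
screen_trait_associations <- function(traits, v_cutoff = 0.5, alpha = 0.05,
                                      drop = NULL) {
  stopifnot(is.data.frame(traits), ncol(traits) >= 2)
  nlev <- vapply(traits, function(v) length(unique(v[!is.na(v)])), integer(1))
  if (any(nlev < 2)) {
    warning("excluding single-level trait(s): ",
            paste(names(traits)[nlev < 2], collapse = ", "))
    traits <- traits[nlev >= 2]
  }
  nm <- names(traits)
  if (length(nm) < 2) stop("need at least 2 multi-level traits to screen")
  V <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  diag(V) <- 1
  rep_rows <- list()
  for (pair in combn(nm, 2, simplify = FALSE)) {
    a <- pair[1]; b <- pair[2]
    tab <- table(traits[[a]], traits[[b]])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    expct <- suppressWarnings(chisq.test(tab, correct = FALSE))$expected
    use_fisher <- any(expct < 5)
    p <- if (use_fisher) {
      tryCatch(fisher.test(tab)$p.value,
               error = function(e) fisher.test(tab, simulate.p.value = TRUE,
                                               B = 1e4)$p.value)
    } else {
      suppressWarnings(chisq.test(tab, correct = FALSE))$p.value
    }
    v <- cramers_v(tab)
    V[a, b] <- V[b, a] <- v
    rep_rows[[paste(a, b)]] <- data.frame(
      trait_a = a, trait_b = b, v = v,
      test = if (use_fisher) "fisher" else "chisq", p = p,
      flagged = (p <= alpha) && (v >= v_cutoff))
  }
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  dropped <- character(0)
  flagged_pairs <- report[report$flagged, , drop = FALSE]
  if (nrow(flagged_pairs)) {
    if (!is.null(drop)) {
      dropped <- intersect(drop, nm)
    } else {
      mean_v <- rowMeans(V, na.rm = TRUE)
      for (i in seq_len(nrow(flagged_pairs))) {
        a <- flagged_pairs$trait_a[i]; b <- flagged_pairs$trait_b[i]
        if (a %in% dropped || b %in% dropped) next
        dropped <- c(dropped, if (mean_v[a] >= mean_v[b]) a else b)
      }
    }
  }
  list(v_matrix = V, report = report,
       retained = setdiff(nm, dropped), dropped = dropped)
}

#' Derive the full categorical trait table
#'
#' Convenience wrapper producing the eight final traits from a raw trait
#' table and the usage matrices: migration (as recorded), quartile classes of
#' dispersal ratio, annual fecundity and incubation period, diet class, nest
#' type, landscape type and the specialization-index class.
#'
#' @param traits raw trait data frame; see [derive_numeric_traits()],
#'   [assign_diet()] (columns prefixed `diet_`), [assign_nest_type()]
#'   (`nest_raw`), [assign_landscape_type()] (columns prefixed `cover_`).
#' @param usage list of binary usage matrices for [compute_specialization()].
#' @return data frame with `species_id` and the eight categorical traits,
#'   plus the numeric `dispersal_ratio`, `annual_fecundity`,
#'   `incubation_period` and `si` values.
#' @export
derive_traits <- function(traits, usage) {
  traits <- derive_numeric_traits(traits)
  diet_cols <- c(vertebrates = "diet_vertebrates", plants = "diet_plants",
                 invertebrates = "diet_invertebrates", other = "diet_other")
  diet <- setNames(traits[diet_cols], names(diet_cols))
  if ("diet_scavenger" %in% names(traits)) diet$scavenger <- traits$diet_scavenger
  cover_cols <- c(urban = "cover_urban", agricultural = "cover_agricultural",
                  forest = "cover_forest", natural_open = "cover_natural_open",
                  wetland = "cover_wetland")
  covers <- setNames(traits[cover_cols], names(cover_cols))
  spec <- compute_specialization(usage)
  data.frame(
    species_id = traits$species_id,
    migration = factor(traits$migration,
                       levels = c("sedentary", "short-distance",
                                  "long-distance")),
    dispersal_ratio = traits$dispersal_ratio,
    dr_class = categorize_by_quartiles(traits$dispersal_ratio),
    annual_fecundity = traits$annual_fecundity,
    af_class = categorize_by_quartiles(traits$annual_fecundity),
    incubation_period = traits$incubation_period,
    ip_class = categorize_by_quartiles(traits$incubation_period,
                                       labels = c("short", "intermediate",
                                                  "long")),
    diet_class = assign_diet(diet),
    nest_class = assign_nest_type(traits$nest_raw),
    landscape_class = assign_landscape_type(covers),
    si = spec$si,
    si_class = categorize_by_quartiles(spec$si,
                                       labels = c("generalist", "intermediate",
                                                  "specialist")))
}
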