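# Fixed-df spline design matrices for the count models.
#
# Smooths are unpenalized cubic B-spline bases with interior knots at
# covariate quantiles and at most 4 degrees of freedom each, so maximum
# likelihood, AIC parameter counts and the coefficient covariance are all
# well-defined without smoothing-parameter machinery. The survey year enters
# as a treatment-coded factor (first surveyed year as reference), aspect
# sine/cosine enter linearly, and the spatial trend is a tensor product of
# two df-3 marginal bases in the planar coordinates.

smooth_term_meta <- function(x, df, name) {
  if (df < 1 || df > 4) stop("smooth df must be in 1..4 (term ", name, ")")
  if (df >= 3) {
    b <- splines::bs(x, df = df)
    list(type = "bs", df = df, knots = attr(b, "knots"),
         boundary = attr(b, "Boundary.knots"), degree = attr(b, "degree"))
  } else {
    # low-df fallback: raw polynomial of matching dimension
    list(type = "poly", df = df, center = mean(x), scale = max(sd(x), 1e-8))
  }
}

smooth_term_eval <- function(meta, x) {
  if (meta$type == "bs") {
    # clamp to the training range so bootstrap-time prediction never
    # extrapolates the polynomial tails
    xc <- pmin(pmax(x, meta$boundary[1]), meta$boundary[2])
    unclass(splines::bs(xc, knots = meta$knots, Boundary.knots = meta$boundary,
                        degree = meta$degree))
  } else {
    z <- (x - meta$center) / meta$scale
    sapply(seq_len(meta$df), function(p) z^p)
  }
}

build_part <- function(data, smooth_terms, linear_terms, spatial, year_col,
                       df, spatial_df, year_levels) {
  n <- nrow(data)
  meta <- list(smooth = list(), linear = linear_terms, spatial = NULL,
               year_col = year_col, year_levels = year_levels)
  cols <- list(`(Intercept)` = rep(1, n))
  if (!is.null(year_col)) {
    f <- factor(data[[year_col]], levels = year_levels)
    mm <- model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(year_col, year_levels[-1])
    for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
  }
  for (v in smooth_terms) {
    x <- data[[v]]
    if (is.null(x)) stop("covariate `", v, "` not found")
    if (sd(x) < 1e-12) {
      warning("covariate `", v, "` is constant; its smooth is dropped")
      next
    }
    m <- smooth_term_meta(x, df, v)
    B <- smooth_term_eval(m, x)
    colnames(B) <- paste0(v, "_s", seq_len(ncol(B)))
    meta$smooth[[v]] <- m
    for (j in seq_len(ncol(B))) cols[[colnames(B)[j]]] <- B[, j]
  }
  for (v in linear_terms) {
    if (is.null(data[[v]])) stop("covariate `", v, "` not found")
    cols[[v]] <- data[[v]]
  }
  if (!is.null(spatial)) {
    mx <- smooth_term_meta(data[[spatial[1]]], spatial_df, spatial[1])
    my <- smooth_term_meta(data[[spatial[2]]], spatial_df, spatial[2])
    Bx <- smooth_term_eval(mx, data[[spatial[1]]])
    By <- smooth_term_eval(my, data[[spatial[2]]])
    meta$spatial <- list(vars = spatial, x = mx, y = my)
    for (i in seq_len(ncol(Bx))) for (j in seq_len(ncol(By))) {
      cols[[paste0("spat_", i, "_", j)]] <- Bx[, i] * By[, j]
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, meta = meta)
}

eval_part <- function(meta, keep, data) {
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  if (!is.null(meta$year_col)) {
    yv <- data[[meta$year_col]]
    if (!all(yv %in% meta$year_levels)) {
      stop("prediction years must be surveyed years (factor levels): offending ",
           paste(setdiff(yv, meta$year_levels), collapse = ", "))
    }
    f <- factor(yv, levels = meta$year_levels)
    mm <- model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(meta$year_col, meta$year_levels[-1])
    for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
  }
  for (v in names(meta$smooth)) {
    if (is.null(data[[v]])) stop("covariate `", v, "` missing in newdata")
    B <- smooth_term_eval(meta$smooth[[v]], data[[v]])
    colnames(B) <- paste0(v, "_s", seq_len(ncol(B)))
    for (j in seq_len(ncol(B))) cols[[colnames(B)[j]]] <- B[, j]
  }
  for (v in meta$linear) cols[[v]] <- data[[v]]
  if (!is.null(meta$spatial)) {
    Bx <- smooth_term_eval(meta$spatial$x, data[[meta$spatial$vars[1]]])
    By <- smooth_term_eval(meta$spatial$y, data[[meta$spatial$vars[2]]])
    for (i in seq_len(ncol(Bx))) for (j in seq_len(ncol(By))) {
      cols[[paste0("spat_", i, "_", j)]] <- Bx[, i] * By[, j]
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X[, keep, drop = FALSE]
}

drop_aliased <- function(X, label) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    warning("dropping ", length(dropped), " aliased column(s) from the ",
            label, " design: ", paste(dropped, collapse = ", "))
    X <- X[, sort(q$pivot[seq_len(q$rank)]), drop = FALSE]
  }
  X
}

#' Build the fixed-df spline design for the count models
#'
#' Constructs the count-part design (year factor, df-capped spline smooths of
#' the land-cover and topographic covariates, linear aspect terms, and a
#' tensor-product spatial trend) and, optionally, the zero-part design used by
#' the zero-inflated families (spline smooths of landscape covariates measured
#' at a broader buffer). Aliased columns are dropped by pivoted QR with a
#' warning and the reduced column set is recorded so that bootstrap-time
#' prediction uses exactly the fitted design.
#'
#' @param data data frame of survey sites with one row per site-year; must
#'   contain all named covariates and the `year_col` column.
#' @param smooth_terms character vector of covariates given a spline basis
#'   with `df` degrees of freedom each.
#' @param linear_terms character vector of covariates entering linearly
#'   (e.g. aspect sine and cosine).
#' @param spatial length-2 character vector naming the planar coordinates for
#'   the tensor-product spatial smooth, or `NULL` to omit it.
#' @param year_col name of the survey-year column (treatment-coded factor,
#'   first year as reference), or `NULL` to omit the year effect.
#' @param zero_smooth_terms covariates of the zero-inflation linear predictor
#'   (spline bases with `zero_df` df), or `NULL` when no zero part is needed.
#' @param df,spatial_df,zero_df degrees of freedom per smooth (at most 4).
#' @return An object of class `avitrend_design` carrying the count design
#'   matrix `X`, the zero design `Z` (or `NULL`) and the metadata needed to
#'   rebuild both at new covariate values via [design_matrix()].
#' @examples
#' d <- data.frame(year = rep(2000:2004, each = 20), elev = runif(100),
#'                 x = runif(100), y = runif(100))
#' des <- build_design(d, smooth_terms = "elev", spatial = c("x", "y"))
#' ncol(des$X)  # 1 + 4 (year) + 4 (elev) + 9 (spatial)
#' @export
build_design <- function(data, smooth_terms = character(),
                         linear_terms = character(),
                         spatial = NULL, year_col = "year",
                         zero_smooth_terms = NULL,
                         df = 4, spatial_df = 3, zero_df = 4) {
  stopifnot(is.data.frame(data))
  year_levels <- NULL
  if (!is.null(year_col)) {
    year_levels <- sort(unique(data[[year_col]]))
    if (length(year_levels) < 2) stop("need at least 2 distinct survey years")
  }
  count <- build_part(data, smooth_terms, linear_terms, spatial, year_col,
                      df, spatial_df, year_levels)
  X <- drop_aliased(count$X, "count")
  zero <- NULL; Z <- NULL
  if (!is.null(zero_smooth_terms)) {
    zero <- build_part(data, zero_smooth_terms, character(), NULL, NULL,
                       zero_df, spatial_df, NULL)
    Z <- drop_aliased(zero$X, "zero")
  }
  structure(list(
    X = X, Z = Z,
    count_meta = count$meta, zero_meta = if (!is.null(zero)) zero$meta,
    keep_count = colnames(X), keep_zero = if (!is.null(Z)) colnames(Z),
    n = nrow(data)), class = "avitrend_design")
}

#' Evaluate a fitted design at new covariate values
#'
#' @param design an `avitrend_design` from [build_design()].
#' @param newdata data frame with the covariates (and year) of the rows to
#'   predict; years must be levels seen at build time.
#' @param part `"count"` or `"zero"`.
#' @return numeric matrix with the columns retained at build time.
#' @export
design_matrix <- function(design, newdata, part = c("count", "zero")) {
  part <- match.arg(part)
  if (part == "zero") {
    if (is.null(design$Z)) stop("design has no zero part")
    eval_part(design$zero_meta, design$keep_zero, newdata)
  } else {
    eval_part(design$count_meta, design$keep_count, newdata)
  }
}

#' @export
print.avitrend_design <- function(x, ...) {
  cat("avitrend design:", x$n, "rows;", ncol(x$X), "count columns",
      if (!is.null(x$Z)) paste0("; ", ncol(x$Z), " zero columns"), "\n")
  invisible(x)
}
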