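# Candidate count regressions: Poisson (P), negative binomial NB2 (NB),
# zero-inflated Poisson (ZIP) and zero-inflated negative binomial (ZINB),
# all with log link on the count mean and, for the ZI families, logit link
# on the structural-zero probability. P is fitted by IRLS (stats::glm.fit),
# NB by MASS::glm.nb, and the ZI families by direct maximization of the
# mixture log-likelihood with analytic gradients; the coefficient covariance
# is the inverse observed information at the optimum.

FAMILY_RANK <- c(P = 1L, NB = 2L, ZIP = 3L, ZINB = 4L)

family_label <- function(family) paste0("C-", family, "-GAM")

logspace_add <- function(a, b) pmax(a, b) + log1p(exp(-abs(a - b)))

# mixture log-likelihood contributions; pi = structural-zero probability
zi_loglik_terms <- function(y, eta, zeta, family, log_k = NULL) {
  mu <- exp(eta)
  lp <- plogis(zeta, log.p = TRUE)        # log pi
  l1mp <- plogis(-zeta, log.p = TRUE)     # log(1 - pi)
  out <- numeric(length(y))
  z0 <- y == 0
  if (family == "ZIP") {
    lf0 <- -mu
    lpos <- -mu + y * eta - lgamma(y + 1)
  } else {
    k <- exp(log_k)
    lf0 <- k * (log_k - log(k + mu))
    lpos <- lgamma(y + k) - lgamma(k) - lgamma(y + 1) +
      k * (log_k - log(k + mu)) + y * (eta - log(k + mu))
  }
  out[z0] <- logspace_add(lp[z0], l1mp[z0] + lf0[z0])
  out[!z0] <- l1mp[!z0] + lpos[!z0]
  out
}

make_zi_objective <- function(y, X, Z, family) {
  p <- ncol(X); q <- ncol(Z)
  has_k <- family == "ZINB"
  split_par <- function(par) {
    list(beta = par[seq_len(p)], gamma = par[p + seq_len(q)],
         log_k = if (has_k) par[p + q + 1L])
  }
  negll <- function(par) {
    pr <- split_par(par)
    eta <- drop(X %*% pr$beta); zeta <- drop(Z %*% pr$gamma)
    if (any(!is.finite(eta)) || any(eta > 40) || (has_k && abs(pr$log_k) > 30)) {
      return(1e10)
    }
    ll <- sum(zi_loglik_terms(y, eta, zeta, family, pr$log_k))
    if (!is.finite(ll)) 1e10 else -ll
  }
  grad <- function(par) {
    pr <- split_par(par)
    eta <- drop(X %*% pr$beta); zeta <- drop(Z %*% pr$gamma)
    eta <- pmin(eta, 40)
    mu <- exp(eta)
    lp <- plogis(zeta, log.p = TRUE); l1mp <- plogis(-zeta, log.p = TRUE)
    pi_ <- plogis(zeta)
    z0 <- y == 0
    de <- dz <- numeric(length(y))
    if (family == "ZIP") {
      ll0 <- logspace_add(lp, l1mp - mu)
      de[z0] <- -exp(l1mp[z0] - mu[z0] + eta[z0] - ll0[z0])
      dz[z0] <- exp(lp[z0] + l1mp[z0] + log(-expm1(-mu[z0])) - ll0[z0])
      de[!z0] <- y[!z0] - mu[!z0]
      dz[!z0] <- -pi_[!z0]
      dk <- NULL
    } else {
      k <- exp(pr$log_k)
      lf0 <- k * (pr$log_k - log(k + mu))
      ll0 <- logspace_add(lp, l1mp + lf0)
      de[z0] <- -exp(l1mp[z0] + lf0[z0] + pr$log_k + eta[z0] -
                       log(k + mu[z0]) - ll0[z0])
      dz[z0] <- exp(lp[z0] + l1mp[z0] + log(-expm1(lf0[z0])) - ll0[z0])
      de[!z0] <- y[!z0] - (y[!z0] + k) * mu[!z0] / (k + mu[!z0])
      dz[!z0] <- -pi_[!z0]
      dk_i <- numeric(length(y))
      dk_i[z0] <- exp(l1mp[z0] + lf0[z0] - ll0[z0]) * k *
        (pr$log_k - log(k + mu[z0]) + mu[z0] / (k + mu[z0]))
      dk_i[!z0] <- k * (digamma(y[!z0] + k) - digamma(k) + pr$log_k + 1 -
                          log(k + mu[!z0]) - (y[!z0] + k) / (k + mu[!z0]))
      dk <- sum(dk_i)
    }
    g <- c(drop(crossprod(X, de)), drop(crossprod(Z, dz)), dk)
    if (any(!is.finite(g))) g[!is.finite(g)] <- 0
    -g
  }
  list(negll = negll, grad = grad, split_par = split_par)
}

new_count_fit <- function(family, coef, idx, vcov, loglik, npar, converged,
                          mu, pi, k, y, design, message = NULL) {
  structure(list(
    family = family, label = family_label(family), coef = coef, idx = idx,
    vcov = vcov, loglik = loglik, aic = -2 * loglik + 2 * npar, npar = npar,
    converged = converged, mu = mu, pi = pi, k = k, y = y, design = design,
    message = message), class = "avitrend_fit")
}

#' Fit one candidate count model by maximum likelihood
#'
#' Fits the requested family on the count design of `design` (and, for the
#' zero-inflated families, the logit zero part on the zero design). The
#' returned object carries the full coefficient vector, the inverse
#' observed-information covariance, the log-likelihood (including all
#' normalizing constants, so likelihoods are comparable across families),
#' the AIC with one parameter counted per estimated coefficient plus one for
#' the NB/ZINB dispersion, and the explained deviance per model component.
#'
#' The zero-inflated fits are initialized from the corresponding non-inflated
#' fit plus a zero-part intercept matched to the empirical excess-zero
#' fraction, then maximized by BFGS with analytic gradients (relative
#' log-likelihood tolerance 1e-10, at most 500 iterations). Non-convergence
#' or a non-invertible information matrix flags the fit, which
#' [select_best_model()] then excludes.
#'
#' @param design an [build_design()] object; a zero part is required for the
#'   ZIP/ZINB families.
#' @param y vector of non-negative integer counts (breeding pairs), one per
#'   design row.
#' @param family one of `"P"`, `"NB"`, `"ZIP"`, `"ZINB"`.
#' @return An object of class `avitrend_fit`.
#' @seealso [fit_count_models()], [select_best_model()], [explained_deviance()]
#' @export
fit_count_model <- function(design, y, family = c("P", "NB", "ZIP", "ZINB")) {
  family <- match.arg(family)
  stopifnot(inherits(design, "avitrend_design"))
  if (length(y) != design$n) stop("length(y) must match the design rows")
  if (any(y < 0) || any(y != round(y))) stop("`y` must be non-negative integers")
  X <- design$X
  p <- ncol(X)
  idx <- list(count = seq_len(p))

  if (family == "P") {
    fit <- suppressWarnings(glm.fit(x = X, y = y, family = poisson(),
                                    control = list(epsilon = 1e-12,
                                                   maxit = 100)))
    beta <- coef(fit); mu <- fit$fitted.values
    ll <- sum(dpois(y, mu, log = TRUE))
    V <- tryCatch(chol2inv(chol(crossprod(X * sqrt(mu)))), error = function(e) NULL)
    conv <- isTRUE(fit$converged) && !is.null(V)
    if (!is.null(V)) dimnames(V) <- list(names(beta), names(beta))
    return(new_count_fit("P", beta, idx, V, ll, p, conv, mu, NULL, NULL, y, design))
  }

  if (family == "NB") {
    nb <- tryCatch(suppressWarnings(MASS::glm.nb(y ~ X - 1)),
                   error = function(e) e)
    if (inherits(nb, "error")) {
      return(new_count_fit("NB", setNames(rep(NA_real_, p), colnames(X)), idx,
                           NULL, -Inf, p + 1, FALSE, NULL, NULL, NULL, y,
                           design, message = conditionMessage(nb)))
    }
    beta <- setNames(coef(nb), colnames(X))
    V <- vcov(nb)  # conditional on the dispersion, fixed at its MLE downstream
    dimnames(V) <- list(colnames(X), colnames(X))
    return(new_count_fit("NB", beta, idx, V, as.numeric(logLik(nb)), p + 1,
                         TRUE, fitted(nb), NULL, nb$theta, y, design))
  }

  # zero-inflated families
  if (is.null(design$Z)) stop(family, " requires a zero-part design")
  Z <- design$Z
  q <- ncol(Z)
  idx$zero <- p + seq_len(q)
  base <- fit_count_model(design, y, if (family == "ZIP") "P" else "NB")
  beta0 <- base$coef
  if (any(!is.finite(beta0))) {
    beta0 <- c(log(mean(y) + 0.01), rep(0, p - 1))
  }
  f0 <- if (family == "ZIP") exp(-pmax(base$mu, 1e-8)) else {
    k0 <- base$k
    (k0 / (k0 + base$mu))^k0
  }
  excess <- (mean(y == 0) - mean(f0)) / max(1 - mean(f0), 1e-8)
  g0 <- qlogis(min(max(excess, 0.02), 0.90))
  par0 <- c(beta0, g0, rep(0, q - 1))
  if (family == "ZINB") {
    idx$disp <- p + q + 1L
    par0 <- c(par0, log(max(base$k, 0.05)))
  }
  obj <- make_zi_objective(y, X, Z, family)
  opt <- optim(par0, obj$negll, obj$grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  par <- opt$par
  nms <- c(colnames(X), paste0("zero_", colnames(Z)),
           if (family == "ZINB") "log_k")
  names(par) <- nms
  H <- tryCatch(optimHess(par, obj$negll, obj$grad), error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
  conv <- opt$convergence == 0 && !is.null(V) && all(diag(V) > 0)
  if (!is.null(V)) {
    V <- (V + t(V)) / 2
    dimnames(V) <- list(nms, nms)
  }
  pr <- obj$split_par(par)
  mu <- exp(pmin(drop(X %*% pr$beta), 40))
  pi_ <- plogis(drop(Z %*% pr$gamma))
  new_count_fit(family, par, idx, V, -opt$value, length(par), conv,
                mu, pi_, if (family == "ZINB") exp(pr$log_k), y, design)
}

#' Fit all candidate families on one species
#'
#' @inheritParams fit_count_model
#' @param families families to attempt; ZI families are skipped with a
#'   warning when the design has no zero part.
#' @return named list of `avitrend_fit` objects.
#' @export
fit_count_models <- function(design, y, families = c("P", "NB", "ZIP", "ZINB")) {
  families <- match.arg(families, c("P", "NB", "ZIP", "ZINB"), several.ok = TRUE)
  if (is.null(design$Z) && any(families %in% c("ZIP", "ZINB"))) {
    warning("no zero-part design; skipping ZIP/ZINB")
    families <- setdiff(families, c("ZIP", "ZINB"))
  }
  fits <- lapply(families, function(f) {
    tryCatch(fit_count_model(design, y, f), error = function(e) {
      warning("fit of family ", f, " failed: ", conditionMessage(e))
      NULL
    })
  })
  setNames(Filter(Negate(is.null), fits),
           families[!vapply(fits, is.null, logical(1))])
}

#' Select the best candidate model by AIC
#'
#' Returns the converged fit with the smallest AIC. Exact ties are broken in
#' favor of the simpler family, in the order P < NB < ZIP < ZINB.
#'
#' @param fits list of `avitrend_fit` objects (one per family).
#' @return the selected `avitrend_fit`.
#' @export
select_best_model <- function(fits) {
  fits <- Filter(function(f) inherits(f, "avitrend_fit") && isTRUE(f$converged),
                 fits)
  if (!length(fits)) stop("no converged candidate model to select from")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  rank <- FAMILY_RANK[vapply(fits, `[[`, character(1), "family")]
  ord <- order(aic, rank)
  best <- ord[1]
  # exact ties go to the simpler family
  tied <- which(aic == aic[best])
  if (length(tied) > 1) best <- tied[which.min(rank[tied])]
  fits[[best]]
}

poisson_unit_dev <- function(y, mu) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  2 * (t1 - (y - mu))
}

nb_unit_dev <- function(y, mu, k) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  2 * (t1 - (y + k) * log((y + k) / (mu + k)))
}

binom_dev <- function(z, p) {
  xlogy <- function(a, b) ifelse(a > 0, a * log(b), 0)
  model <- -2 * sum(xlogy(z, p) + xlogy(1 - z, 1 - p))
  sat <- -2 * sum(xlogy(z, z) + xlogy(1 - z, 1 - z))
  model - sat
}

#' Explained deviance of a fitted count model
#'
#' For the non-inflated families this is the usual 1 - D_model/D_null with the
#' family deviance and an intercept-only null (the NB dispersion of the fitted
#' model is used in both). For the zero-inflated families the two components
#' are assessed on the complete-data scale: each zero observation is given its
#' posterior structural-zero probability under the fitted mixture, the count
#' component is the posterior-weighted family deviance against a weighted
#' intercept-only null, and the zero component is the binomial deviance of the
#' fitted zero probabilities against the posterior indicators, relative to an
#' intercept-only zero part.
#'
#' @param fit an `avitrend_fit`.
#' @return named numeric vector: `count`, plus `zero` for ZI families.
#'   A degenerate null deviance yields `NA` for that component.
#' @export
explained_deviance <- function(fit) {
  stopifnot(inherits(fit, "avitrend_fit"))
  y <- fit$y; mu <- fit$mu
  if (fit$family %in% c("P", "NB")) {
    mu0 <- mean(y)
    if (fit$family == "P") {
      d <- sum(poisson_unit_dev(y, mu)); d0 <- sum(poisson_unit_dev(y, mu0))
    } else {
      d <- sum(nb_unit_dev(y, mu, fit$k)); d0 <- sum(nb_unit_dev(y, mu0, fit$k))
    }
    return(c(count = if (d0 <= 0) NA_real_ else 1 - d / d0))
  }
  pi_ <- fit$pi
  f0 <- if (fit$family == "ZIP") exp(-mu) else (fit$k / (fit$k + mu))^fit$k
  z <- ifelse(y == 0, pi_ * 1 / (pi_ + (1 - pi_) * f0), 0)
  w <- 1 - z
  mu0 <- sum(w * y) / sum(w)
  if (fit$family == "ZIP") {
    d <- sum(w * poisson_unit_dev(y, mu)); d0 <- sum(w * poisson_unit_dev(y, mu0))
  } else {
    d <- sum(w * nb_unit_dev(y, mu, fit$k)); d0 <- sum(w * nb_unit_dev(y, mu0, fit$k))
  }
  dz <- binom_dev(z, pi_); dz0 <- binom_dev(z, mean(z))
  c(count = if (d0 <= 0) NA_real_ else 1 - d / d0,
    zero = if (dz0 <= 0) NA_real_ else 1 - dz / dz0)
}

#' @export
print.avitrend_fit <- function(x, ...) {
  cat(x$label, "fit:", x$npar, "parameters, logLik", format(x$loglik),
      ", AIC", format(x$aic),
      if (!x$converged) "(NOT converged)", "\n")
  invisible(x)
}
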