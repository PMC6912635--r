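#' Random-intercept linear mixed model by profile likelihood
#'
#' Fits the two-level Gaussian model
#' `y = X beta + u[group] + e`, `u ~ N(0, sigma2_u)`, `e ~ N(0, sigma2)`,
#' the model used for free-running-period analyses with isofemale line
#' (nested in location, encoded as line-unique labels) as the random
#' effect. Estimation profiles the likelihood over the variance ratio
#' `lambda = sigma2_u / sigma2`: for each ratio the fixed effects are the
#' GLS solution and `sigma2` has a closed form, leaving a one-dimensional
#' optimisation. The default `method = "ML"` makes likelihood-ratio tests
#' on fixed effects valid; `"REML"` is offered for variance reporting.
#'
#' @param formula fixed-effects formula, e.g. `tau_hat ~ latitude`
#' @param data data.frame holding the variables
#' @param groups grouping labels: a vector of length `nrow(data)` or the
#'   name of a column of `data`
#' @param method `"ML"` (default) or `"REML"`
#' @return an object of class `ri_lmm`
#' @export
fit_random_intercept <- function(formula, data, groups,
                                 method = c("ML", "REML")) {
  method <- match.arg(method)
  if (is.character(groups) && length(groups) == 1L) {
    group_name <- groups
    groups <- data[[groups]]
    if (is.null(groups)) stop("no column '", group_name, "' in data")
  } else group_name <- deparse(substitute(groups))
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  keep <- as.integer(rownames(mf))
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  g <- factor(groups[keep])
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design matrix is singular")
  if (nlevels(g) < 2) {
    warning("only one group: model reduces to ordinary least squares")
    return(.ri_fit(y, X, g, lambda = 0, method, formula, group_name,
                   force_ols = TRUE))
  }
  nll <- function(s) -.ri_profile_ll(y, X, g, exp(s), method)
  opt <- stats::optimize(nll, interval = c(-15, 8))
  lam <- exp(opt$minimum)
  if (-opt$objective < .ri_profile_ll(y, X, g, 0, method)) lam <- 0
  .ri_fit(y, X, g, lam, method, formula, group_name)
}

# sufficient statistics of the GLS problem at ratio lambda
.ri_gls <- function(y, X, g, lambda) {
  gi <- split(seq_along(y), g)
  n_j <- lengths(gi)
  c_j <- lambda / (1 + lambda * n_j)
  S <- t(vapply(gi, function(i) colSums(X[i, , drop = FALSE]),
                numeric(ncol(X))))          # groups x p
  if (ncol(X) == 1L) S <- matrix(S, ncol = 1L)
  t_j <- vapply(gi, function(i) sum(y[i]), numeric(1))
  A <- crossprod(X) - crossprod(S * sqrt(c_j))
  b <- crossprod(X, y) - colSums(S * (c_j * t_j))
  beta <- solve(A, b)
  rssv <- sum(y^2) - sum(c_j * t_j^2) - sum(beta * b)
  list(A = A, beta = drop(beta), rssv = max(rssv, 1e-300),
       logdetV = sum(log(1 + lambda * n_j)), n_j = n_j, c_j = c_j, gi = gi)
}

.ri_profile_ll <- function(y, X, g, lambda, method) {
  n <- length(y); p <- ncol(X)
  gls <- .ri_gls(y, X, g, lambda)
  if (method == "ML") {
    s2 <- gls$rssv / n
    -0.5 * (n * log(2 * pi * s2) + gls$logdetV + n)
  } else {
    s2 <- gls$rssv / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + gls$logdetV +
              determinant(gls$A, logarithm = TRUE)$modulus + (n - p))
  }
}

.ri_fit <- function(y, X, g, lambda, method, formula, group_name,
                    force_ols = FALSE) {
  n <- length(y); p <- ncol(X)
  gls <- .ri_gls(y, X, g, lambda)
  s2 <- if (method == "ML") gls$rssv / n else gls$rssv / (n - p)
  vc <- s2 * solve(gls$A)
  se <- sqrt(diag(vc))
  names(se) <- rownames(vc)
  fitted_fx <- unname(drop(X %*% gls$beta))
  resid_m <- unname(y - fitted_fx)
  # BLUPs: shrunken group means of marginal residuals
  u <- vapply(gls$gi, function(i) sum(resid_m[i]), numeric(1)) * gls$c_j
  ll <- .ri_profile_ll(y, X, g, lambda, method)
  structure(list(coefficients = stats::setNames(gls$beta, colnames(X)),
                 se = se, vcov = vc, sigma2 = s2,
                 sigma2_u = lambda * s2, lambda = lambda,
                 loglik = as.numeric(ll), n = n, p = p,
                 n_par = p + 2L, n_groups = nlevels(g),
                 formula = formula, group_name = group_name,
                 groups = g, y = y, fitted = fitted_fx,
                 residuals = resid_m, ranef = u, method = method,
                 force_ols = force_ols),
            class = "ri_lmm")
}

#' @export
print.ri_lmm <- function(x, ...) {
  cat("Random-intercept linear mixed model (", x$method,
      ", profile likelihood)\n", sep = "")
  cat("  ", deparse(x$formula), " + (1 | ", x$group_name, ")\n", sep = "")
  cat("  n = ", x$n, ", groups = ", x$n_groups,
      sprintf(", logLik = %.3f\n", x$loglik), sep = "")
  cat(sprintf("  sigma2 (residual) = %.4g, sigma2_u (%s) = %.4g\n",
              x$sigma2, x$group_name, x$sigma2_u))
  cat("  Fixed effects:\n")
  print(round(cbind(Estimate = x$coefficients, `Std.Error` = x$se), 5))
  invisible(x)
}

#' @export
summary.ri_lmm <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std.Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.ri_lmm"
  out
}

#' @export
print.summary.ri_lmm <- function(x, ...) {
  print(x$fit)
  cat("  Wald tests:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.ri_lmm <- function(object, ...) object$coefficients

#' @export
vcov.ri_lmm <- function(object, ...) object$vcov

#' @export
logLik.ri_lmm <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n,
            class = "logLik")
}

#' @export
fitted.ri_lmm <- function(object, ...) object$fitted

#' @export
residuals.ri_lmm <- function(object, level = c("marginal", "conditional"),
                             ...) {
  level <- match.arg(level)
  if (level == "marginal") object$residuals
  else object$residuals - object$ranef[as.character(object$groups)]
}

#' Predict from a random-intercept mixed model
#'
#' @param object an `ri_lmm`
#' @param newdata data.frame of covariates; omitted means the fitted data
#' @param level 0 for population-level (fixed effects only), 1 to add the
#'   group BLUP where the group is known
#' @param groups group labels for `newdata` when `level = 1`
#' @param ... unused
#' @export
predict.ri_lmm <- function(object, newdata = NULL, level = 0,
                           groups = NULL, ...) {
  if (is.null(newdata)) {
    out <- object$fitted
    if (level >= 1) out <- out + object$ranef[as.character(object$groups)]
    return(unname(out))
  }
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                           newdata)
  out <- drop(X %*% object$coefficients)
  if (level >= 1) {
    if (is.null(groups)) groups <- newdata[[object$group_name]]
    u <- object$ranef[as.character(groups)]
    u[is.na(u)] <- 0
    out <- out + u
  }
  unname(out)
}

#' Normal QQ plot of mixed-model residuals
#'
#' Diagnostic for the Gaussian assumption of [fit_random_intercept()].
#'
#' @param x an `ri_lmm`
#' @param ... passed to [stats::qqnorm()]
#' @export
plot.ri_lmm <- function(x, ...) {
  r <- residuals(x, level = "conditional")
  stats::qqnorm(r, main = "Conditional residuals", ...)
  stats::qqline(r)
  invisible(x)
}

#' Likelihood-ratio test between nested mixed models
#'
#' `LRT = 2 (logLik_full - logLik_reduced)`, referred to a chi-square with
#' degrees of freedom equal to the parameter-count difference. Both fits
#' must be ML fits of nested mean structures on identical data.
#'
#' @param full,reduced `ri_lmm` fits (reduced nested in full)
#' @return list with `statistic`, `df`, `p_value`
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "ri_lmm"), inherits(reduced, "ri_lmm"))
  if (full$method != "ML" || reduced$method != "ML")
    stop("likelihood-ratio tests require ML fits")
  if (full$n != reduced$n || !isTRUE(all.equal(full$y, reduced$y)))
    stop("models were not fit to identical data")
  tf <- attr(stats::terms(full$formula), "term.labels")
  tr <- attr(stats::terms(reduced$formula), "term.labels")
  if (!all(tr %in% tf))
    stop("'reduced' is not nested in 'full'")
  df <- full$n_par - reduced$n_par
  if (df < 0) stop("'reduced' has more parameters than 'full'")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Rhythmicity proportions: binomial GLM with analysis of deviance
#'
#' Fits a binomial-logit GLM of the rhythmic/arrhythmic outcome on the
#' requested factors and tests each factor by the deviance chi-square of
#' dropping it from the full model. The factor name `"location"` refers to
#' the `population` column. Complete separation is flagged and the
#' affected tests reported as unreliable.
#'
#' @param table cohort data.frame with a logical `rhythmic` column and the
#'   factor columns
#' @param factors character vector among
#'   `c("location", "latitude", "sex", "mating")`, or other column names
#' @return data.frame (term, chisq, df, p_value, reliable) with the fitted
#'   `glm` attached as attribute `"model"`
#' @export
rhythmicity_glm <- function(table, factors = c("location", "sex", "mating")) {
  cols <- ifelse(factors == "location", "population", factors)
  missing_cols <- setdiff(c("rhythmic", cols), names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  dat <- table[c("rhythmic", cols)]
  dat <- dat[stats::complete.cases(dat), ]
  f <- stats::reformulate(cols, response = "rhythmic")
  fit <- stats::glm(f, family = stats::binomial(), data = dat)
  sep <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8) ||
    any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  if (sep)
    warning("possible complete separation; deviance tests may be unreliable")
  an <- stats::drop1(fit, test = "Chisq")
  out <- data.frame(term = factors,
                    chisq = an$Deviance[-1] - 0,  # deviance increase on drop
                    df = an$Df[-1],
                    p_value = an[["Pr(>Chi)"]][-1],
                    reliable = !sep, stringsAsFactors = FALSE)
  # drop1 reports the LRT deviance directly under "LRT" in some R versions
  if ("LRT" %in% names(an)) out$chisq <- an$LRT[-1]
  attr(out, "model") <- fit
  out
}

#' Regression of free-running period on peak activity phase
#'
#' Tests whether individuals with earlier activity peaks have shorter
#' free-running periods. Peak phase, a circular quantity, is unwrapped to a
#' continuous covariate as the signed deviation from the cohort circular
#' mean before regressing `tau_hat` on it with an isofemale-line random
#' intercept.
#'
#' @param table cohort data.frame with `tau_hat`, `peak` and `line` columns
#' @param method passed to [fit_random_intercept()]
#' @return an `ri_lmm` fit; the unwrapped covariate is named `peak_c`
#' @export
phase_tau_regression <- function(table, method = "ML") {
  need <- c("tau_hat", "peak", "line")
  if (!all(need %in% names(table)))
    stop("missing columns: ", paste(setdiff(need, names(table)),
                                    collapse = ", "))
  dat <- table[stats::complete.cases(table[need]), need]
  if (nrow(dat) < 3) stop("fewer than 3 complete rows")
  dat$peak_c <- circ_diff(dat$peak, circ_mean(dat$peak))
  if (stats::sd(dat$peak_c) == 0)
    stop("peak phase is constant; slope undefined")
  fit_random_intercept(tau_hat ~ peak_c, dat, groups = "line",
                       method = method)
}

#' Latitudinal cline summary of the free-running period
#'
#' Per-population mean tau with standard error, ordered by latitude, plus
#' the latitude slope (h per degree north) from the random-intercept mixed
#' model with line as the grouping factor, restricted to the requested
#' subgroup. Only rhythmic individuals (those with a tau estimate) enter.
#'
#' @param table cohort data.frame with `population`, `latitude`, `line`,
#'   `tau_hat` and any subgroup columns
#' @param subgroup optional named list of column filters, e.g.
#'   `list(sex = "F", mating = "virgin")`
#' @return object of class `cline_summary`: `populations` (data.frame
#'   population, latitude, n, mean_tau, se_tau), `slope`, `slope_se`,
#'   `fit` (the `ri_lmm`)
#' @export
summarize_cline <- function(table, subgroup = NULL) {
  dat <- table
  for (nm in names(subgroup)) dat <- dat[dat[[nm]] == subgroup[[nm]], ]
  dat <- dat[!is.na(dat$tau_hat), ]
  if (nrow(dat) == 0L) stop("subgroup is empty")
  if (length(unique(dat$population)) < 2)
    stop("at least 2 populations are required")
  pops <- do.call(rbind, lapply(split(dat, dat$population), function(d)
    data.frame(population = d$population[1], latitude = d$latitude[1],
               n = nrow(d), mean_tau = mean(d$tau_hat),
               se_tau = stats::sd(d$tau_hat) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)))
  pops <- pops[order(pops$latitude), ]
  rownames(pops) <- NULL
  fit <- fit_random_intercept(tau_hat ~ latitude, dat, groups = "line")
  structure(list(populations = pops,
                 slope = unname(stats::coef(fit)["latitude"]),
                 slope_se = unname(fit$se["latitude"]), fit = fit),
            class = "cline_summary")
}

#' @export
print.cline_summary <- function(x, ...) {
  cat("Free-running period by population (south to north):\n")
  print(transform(x$populations, mean_tau = round(mean_tau, 3),
                  se_tau = round(se_tau, 3)), row.names = FALSE)
  cat(sprintf("Latitude slope: %.4f +/- %.4f h per degree N\n",
              x$slope, x$slope_se))
  invisible(x)
}

#' Assemble the per-individual cohort table
#'
#' Joins periodogram results ([estimate_tau_cohort()]) with per-individual
#' phase markers ([summarize_markers()]'s `per_individual` table, if
#' available). Enforces the convention that `tau_hat` is present only for
#' rhythmic individuals.
#'
#' @param tau data.frame from [estimate_tau_cohort()]
#' @param markers optional `per_individual` data.frame (columns
#'   individual_id, onset, peak, offset)
#' @return data.frame, one row per individual
#' @export
cohort_table <- function(tau, markers = NULL) {
  out <- tau
  out$tau_hat[!out$rhythmic] <- NA_real_
  if (!is.null(markers))
    out <- merge(out, markers[c("individual_id", "onset", "peak", "offset")],
                 by = "individual_id", all.x = TRUE, sort = FALSE)
  out
}
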