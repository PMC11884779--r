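# Mixed models of log substitution rate on pair features: crossed
# random intercepts for the two amino acids of each pair, Satterthwaite
# degrees of freedom, likelihood-ratio model comparison, marginal /
# conditional R-squared, per-step subset fits, and the Welch group tests.

.default_formula <- log_rate ~ PC1 * PC2 + min_steps + pyr_diff

#' Fit a mixed model of log substitution rate
#'
#' Fits a Gaussian linear mixed model of log substitution rate on pair-level
#' covariates with independent random intercepts for each amino-acid slot of
#' the pair (donor and acceptor in directed tables). Estimation is REML by
#' default; coefficient tests use Satterthwaite denominator degrees of
#' freedom. By default the response and all numeric fixed covariates are
#' z-scored before fitting, so estimates are standardized slopes; the scaling
#' is recorded on the object and [predict.rate_lmm()] can map back.
#'
#' @param formula Fixed-effects formula, e.g.
#'   `log_rate ~ PC1 * PC2 + min_steps + pyr_diff` (the default when `NULL`).
#'   Random intercepts are added automatically from `random`.
#' @param data A feature table from [feature_table()] (or any data frame
#'   with the referenced columns plus the `random` factors).
#' @param random Character vector of grouping factors receiving independent
#'   random intercepts; default `c("aa1", "aa2")`, the two pair slots.
#' @param scale Z-score the response and numeric covariates (default `TRUE`).
#' @param REML Use REML (default) or maximum likelihood.
#' @return An object of class `"rate_lmm"`: `coefficients` (a data frame of
#'   term, estimate, se, df, t, p), `varcor` (random-intercept variances),
#'   `sigma2` (residual variance), `loglik`, `aic`, `r2_marginal`,
#'   `r2_conditional`, `boundary` (TRUE when a variance estimate hit zero),
#'   `scaling`, and the underlying `lmerTest` fit in `$fit`.
#' @seealso [compare_models()], [fit_by_steps()], [marginal_r2()]
#' @export
#' @examples
#' sc <- synth_scenario(seed = 1)
#' dat <- synth_features(sc)
#' fit <- rate_lmm(data = dat)
#' summary(fit)
rate_lmm <- function(formula = NULL, data, random = c("aa1", "aa2"),
                     scale = TRUE, REML = TRUE) {
  if (is.null(formula)) formula <- .default_formula
  if (length(random) < 1) stop("need at least one random factor", call. = FALSE)
  miss <- setdiff(random, names(data))
  if (length(miss)) stop("random factor(s) not in data: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (r in random) {
    if (length(unique(data[[r]])) < 2)
      stop("random factor '", r, "' has fewer than 2 levels", call. = FALSE)
  }

  response <- all.vars(formula)[1]
  if (!response %in% names(data)) stop("response '", response, "' not in data",
                                       call. = FALSE)
  if (!all(is.finite(data[[response]])))
    stop("non-finite response values", call. = FALSE)

  vars <- all.vars(formula)
  covars <- setdiff(vars, response)
  miss <- setdiff(covars, names(data))
  if (length(miss)) stop("covariate(s) not in data: ",
                         paste(miss, collapse = ", "), call. = FALSE)

  dat <- as.data.frame(data)[, union(vars, random), drop = FALSE]
  scaling <- NULL
  if (scale) {
    scaled_vars <- c(response, covars[vapply(covars, function(v)
      is.numeric(dat[[v]]), logical(1))])
    ctr <- vapply(scaled_vars, function(v) mean(dat[[v]]), numeric(1))
    scl <- vapply(scaled_vars, function(v) sd(dat[[v]]), numeric(1))
    if (any(scl == 0))
      stop("constant variable(s) cannot be scaled: ",
           paste(scaled_vars[scl == 0], collapse = ", "), call. = FALSE)
    for (v in scaled_vars) dat[[v]] <- (dat[[v]] - ctr[v]) / scl[v]
    scaling <- list(center = ctr, scale = scl)
  }

  # check the fixed design for aliasing before lme4 silently drops columns
  X0 <- model.matrix(formula[-2], dat)
  qx <- qr(X0)
  if (qx$rank < ncol(X0))
    stop("rank-deficient fixed-effect design; aliased term(s): ",
         paste(colnames(X0)[qx$pivot[seq(qx$rank + 1, ncol(X0))]],
               collapse = ", "), call. = FALSE)

  lmm_formula <- as.formula(paste(
    deparse(formula, width.cutoff = 500),
    paste(sprintf("(1 | %s)", random), collapse = " + "), sep = " + "))

  warns <- character(0)
  fit <- withCallingHandlers(
    lmerTest::lmer(lmm_formula, data = dat, REML = REML,
                   control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  X <- model.matrix(fit)
  smry <- summary(fit)
  ct <- as.data.frame(smry$coefficients)
  coefs <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                      se = ct[, "Std. Error"], df = ct[, "df"],
                      t = ct[, "t value"], p = ct[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_u <- setNames(vc$vcov[vc$grp != "Residual"], vc$grp[vc$grp != "Residual"])
  sigma2 <- vc$vcov[vc$grp == "Residual"]

  var_fixed <- var(as.vector(X %*% lme4::fixef(fit)))
  tot <- var_fixed + sum(var_u) + sigma2
  ll <- logLik(fit)

  out <- structure(list(
    coefficients = coefs,
    varcor = var_u,
    sigma2 = sigma2,
    loglik = as.numeric(ll),
    aic = AIC(fit),
    n_params = attr(ll, "df"),
    r2_marginal = var_fixed / tot,
    r2_conditional = (var_fixed + sum(var_u)) / tot,
    boundary = lme4::isSingular(fit),
    warnings = warns,
    scaling = scaling,
    formula = formula,
    random = random,
    REML = REML,
    n = nrow(dat),
    data = dat,
    fit = fit,
    call = match.call()
  ), class = "rate_lmm")
  out
}

#' @export
print.rate_lmm <- function(x, ...) {
  cat("Linear mixed model of", deparse(x$formula[[2]]),
      if (x$REML) "(REML)" else "(ML)", "\n")
  cat("  n =", x$n, "; random intercepts:", paste(x$random, collapse = ", "), "\n")
  est <- setNames(x$coefficients$estimate, x$coefficients$term)
  print(round(est, 4))
  cat("  marginal R2 =", round(x$r2_marginal, 3),
      "; conditional R2 =", round(x$r2_conditional, 3), "\n")
  if (x$boundary) cat("  note: variance estimate at boundary (singular fit)\n")
  invisible(x)
}

#' @export
summary.rate_lmm <- function(object, ...) {
  structure(list(
    formula = object$formula, REML = object$REML, n = object$n,
    coefficients = object$coefficients, varcor = object$varcor,
    sigma2 = object$sigma2, loglik = object$loglik, aic = object$aic,
    r2_marginal = object$r2_marginal, r2_conditional = object$r2_conditional,
    boundary = object$boundary, scaling = !is.null(object$scaling)
  ), class = "summary.rate_lmm")
}

#' @export
print.summary.rate_lmm <- function(x, ...) {
  cat("Linear mixed model of", deparse(x$formula[[2]]),
      if (x$REML) "(REML" else "(ML", ", n =", x$n,
      if (x$scaling) ", standardized)" else ")", "\n\nFixed effects:\n")
  tab <- x$coefficients
  # floor tiny p-values only in display
  pshow <- ifelse(tab$p < 2e-16, "<2.0E-16", format(signif(tab$p, 3)))
  out <- data.frame(Estimate = round(tab$estimate, 4), SE = round(tab$se, 4),
                    df = round(tab$df, 2), t = round(tab$t, 2), P = pshow,
                    row.names = tab$term)
  print(out)
  cat("\nRandom-intercept variances:\n")
  print(round(c(x$varcor, residual = x$sigma2), 5))
  cat("\nlogLik =", round(x$loglik, 2), "; AIC =", round(x$aic, 2),
      "; marginal R2 =", round(x$r2_marginal, 3),
      "; conditional R2 =", round(x$r2_conditional, 3), "\n")
  if (x$boundary) cat("Note: a variance estimate is at the zero boundary.\n")
  invisible(x)
}

#' @export
coef.rate_lmm <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.rate_lmm <- function(object, ...) logLik(object$fit)

#' @export
fitted.rate_lmm <- function(object, ...) fitted(object$fit)

#' @export
residuals.rate_lmm <- function(object, ...) residuals(object$fit)

#' Predict from a rate mixed model
#'
#' @param object A [rate_lmm()] fit.
#' @param newdata Optional data frame on the raw covariate scale; internal
#'   z-scoring is re-applied from the stored scaling.
#' @param re.form Random-effects specification passed to
#'   [lme4::predict.merMod()]; `NA` (default) uses fixed effects only.
#' @param rescale Return predictions on the raw response scale (default);
#'   `FALSE` leaves them on the internal standardized scale.
#' @param ... Unused.
#' @return Numeric vector of predicted (log) rates.
#' @export
predict.rate_lmm <- function(object, newdata = NULL, re.form = NA,
                             rescale = TRUE, ...) {
  resp <- all.vars(object$formula)[1]
  if (is.null(newdata)) {
    p <- predict(object$fit, re.form = re.form)
  } else {
    nd <- as.data.frame(newdata)
    if (!is.null(object$scaling)) {
      sv <- setdiff(names(object$scaling$center), resp)
      for (v in sv) {
        if (!v %in% names(nd)) stop("newdata lacks covariate '", v, "'", call. = FALSE)
        nd[[v]] <- (nd[[v]] - object$scaling$center[v]) / object$scaling$scale[v]
      }
    }
    p <- predict(object$fit, newdata = nd, re.form = re.form,
                 allow.new.levels = TRUE)
  }
  if (rescale && !is.null(object$scaling))
    p <- p * object$scaling$scale[resp] + object$scaling$center[resp]
  unname(p)
}

#' Simulate responses from a fitted rate model
#'
#' Draws new response vectors from the fitted model (new random intercepts
#' and residuals), on the internal (standardized, if scaled) response scale.
#'
#' @param object A [rate_lmm()] fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Passed to [lme4::simulate.merMod()].
#' @return A data frame with `nsim` columns.
#' @export
simulate.rate_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$fit, nsim = nsim, seed = seed,
           re.form = NA, allow.new.levels = TRUE, ...)
}

#' Plot a fitted rate model
#'
#' Residuals-versus-fitted on the internal scale, the standard first look at
#' a Gaussian mixed-model fit.
#'
#' @param x A `rate_lmm` object.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.rate_lmm <- function(x, ...) {
  plot(fitted(x$fit), residuals(x$fit), xlab = "fitted", ylab = "residual",
       pch = 16, col = "grey40", ...)
  abline(h = 0, lty = 2)
  invisible(x)
}

#' Marginal and conditional R-squared
#'
#' Variance decomposition of a fitted mixed model: the marginal R-squared is
#' the variance of the fixed-effect predictions divided by the sum of
#' fixed-effect, random-intercept and residual variances; the conditional
#' variant adds the random-intercept variance to the numerator.
#'
#' @param fit A [rate_lmm()] fit.
#' @param conditional Return the conditional variant.
#' @return A fraction in `[0, 1]`.
#' @export
marginal_r2 <- function(fit, conditional = FALSE) {
  stopifnot(inherits(fit, "rate_lmm"))
  if (conditional) fit$r2_conditional else fit$r2_marginal
}

#' Likelihood-ratio comparison of nested fits
#'
#' Compares two fits of nested fixed-effect specifications on the same data
#' by a likelihood-ratio chi-squared test. REML fits are refitted by maximum
#' likelihood first (fixed-effect comparisons are not valid under REML).
#'
#' @param full,reduced [rate_lmm()] fits; `reduced`'s fixed terms must be a
#'   subset of `full`'s.
#' @return A list with `chi2`, `df`, `p`, `delta_aic`
#'   (`aic_reduced - aic_full`, ML scale; positive favors the full model),
#'   and the two ML log-likelihoods.
#' @export
compare_models <- function(full, reduced) {
  stopifnot(inherits(full, "rate_lmm"), inherits(reduced, "rate_lmm"))
  if (full$n != reduced$n)
    stop("models were fitted to different numbers of observations", call. = FALSE)
  tf <- colnames(model.matrix(full$fit))
  tr <- colnames(model.matrix(reduced$fit))
  if (!all(tr %in% tf))
    stop("models are not nested: reduced has term(s) ",
         paste(setdiff(tr, tf), collapse = ", "), " absent from full",
         call. = FALSE)
  mf <- if (full$REML) lme4::refitML(full$fit) else full$fit
  mr <- if (reduced$REML) lme4::refitML(reduced$fit) else reduced$fit
  llf <- as.numeric(logLik(mf)); llr <- as.numeric(logLik(mr))
  df <- length(tf) - length(tr)
  chi2 <- max(0, 2 * (llf - llr))
  list(chi2 = chi2, df = df,
       p = if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE),
       delta_aic = AIC(mr) - AIC(mf),
       loglik_full = llf, loglik_reduced = llr)
}

#' Fit within one mutational-step class
#'
#' Refits the model on the subset of pairs separated by exactly
#' `step` minimum mutational steps. The formula must not contain
#' `min_steps` (constant within a class).
#'
#' @param data Feature table (must contain `min_steps`).
#' @param step Step class: 1, 2 or 3.
#' @param formula Fixed-effects formula; defaults to
#'   `log_rate ~ PC1 * PC2 + pyr_diff`.
#' @param ... Passed to [rate_lmm()].
#' @return A [rate_lmm()] fit on the subset.
#' @export
fit_by_steps <- function(data, step, formula = log_rate ~ PC1 * PC2 + pyr_diff,
                         ...) {
  stopifnot(step %in% 1:3)
  if ("min_steps" %in% all.vars(formula))
    stop("formula must not contain min_steps (constant within a step class)",
         call. = FALSE)
  sub <- data[data$min_steps == step, , drop = FALSE]
  if (nrow(sub) == 0) stop("no pairs with min_steps = ", step, call. = FALSE)
  rate_lmm(formula, sub, ...)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' One-way comparison of group means without assuming equal variances
#' (Welch 1951), as implemented by [stats::oneway.test()].
#'
#' @param values Numeric vector.
#' @param groups Group labels (coerced to factor).
#' @return A list with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  n <- tapply(values, groups, length)
  v <- tapply(values, groups, var)
  if (any(n < 2)) stop("every group needs at least 2 observations", call. = FALSE)
  if (any(v == 0)) stop("zero within-group variance in group(s): ",
                        paste(levels(groups)[v == 0], collapse = ", "),
                        call. = FALSE)
  ht <- oneway.test(values ~ groups, var.equal = FALSE)
  list(F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]), p = ht$p.value)
}

#' Welch's two-sample t-test
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom, as implemented by [stats::t.test()].
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return A list with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (sd(x) == 0 && sd(y) == 0) stop("both samples are constant", call. = FALSE)
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_x = mean(x), mean_y = mean(y))
}
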