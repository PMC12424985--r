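#' Additive mixed model for body temperature over scaled age
#'
#' Penalized-spline model of body temperature: parametric sex and strain
#' (strain as a fixed effect so its terms can be tested), optional diet,
#' cubic B-spline smooths with second-difference penalties (P-splines,
#' basis dimension 10) for proportion of life lived and 6-month body
#' weight, smoothing parameters chosen by REML, and a per-mouse random
#' intercept for the repeated measures. Fitting is delegated to `mgcv`.
#'
#' @param data data frame with `value` (temperature), `pll`, `bw6mo`,
#'   `sex`, `strain`, `mouse_id`, and `diet` if modelled.
#' @param include_diet add a parametric diet effect.
#' @param k basis dimension for each smooth (reduced with a warning when it
#'   exceeds the number of distinct covariate values).
#' @return An object of class `temp_gamm`: the `mgcv::gam` model, deviance,
#'   per-smooth effective degrees of freedom, and `n`.
#' @export
fit_temp_gamm <- function(data, include_diet = FALSE, k = 10) {
  need <- c("value", "pll", "bw6mo", "sex", "strain", "mouse_id")
  stopifnot(all(need %in% names(data)))
  d <- data[complete.cases(data[, need]), , drop = FALSE]
  if (nrow(d) < 100) stop("need n >= 100 observations")
  d$mouse_id <- factor(d$mouse_id)
  d$strain <- factor(d$strain)
  d$sex <- factor(d$sex)
  k_pll <- min(k, length(unique(d$pll)) - 1)
  k_bw <- min(k, length(unique(d$bw6mo)) - 1)
  if (k_pll < k || k_bw < k)
    warning("basis dimension reduced to match distinct covariate values")
  fixed <- "sex + strain"
  if (include_diet) fixed <- paste(fixed, "+ diet")
  fm <- as.formula(sprintf(
    "value ~ %s + s(pll, bs = 'ps', k = %d, m = c(2, 2)) + s(bw6mo, bs = 'ps', k = %d, m = c(2, 2)) + s(mouse_id, bs = 're')",
    fixed, k_pll, k_bw))
  model <- mgcv::gam(fm, data = d, method = "REML")
  ## ML companion fit for nested fixed-effect comparisons: REML scores are
  ## not comparable across different parametric structures
  model_ml <- mgcv::gam(fm, data = d, method = "ML")
  edf <- setNames(vapply(model$smooth, function(s)
    sum(model$edf[s$first.para:s$last.para]), numeric(1)),
    vapply(model$smooth, function(s) s$label, character(1)))
  structure(list(model = model, deviance = deviance(model),
                 scale = model$sig2, edf = edf,
                 ## marginal ML score with smooth/random coefficients
                 ## integrated out and parametric terms maximized
                 ml_loglik = -as.numeric(model_ml$gcv.ubre),
                 include_diet = include_diet, n = nrow(d)),
            class = "temp_gamm")
}

#' @export
print.temp_gamm <- function(x, ...) {
  cat("<temp_gamm> n = ", x$n, ", deviance = ",
      format(x$deviance, digits = 6),
      if (x$include_diet) ", with diet" else ", no diet", "\n", sep = "")
  cat("  edf:", paste(sprintf("%s %.2f", names(x$edf), x$edf),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Nested analysis-of-deviance comparison
#'
#' Chi-square test comparing two nested additive fits (e.g. with and without
#' the diet term), with degrees of freedom equal to the number of added
#' parametric coefficients. The deviance difference is measured on the
#' maximum-likelihood scale (twice the ML log-likelihood gap from each fit's
#' ML companion): the residual sum of squares alone has no power against
#' between-mouse terms, because the per-mouse random intercepts absorb them,
#' and REML scores are not comparable across parametric structures. Used to
#' decide whether diet belongs in the temperature model.
#'
#' @param full,reduced two `temp_gamm` fits on the same data, `reduced`
#'   nested in `full`.
#' @return Data frame `statistic`, `df`, `p`.
#' @export
compare_deviance <- function(full, reduced) {
  stopifnot(inherits(full, "temp_gamm"), inherits(reduced, "temp_gamm"))
  if (full$n != reduced$n) stop("fits use different data")
  df <- full$model$nsdf - reduced$model$nsdf
  if (df < 0) stop("'full' has fewer parametric terms than 'reduced'")
  stat <- max(0, 2 * (full$ml_loglik - reduced$ml_loglik))
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  if (stat == 0) p <- 1
  data.frame(statistic = stat, df = df, p = p)
}

#' Locate a late-life inflection in a PLL trajectory
#'
#' Fits a continuous broken-stick (two connected line segments) by least
#' squares over a grid of candidate knots and returns the knot minimizing
#' the residual sum of squares — the late-life transition point, e.g. the
#' onset of terminal thermoregulatory decline around 80% of life lived. If
#' the best broken stick does not improve on a single line beyond the
#' F-test tolerance, a "no inflection" result is returned rather than an
#' arbitrary knot.
#'
#' @param pll proportion-of-life-lived values (needs >= 10 distinct values).
#' @param value measurements (e.g. temperature).
#' @param knots candidate knot grid (default 0.50 to 0.95 by 0.01).
#' @param alpha significance level for the improvement F-test (default
#'   0.05).
#' @return An object of class `inflection_estimate`: `pll_star` (NA when no
#'   inflection), `slope_pre`, `slope_post`, `rss`, `rss_line`,
#'   `improvement_p`, `no_inflection`.
#' @export
locate_inflection <- function(pll, value, knots = seq(0.5, 0.95, by = 0.01),
                              alpha = 0.05) {
  ok <- !is.na(pll) & !is.na(value)
  pll <- pll[ok]; value <- value[ok]
  if (length(unique(pll)) < 10)
    stop("need >= 10 distinct PLL values")
  n <- length(pll)
  fit0 <- lm(value ~ pll)
  rss0 <- sum(resid(fit0)^2)
  usable <- knots[vapply(knots, function(kn)
    sum(pll < kn) >= 2 && sum(pll > kn) >= 2, logical(1))]
  if (length(usable) == 0) stop("no candidate knot has support on both sides")
  rss <- vapply(usable, function(kn) {
    X <- cbind(1, pll, pmax(pll - kn, 0))
    sum(lm.fit(X, value)$residuals^2)
  }, numeric(1))
  best <- which.min(rss)
  kn <- usable[best]
  X <- cbind(1, pll, pmax(pll - kn, 0))
  b <- coef(lm.fit(X, value))
  fstat <- ((rss0 - rss[best]) / 1) / (rss[best] / (n - 3))
  p_imp <- stats::pf(fstat, 1, n - 3, lower.tail = FALSE)
  none <- p_imp >= alpha
  structure(list(pll_star = if (none) NA_real_ else kn,
                 slope_pre = unname(b[2]),
                 slope_post = unname(b[2] + b[3]),
                 rss = rss[best], rss_line = rss0,
                 improvement_p = p_imp, no_inflection = none,
                 knots = usable, rss_grid = rss),
            class = "inflection_estimate")
}

#' @export
print.inflection_estimate <- function(x, ...) {
  if (x$no_inflection) {
    cat("<inflection_estimate> no inflection (improvement p = ",
        format(x$improvement_p, digits = 3), ")\n", sep = "")
  } else {
    cat(sprintf(
      "<inflection_estimate> knee at PLL = %.2f; slopes %.3f -> %.3f\n",
      x$pll_star, x$slope_pre, x$slope_post))
  }
  invisible(x)
}
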