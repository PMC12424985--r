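#' Broad-sense heritability from strain replicates
#'
#' Fits the random-intercept model
#' `y = X beta + u_j + eps`, `u_j ~ N(0, sigma_u^2)`, `eps ~ N(0, sigma^2)`
#' by REML, with fixed covariates for sex, diet and their interaction by
#' default, and reports broad-sense heritability
#' `H^2 = sigma_u^2 / (sigma_u^2 + sigma^2)` together with the share of
#' variance explained by the fixed effects,
#' `var(X beta-hat) / (var(X beta-hat) + sigma_u^2 + sigma^2)`. Individual
#' replicates are always modelled — collapsing to strain means biases
#' heritability upward.
#'
#' @param data data frame of animals (one row per mouse).
#' @param response response column (default `"lifespan_months"`).
#' @param covariates one-sided formula of fixed effects
#'   (default `~ sex * diet`).
#' @param group strain column (default `"strain"`).
#' @return An object of class `heritability_estimate`: `kind` (`"H2"`),
#'   `estimate`, `proportions` (fixed / strain / residual variance shares,
#'   summing to 1), variance components, and the underlying `lmm_fit`.
#' @export
estimate_H2 <- function(data, response = "lifespan_months",
                        covariates = ~ sex * diet, group = "strain") {
  check_strain_design(data, group)
  fm <- as.formula(paste(response, "~", deparse(covariates[[2]]),
                         "+ (1 |", group, ")"))
  fit <- fit_lmm(fm, data)
  heritability_from_fit(fit, kind = "H2", group = group)
}

#' Narrow-sense heritability with a kinship matrix
#'
#' Same model as [estimate_H2()] but the strain random effect has covariance
#' `sigma_g^2 K`, where `K` is the strain-level additive relatedness matrix
#' (rescaled internally so its mean diagonal is 1). Narrow-sense
#' heritability is `h^2 = sigma_g^2 / (sigma_g^2 + sigma^2)`. With `K = I`
#' this reduces numerically to [estimate_H2()].
#'
#' @inheritParams estimate_H2
#' @param K square symmetric PSD relatedness matrix covering all strains in
#'   `data`.
#' @return A `heritability_estimate` with `kind = "h2"`.
#' @export
estimate_h2 <- function(data, K, response = "lifespan_months",
                        covariates = ~ sex * diet, group = "strain") {
  check_strain_design(data, group)
  fm <- as.formula(paste(response, "~", deparse(covariates[[2]]),
                         "+ (1 |", group, ")"))
  fit <- fit_lmm(fm, data, kinship = K, kinship_group = group)
  est <- heritability_from_fit(fit, kind = "h2", group = group)
  est$kinship <- K
  est
}

check_strain_design <- function(data, group) {
  tab <- table(data[[group]])
  if (length(tab) < 2)
    stop("design error: need >= 2 strains to separate strain variance")
  if (sum(tab >= 2) < 2)
    stop("design error: need >= 2 strains with >= 2 replicates")
  invisible(TRUE)
}

heritability_from_fit <- function(fit, kind, group) {
  vc <- varcomp(fit)
  s2u <- vc$vcov[vc$grp == group & is.na(vc$var2) &
                   vc$var1 == "(Intercept)"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  h2 <- s2u / (s2u + s2e)
  xb <- as.vector(model.matrix(lme4::nobars(fit$formula), fit$data) %*%
                    lme4::fixef(fit$model))
  vfix <- var(xb)
  tot <- vfix + s2u + s2e
  props <- c(fixed = vfix / tot, strain = s2u / tot, residual = s2e / tot)
  structure(list(kind = kind, estimate = h2, proportions = props,
                 sigma2_strain = s2u, sigma2_resid = s2e,
                 fit = fit, group = group, ci = NULL, ci_method = NULL),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat("<heritability_estimate> ", x$kind, " = ",
      format(x$estimate, digits = 4), "\n", sep = "")
  if (!is.null(x$ci))
    cat("  ", round(100 * x$ci_level), "% ", x$ci_method, " CI [",
        format(x$ci[1], digits = 3), ", ", format(x$ci[2], digits = 3),
        "]\n", sep = "")
  cat("  variance shares: fixed ", format(x$proportions["fixed"], digits = 3),
      ", strain ", format(x$proportions["strain"], digits = 3),
      ", residual ", format(x$proportions["residual"], digits = 3),
      "\n", sep = "")
  invisible(x)
}

## REML deviance as a function of the heritability ratio h in [0,1), via the
## single-theta devfun: theta = sd ratio = sqrt(h / (1 - h))
ratio_devfun <- function(est) {
  fit <- est$fit
  control <- lme4::lmerControl(check.conv.singular = "ignore")
  lf <- lme4::lFormula(fit$formula, fit$data, REML = fit$reml,
                       control = control)
  if (!is.null(fit$kinship_group)) {
    lev <- levels(factor(fit$data[[fit$kinship_group]]))
    lf <- rotate_reTrms(lf, est$kinship, fit$kinship_group, lev)
  }
  devfun <- do.call(lme4::mkLmerDevfun, lf)
  if (length(lme4::getME(fit$model, "theta")) != 1)
    stop("profile CI supports a single strain variance component")
  function(h2) devfun(sqrt(h2 / (1 - h2)))
}

#' Confidence interval for a heritability estimate
#'
#' Profile method: the REML log-likelihood, profiled over fixed effects and
#' the residual scale, is evaluated along the heritability ratio and the
#' interval is the set of ratios within the chi-square(1) cutoff of the
#' maximum (endpoints satisfy `2 * (l_max - l_end) = qchisq(level, 1)`). An
#' estimate at the zero boundary yields a one-sided interval with lower
#' bound 0 (flagged). Bootstrap method: strains — the exchangeable genetic
#' unit — are resampled with replacement `B` times and the percentile
#' interval of the re-estimates is returned.
#'
#' @param est a `heritability_estimate`.
#' @param method `"profile"` or `"bootstrap"`.
#' @param B bootstrap replicates (default 500; fewer than 50 warns).
#' @param seed seed for the bootstrap resampling.
#' @param level confidence level (default 0.95).
#' @return The `heritability_estimate` with `ci`, `ci_method`, `ci_level`
#'   and `boundary` filled in.
#' @export
heritability_ci <- function(est, method = c("profile", "bootstrap"),
                            B = 500, seed = 1L, level = 0.95) {
  stopifnot(inherits(est, "heritability_estimate"))
  method <- match.arg(method)
  if (method == "profile") {
    dev <- ratio_devfun(est)
    h_hat <- est$estimate
    d0 <- dev(min(max(h_hat, 1e-10), 1 - 1e-10))
    cut <- qchisq(level, 1)
    boundary <- FALSE
    eps <- 1e-10
    lo <- if (h_hat <= 1e-8 || dev(eps) - d0 < cut) {
      boundary <- boundary || h_hat <= 1e-8
      0
    } else {
      uniroot(function(h) dev(h) - d0 - cut, c(eps, h_hat),
              tol = 1e-10)$root
    }
    hi <- if (dev(1 - 1e-7) - d0 < cut) 1 else {
      uniroot(function(h) dev(h) - d0 - cut, c(max(h_hat, eps), 1 - 1e-7),
              tol = 1e-10)$root
    }
    est$ci <- c(lo, hi)
    est$boundary <- boundary
  } else {
    if (B < 50) warning("B < 50 bootstrap replicates is unreliable")
    set.seed(as.integer(seed))
    dat <- est$fit$data
    strains <- unique(as.character(dat[[est$group]]))
    reps <- vapply(seq_len(B), function(b) {
      pick <- sample(strains, replace = TRUE)
      pieces <- lapply(seq_along(pick), function(i) {
        d <- dat[dat[[est$group]] == pick[i], , drop = FALSE]
        d[[est$group]] <- sprintf("bs%03d", i)
        d
      })
      db <- do.call(rbind, pieces)
      eb <- try(suppressWarnings({
        if (est$kind == "h2") {
          Kb <- est$kinship[pick, pick, drop = FALSE]
          dimnames(Kb) <- rep(list(sprintf("bs%03d", seq_along(pick))), 2)
          estimate_h2(db, Kb,
                      response = all.vars(est$fit$formula)[1],
                      covariates = strip_random(est$fit$formula),
                      group = est$group)
        } else {
          estimate_H2(db, response = all.vars(est$fit$formula)[1],
                      covariates = strip_random(est$fit$formula),
                      group = est$group)
        }
      }), silent = TRUE)
      if (inherits(eb, "try-error")) NA_real_ else eb$estimate
    }, numeric(1))
    alpha <- (1 - level) / 2
    est$ci <- unname(quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
    est$boundary <- est$estimate <= 1e-8
    est$bootstrap_estimates <- reps
  }
  est$ci_method <- method
  est$ci_level <- level
  est
}

## one-sided fixed-effect formula from a mixed formula
strip_random <- function(formula) {
  fx <- lme4::nobars(formula)
  as.formula(paste("~", deparse(fx[[3]])))
}
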