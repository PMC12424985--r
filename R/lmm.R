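#' Fit a Gaussian linear mixed model by REML
#'
#' The workhorse behind the heritability, GxT and biomarker modules. Models
#' are specified with `lme4` formula syntax, e.g.
#' `y ~ diet * sex * timepoint + bw6mo + (1 + diet | strain) + (1 | mouse_id)`.
#' A random intercept term can be given a kinship covariance
#' `u ~ N(0, sigma_g^2 K)` by passing the relatedness matrix `K`: the term's
#' random-effect design is rotated by a factor `L` with `K = L L'`, so the
#' standard iid machinery estimates `sigma_g^2` on the kinship scale.
#' A formula with no random terms reduces to ordinary least squares.
#'
#' Rows with missing values in any modelled column are dropped and the count
#' is recorded in the fit (`n_dropped`).
#'
#' @param formula model formula in `lme4` syntax.
#' @param data a data frame.
#' @param kinship optional square relatedness matrix with dimnames covering
#'   the levels of `kinship_group`; internally rescaled to mean diagonal 1.
#' @param kinship_group name of the grouping factor (e.g. `"strain"`) whose
#'   random intercept is scaled by `kinship`.
#' @param reml fit by REML (default) or maximum likelihood.
#' @param control an optional [lme4::lmerControl()]; by default singular-fit
#'   messages are silenced since boundary fits are expected in screens.
#' @return An object of class `lmm_fit`: list with the underlying `model`
#'   (`lmerModLmerTest`, `merMod` or `lm`), `reml_loglik`, `n_used`,
#'   `n_dropped`, and kinship bookkeeping.
#' @export
fit_lmm <- function(formula, data, kinship = NULL, kinship_group = NULL,
                    reml = TRUE, control = NULL) {
  vars <- all.vars(formula)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  keep <- complete.cases(data[, vars, drop = FALSE])
  n_dropped <- sum(!keep)
  dat <- droplevels(data[keep, , drop = FALSE])

  has_bars <- length(lme4::findbars(formula)) > 0
  fixed_form <- if (has_bars) lme4::nobars(formula) else formula

  ## rank check on the fixed-effect design, naming aliased columns
  X <- model.matrix(fixed_form, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; aliased: ",
         paste(aliased, collapse = ", "))
  }

  if (!has_bars) {
    model <- lm(formula, dat)
    out <- list(model = model, formula = formula, data = dat,
                reml = reml, reml_loglik = as.numeric(logLik(model)),
                n_used = nrow(dat), n_dropped = n_dropped,
                n_vcov_par = 1L, kinship_group = NULL)
    return(structure(out, class = "lmm_fit"))
  }

  ## boundary (singular) fits are legitimate outcomes in variance screens,
  ## and the gradient/Hessian heuristics misfire there; the Newton polish
  ## below provides its own check that the optimum was reached
  if (is.null(control))
    control <- lme4::lmerControl(check.conv.singular = "ignore",
                                 check.conv.grad = "ignore",
                                 check.conv.hess = "ignore",
                                 optCtrl = list(xtol_abs = 1e-10,
                                                ftol_abs = 1e-12))

  kin_L <- NULL
  if (!is.null(kinship)) {
    if (is.null(kinship_group))
      stop("kinship_group must name the grouping factor scaled by 'kinship'")
    model <- fit_lmer_kinship(formula, dat, kinship, kinship_group,
                              reml = reml, control = control)
    kin_L <- attr(model, "kin_L")
    attr(model, "kin_L") <- NULL
  } else {
    ## lmerTest recomputes a deviance Hessian for Satterthwaite df and warns
    ## at boundary fits; the polish step below is our convergence check
    quiet_boundary <- function(expr) withCallingHandlers(expr,
      warning = function(w) {
        if (grepl("negative eigenvalue", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    model <- quiet_boundary(
      lmerTest::lmer(formula, dat, REML = reml, control = control))
    model <- retry_if_unconverged(model, formula, dat, reml, control)
    model <- quiet_boundary(polish_lmer(model, formula, dat, reml))
  }

  out <- list(model = model, formula = formula, data = dat, reml = reml,
              reml_loglik = as.numeric(logLik(model)),
              n_used = nrow(dat), n_dropped = n_dropped,
              n_vcov_par = length(lme4::getME(model, "theta")) + 1L,
              kinship_group = kinship_group, kin_L = kin_L)
  structure(out, class = "lmm_fit")
}

## Newton refinement of the covariance parameters on the REML deviance with
## finite-difference derivatives: derivative-free optimizers stop within
## ~1e-7 of the optimum in theta, which is visible when variance components
## are compared against closed forms. Skipped at a boundary (theta ~ 0).
newton_polish <- function(devfun, th, lower, h = 4e-5, iters = 4L) {
  p <- length(th)
  at_bound <- lower == 0 & th < 1e-6
  if (any(at_bound)) return(NULL)
  best <- th
  fbest <- devfun(th)
  for (it in seq_len(iters)) {
    g <- numeric(p); H <- matrix(0, p, p)
    f0 <- devfun(best)
    for (i in seq_len(p)) {
      ei <- replace(numeric(p), i, h)
      fp <- devfun(best + ei); fm <- devfun(best - ei)
      g[i] <- (fp - fm) / (2 * h)
      H[i, i] <- (fp - 2 * f0 + fm) / h^2
    }
    if (p > 1) for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      ei <- replace(numeric(p), i, h); ej <- replace(numeric(p), j, h)
      H[i, j] <- H[j, i] <- (devfun(best + ei + ej) - devfun(best + ei - ej) -
                               devfun(best - ei + ej) +
                               devfun(best - ei - ej)) / (4 * h^2)
    }
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) -1)
    if (min(ev) <= 1e-8) break
    cand <- best - solve(H, g)
    cand <- pmax(cand, ifelse(lower == 0, 0, -Inf))
    fc <- tryCatch(devfun(cand), error = function(e) Inf)
    if (!is.finite(fc) || fc > fbest + 1e-9) break
    moved <- max(abs(cand - best))
    best <- cand; fbest <- fc
    if (moved < 1e-11) break
  }
  if (identical(best, th)) NULL else list(par = best, fval = fbest)
}

polish_lmer <- function(model, formula, dat, reml) {
  pol <- tryCatch({
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
    lf <- lme4::lFormula(formula, dat, REML = reml, control = ctrl)
    devfun <- do.call(lme4::mkLmerDevfun, lf)
    newton_polish(devfun, lme4::getME(model, "theta"),
                  lme4::getME(model, "lower"))
  }, error = function(e) NULL)
  if (is.null(pol)) return(model)
  tryCatch(suppressMessages(
    lmerTest::lmer(formula, dat, REML = reml, start = pol$par,
                   control = lme4::lmerControl(
                     optimizer = NULL, check.conv.singular = "ignore",
                     check.conv.grad = "ignore",
                     check.conv.hess = "ignore"))),
    error = function(e) model)
}

## second optimizer start on convergence failure (not on mere singularity)
retry_if_unconverged <- function(model, formula, dat, reml, control) {
  msgs <- unlist(model@optinfo$conv$lme4$messages)
  failed <- !is.null(msgs) && any(grepl("failed to converge", msgs))
  if (!failed) return(model)
  ctrl2 <- lme4::lmerControl(optimizer = "Nelder_Mead",
                             check.conv.singular = "ignore",
                             check.conv.grad = "ignore",
                             check.conv.hess = "ignore")
  m2 <- try(lmerTest::lmer(formula, dat, REML = reml, control = ctrl2),
            silent = TRUE)
  if (inherits(m2, "try-error")) return(model)
  if (logLik(m2) > logLik(model)) m2 else model
}

## rotate the rows of Zt belonging to the random intercept of `group` by the
## kinship factor L (K = L L'), so iid machinery estimates sigma_g^2 K
rotate_reTrms <- function(lf, K, group, lev) {
  terms_grp <- names(lf$reTrms$cnms)
  idx <- which(terms_grp == group & vapply(lf$reTrms$cnms, identical,
                                           logical(1), "(Intercept)"))
  if (length(idx) != 1)
    stop("kinship requires exactly one random intercept term for '",
         group, "'")
  Ksub <- rescale_kinship(K, lev)
  L <- kinship_factor(Ksub)
  Gp <- lf$reTrms$Gp
  rows <- (Gp[idx] + 1):Gp[idx + 1]
  stopifnot(length(rows) == length(lev))
  Zt <- lf$reTrms$Zt
  Zt[rows, ] <- as(t(L) %*% Zt[rows, , drop = FALSE], "CsparseMatrix")
  lf$reTrms$Zt <- Zt
  attr(lf, "kin_L") <- L
  lf
}

## modular lmer fit with one kinship-scaled random intercept term
fit_lmer_kinship <- function(formula, dat, K, group, reml, control) {
  if (!group %in% names(dat)) stop("kinship_group not in data: ", group)
  dat[[group]] <- factor(dat[[group]])
  lev <- levels(dat[[group]])
  if (!all(lev %in% rownames(K)))
    stop("kinship matrix does not cover strain(s): ",
         paste(setdiff(lev, rownames(K)), collapse = ", "))
  lf <- lme4::lFormula(formula, dat, REML = reml, control = control)
  lf <- rotate_reTrms(lf, K, group, lev)
  L <- attr(lf, "kin_L")
  attr(lf, "kin_L") <- NULL
  devfun <- do.call(lme4::mkLmerDevfun, lf)
  opt <- lme4::optimizeLmer(devfun, control = control$optCtrl)
  pol <- newton_polish(devfun, opt$par, environment(devfun)$lower)
  if (!is.null(pol)) {
    opt$par <- pol$par
    opt$fval <- pol$fval
  }
  devfun(opt$par)  # leave the devfun environment at the optimum
  model <- lme4::mkMerMod(environment(devfun), opt, lf$reTrms, fr = lf$fr)
  attr(model, "kin_L") <- L
  model
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> ", deparse(x$formula), "\n", sep = "")
  cat("  n = ", x$n_used, " (", x$n_dropped, " dropped), ",
      if (x$reml) "REML" else "ML", " log-lik = ",
      format(x$reml_loglik, digits = 7), "\n", sep = "")
  if (!is.null(x$kinship_group))
    cat("  kinship-scaled term: (1|", x$kinship_group, ")\n", sep = "")
  invisible(x)
}

#' @export
logLik.lmm_fit <- function(object, ...) logLik(object$model, ...)

#' Variance components of a mixed-model fit
#'
#' @param fit an `lmm_fit`.
#' @return Data frame with columns `grp`, `var1`, `var2`, `vcov` (variance or
#'   covariance) and `sdcor` (SD or correlation), residual last — the
#'   intercept-slope correlation of a `(1 + d | strain)` term appears as the
#'   row with both `var1` and `var2` set.
#' @export
varcomp <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (inherits(fit$model, "lm")) {
    s2 <- sum(resid(fit$model)^2) / stats::df.residual(fit$model)
    return(data.frame(grp = "Residual", var1 = NA, var2 = NA,
                      vcov = s2, sdcor = sqrt(s2)))
  }
  as.data.frame(lme4::VarCorr(fit$model))
}

#' Empirical-Bayes random-effect estimates (BLUPs)
#'
#' Conditional modes of the random effects for one grouping term, with
#' conditional SDs. For a kinship-scaled term the rotated effects are mapped
#' back to the strain scale (`u = L u*`); their conditional SDs use the same
#' rotation and treat the levels' conditional variances as independent.
#'
#' @param fit an `lmm_fit` with random terms.
#' @param term grouping factor name (e.g. `"strain"`).
#' @param which for terms with intercept and slope, which column (default
#'   all columns, returned wide).
#' @return Data frame: `level`, one column per random coefficient, and
#'   matching `.sd` columns of conditional SDs.
#' @export
blups <- function(fit, term, which = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (inherits(fit$model, "lm")) stop("fit has no random terms")
  re <- lme4::ranef(fit$model, condVar = TRUE)
  if (!term %in% names(re)) stop("no random term for grouping factor ", term)
  b <- re[[term]]
  pv <- attr(b, "postVar")  # q x q x nlevels
  q <- dim(pv)[1]
  sm <- vapply(seq_len(dim(pv)[3]),
               function(i) sqrt(diag(as.matrix(pv[, , i]))), numeric(q))
  sds <- if (q > 1) t(sm) else matrix(sm, ncol = 1)
  colnames(sds) <- paste0(colnames(b), ".sd")
  if (!is.null(fit$kinship_group) && identical(term, fit$kinship_group)) {
    L <- fit$kin_L
    u <- as.vector(L %*% b[rownames(L), 1])
    v <- as.vector(diag(L %*% diag(pv[1, 1, ], nrow(L)) %*% t(L)))
    b[rownames(L), 1] <- u
    sds[, 1] <- sqrt(v)
  }
  out <- data.frame(level = rownames(b), b, sds, check.names = FALSE,
                    row.names = NULL)
  if (!is.null(which)) out <- out[, c("level", which, paste0(which, ".sd"))]
  out
}

#' Likelihood-ratio test for nested random-effect structures
#'
#' Tests whether extra variance-covariance parameters in `full` (for example
#' the strain diet slope and its correlation with the strain intercept, the
#' GxT term) improve the REML fit. The statistic `2(l_full - l_reduced)`,
#' floored at zero, is referred to a chi-square with df equal to the number
#' of dropped covariance parameters; this reference is conservative when the
#' null puts a variance on its boundary, and a 50:50 chi-square mixture
#' reference is available via `mixture = TRUE`.
#'
#' @param full,reduced two `lmm_fit` objects on the same data and fixed
#'   effects, `reduced` nested in `full`.
#' @param mixture use the equal-weights chi-square mixture of df and df-1.
#' @return Data frame with `statistic`, `df`, `p`.
#' @export
lrt_random <- function(full, reduced, mixture = FALSE) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (full$n_used != reduced$n_used)
    stop("fits use different data (", full$n_used, " vs ", reduced$n_used,
         " rows); refit on a common subset")
  df <- full$n_vcov_par - reduced$n_vcov_par
  if (df < 0) stop("'full' has fewer covariance parameters than 'reduced'")
  stat <- max(0, 2 * (full$reml_loglik - reduced$reml_loglik))
  p <- if (df == 0) 1 else if (mixture) {
    0.5 * pchisq(stat, df, lower.tail = FALSE) +
      0.5 * pchisq(stat, max(df - 1, 0), lower.tail = FALSE)
  } else {
    pchisq(stat, df, lower.tail = FALSE)
  }
  if (stat == 0) p <- 1
  data.frame(statistic = stat, df = df, p = p)
}

#' Population-averaged contrasts of model-based means
#'
#' Cell means on an equal-weight reference grid over the other factors
#' (delegated to `emmeans`), with pairwise differences, SEs from the
#' fixed-effect covariance and, for mixed fits, Satterthwaite degrees of
#' freedom.
#'
#' @param fit an `lmm_fit`.
#' @param factor name of the fixed factor to contrast (e.g. `"diet"`).
#' @param by optional stratifier name(s) (e.g. `"sex"`) for within-stratum
#'   contrasts.
#' @return Data frame of contrasts: `contrast`, stratifier columns if any,
#'   `estimate`, `SE`, `df`, `p`.
#' @export
contrast_means <- function(fit, factor, by = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  fvals <- fit$data[[factor]]
  if (is.null(fvals)) stop("no such column: ", factor)
  if (is.numeric(fvals) && length(unique(fvals)) > 8)
    stop("'", factor, "' is continuous; contrasts need a factor")
  spec <- as.formula(paste("~", factor))
  emm <- suppressMessages(
    emmeans::emmeans(fit$model, specs = spec, by = by,
                     lmer.df = "satterthwaite", data = fit$data))
  ctr <- summary(emmeans::contrast(emm, method = "pairwise"), infer = TRUE)
  out <- as.data.frame(ctr)
  names(out)[names(out) == "p.value"] <- "p"
  out
}
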