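#' Kaplan-Meier survival curves
#'
#' Product-limit estimate of lifespan survival, overall or by group, with
#' Greenwood standard errors (delegated to the `survival` package).
#'
#' @param data data frame of animals.
#' @param group optional grouping column name (e.g. `"diet"`).
#' @param time,event column names of follow-up time (months) and the
#'   death-observed indicator (1 = death, 0 = censored).
#' @return An object of class `km_curve`: list of per-group data frames
#'   (`time`, `n.risk`, `n.event`, `surv`, `std.err`) plus the underlying
#'   `survfit` object.
#' @export
km_fit <- function(data, group = NULL, time = "lifespan_months",
                   event = "event_observed") {
  if (nrow(data) == 0) stop("no observations")
  if (any(data[[time]] <= 0)) stop("survival times must be positive")
  fm <- if (is.null(group)) {
    as.formula(sprintf("survival::Surv(%s, %s) ~ 1", time, event))
  } else {
    as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time, event, group))
  }
  sf <- survival::survfit(fm, data = data, conf.type = "log-log")
  sm <- summary(sf, censored = TRUE)
  grp <- if (is.null(sm$strata)) factor(rep("all", length(sm$time)))
         else sm$strata
  tab <- data.frame(group = sub("^[^=]*=", "", as.character(grp)),
                    time = sm$time, n.risk = sm$n.risk, n.event = sm$n.event,
                    surv = sm$surv, std.err = sm$std.err)
  structure(list(table = tab, survfit = sf, group = group),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve>", if (!is.null(x$group)) paste("by", x$group), "\n")
  print(head(x$table, 12))
  invisible(x)
}

#' Survival quantile from a Kaplan-Meier curve
#'
#' The q-th lifespan quantile is the smallest observed time at which the
#' survival estimate drops to `1 - q` or below (the `survfit` convention);
#' if the curve never crosses it, the quantile is undefined and `NA` is
#' returned — never extrapolated. `q = 0.5` gives median lifespan, `q = 0.9`
#' the 90th-percentile "maximum lifespan" summary.
#'
#' @param curve a `km_curve`.
#' @param q quantile in (0, 1).
#' @return Named numeric vector of per-group quantiles (months).
#' @export
survival_quantile <- function(curve, q = 0.5) {
  stopifnot(inherits(curve, "km_curve"), q > 0, q < 1)
  tab <- curve$table
  vapply(split(tab, tab$group), function(d) {
    hit <- which(d$surv <= 1 - q + 1e-12 & d$n.event > 0)
    if (length(hit) == 0) NA_real_ else d$time[min(hit)]
  }, numeric(1))
}

#' Log-rank test, overall or all pairwise
#'
#' Score test comparing survival across groups (chi-square on k-1 df). In
#' pairwise mode every unordered pair of groups is tested and p-values are
#' Benjamini-Hochberg adjusted.
#'
#' @inheritParams km_fit
#' @param group grouping column name.
#' @param pairwise run all pairwise two-group tests.
#' @return For `pairwise = FALSE` a one-row data frame (`statistic`, `df`,
#'   `p`); otherwise a data frame with one row per pair plus a BH-adjusted
#'   `q` column.
#' @export
logrank <- function(data, group, pairwise = FALSE,
                    time = "lifespan_months", event = "event_observed") {
  lev <- unique(as.character(data[[group]]))
  if (length(lev) < 2) stop("need at least 2 groups")
  one <- function(d) {
    fm <- as.formula(sprintf("survival::Surv(%s, %s) ~ %s",
                             time, event, group))
    sd <- survival::survdiff(fm, data = d)
    k <- length(sd$n)
    data.frame(statistic = sd$chisq, df = k - 1,
               p = pchisq(sd$chisq, k - 1, lower.tail = FALSE))
  }
  if (!pairwise) return(one(data))
  lev <- sort(lev)
  prs <- utils::combn(lev, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    d <- data[data[[group]] %in% prs[, i], , drop = FALSE]
    cbind(data.frame(group1 = prs[1, i], group2 = prs[2, i]), one(d))
  }))
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Stratified Cox proportional-hazards fit
#'
#' Estimates average diet, sex and diet-by-sex log-hazard effects with strain
#' as a stratification term (each stratum keeps its own baseline hazard), the
#' design used to pool intervention effects over genetically distinct
#' strains. An optional `cluster` column (housing cage) switches the
#' covariance to the cluster-robust sandwich form as a sensitivity analysis
#' for intra-cage correlation.
#'
#' @inheritParams km_fit
#' @param covariates one-sided formula of fixed effects
#'   (default `~ diet * sex`).
#' @param strata optional stratification column name.
#' @param cluster optional clustering column name for robust SEs.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_fit`: coefficient table (`coef`, `HR`,
#'   `se`, `z`, `p`), `strata`, `ties` and the underlying `coxph` fit.
#' @export
cox_fit <- function(data, covariates = ~ diet * sex, strata = NULL,
                    cluster = NULL, ties = c("efron", "breslow"),
                    time = "lifespan_months", event = "event_observed") {
  ties <- match.arg(ties)
  rhs <- paste(deparse(covariates[[2]]), collapse = " ")
  if (!is.null(strata)) rhs <- paste0(rhs, " + strata(", strata, ")")
  fm <- as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time, event, rhs))
  args <- list(formula = fm, data = data, ties = ties)
  if (!is.null(cluster)) args$cluster <- data[[cluster]]
  fit <- withCallingHandlers(
    do.call(survival::coxph, args),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w)))
        stop("monotone likelihood / separation: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(abs(coef(fit)) > 15))
    stop("divergent coefficient(s): ",
         paste(names(coef(fit))[abs(coef(fit)) > 15], collapse = ", "))
  sm <- summary(fit)
  co <- sm$coefficients
  se_col <- if ("robust se" %in% colnames(co)) "robust se" else "se(coef)"
  tab <- data.frame(term = rownames(co), coef = co[, "coef"],
                    HR = exp(co[, "coef"]), se = co[, se_col],
                    z = co[, "coef"] / co[, se_col],
                    row.names = NULL)
  tab$p <- 2 * pnorm(-abs(tab$z))
  structure(list(coefficients = tab, strata = strata, ties = ties,
                 cluster = cluster, model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> ties = ", x$ties,
      if (!is.null(x$strata)) paste0(", stratified by ", x$strata),
      if (!is.null(x$cluster)) paste0(", robust SE by ", x$cluster),
      "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

## area under a KM step curve from 0 to tau, plus variance (Greenwood form)
rmst_one <- function(time, event, tau) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  tt <- c(0, sf$time[sf$time <= tau], tau)
  ss <- c(1, sf$surv[sf$time <= tau])
  area <- sum(ss * diff(tt))
  ## variance: sum over event times of [int_t^tau S]^2 * d/(Y(Y-d))
  idx <- which(sf$time <= tau)
  v <- 0
  if (length(idx)) {
    tails <- rev(cumsum(rev(ss * diff(tt))))  # area from tt[j] to tau
    a_after <- tails[-1]                      # area from each t_i to tau
    d <- sf$n.event[idx]; y <- sf$n.risk[idx]
    ok <- d > 0 & (y - d) > 0
    v <- sum(a_after[ok]^2 * d[ok] / (y[ok] * (y[ok] - d[ok])))
  }
  c(rmst = area, var = v)
}

#' Restricted mean survival time difference
#'
#' RMST is the area under the Kaplan-Meier curve up to a truncation time
#' `tau` — mean lifespan over the first `tau` months. The between-group
#' difference summarizes the intervention effect in months, with an
#' asymptotic normal CI and z-test based on Greenwood-type variances.
#'
#' @inheritParams km_fit
#' @param group two-level grouping column (default `"diet"`).
#' @param tau truncation time in months; default (logged in the result) is
#'   the smaller of the two groups' largest observed times.
#' @param conf confidence level.
#' @return An object of class `rmst_result`: `tau`, per-group RMST and SE,
#'   `difference` (group2 - group1 in level order), `ci`, `p`.
#' @export
rmst_diff <- function(data, group = "diet", tau = NULL,
                      conf = 0.95, time = "lifespan_months",
                      event = "event_observed") {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("rmst_diff needs exactly 2 groups")
  tmax <- tapply(data[[time]], g, max)
  tau_max <- min(tmax)
  if (is.null(tau)) tau <- tau_max
  if (tau > tau_max + 1e-12)
    stop("tau = ", tau, " exceeds the shortest group follow-up (", tau_max, ")")
  lv <- levels(g)
  r1 <- rmst_one(data[[time]][g == lv[1]], data[[event]][g == lv[1]], tau)
  r2 <- rmst_one(data[[time]][g == lv[2]], data[[event]][g == lv[2]], tau)
  diff <- unname(r2["rmst"] - r1["rmst"])
  se <- sqrt(r1["var"] + r2["var"])
  z <- if (se > 0) diff / se else 0
  ci <- diff + c(-1, 1) * qnorm(1 - (1 - conf) / 2) * se
  structure(list(tau = tau, groups = lv,
                 rmst = setNames(c(r1["rmst"], r2["rmst"]), lv),
                 se = setNames(sqrt(c(r1["var"], r2["var"])), lv),
                 difference = diff, ci = unname(ci),
                 p = 2 * pnorm(-abs(z))),
            class = "rmst_result")
}

#' @export
print.rmst_result <- function(x, ...) {
  cat("<rmst_result> tau =", format(x$tau, digits = 4), "months\n")
  cat("  RMST:", paste(sprintf("%s %.2f", names(x$rmst), x$rmst),
                       collapse = ", "), "\n")
  cat(sprintf("  difference (%s - %s) = %.2f mo, 95%% CI [%.2f, %.2f], p = %.3g\n",
              x$groups[2], x$groups[1], x$difference, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' Lifespan variability comparison by coefficient of variation
#'
#' Computes the CV (SD/mean) of lifespan for each stratum x group cell and
#' runs a Wilcoxon signed-rank test on the paired per-stratum CV differences
#' between the two groups, testing whether the intervention alters lifespan
#' variability. Cells with fewer than 2 animals are dropped with a warning;
#' zero differences are dropped per the signed-rank convention, and an
#' all-zero comparison gives p = 1.
#'
#' @inheritParams km_fit
#' @param strata stratifying column (default `"strain"`).
#' @param group two-level column (default `"diet"`).
#' @return List with `cv` (data frame: stratum, group, n, cv) and `p`.
#' @export
cv_compare <- function(data, strata = "strain", group = "diet",
                       time = "lifespan_months") {
  cells <- split(data[[time]], list(data[[strata]], data[[group]]), sep = "|")
  small <- names(cells)[vapply(cells, length, 1L) < 2]
  if (length(small)) {
    warning("dropping cell(s) with n < 2: ", paste(small, collapse = ", "))
    cells <- cells[!names(cells) %in% small]
  }
  info <- do.call(rbind, strsplit(names(cells), "|", fixed = TRUE))
  cv <- data.frame(stratum = info[, 1], group = info[, 2],
                   n = vapply(cells, length, 1L),
                   cv = vapply(cells, function(x) sd(x) / mean(x), 1),
                   row.names = NULL)
  wide <- tapply(cv$cv, list(cv$stratum, cv$group), identity)
  if (ncol(wide) != 2) stop("cv_compare needs exactly 2 groups")
  keep <- complete.cases(wide)
  d <- wide[keep, 2] - wide[keep, 1]
  d <- d[d != 0]
  p <- if (length(d) == 0) 1 else
    suppressWarnings(wilcox.test(d, exact = TRUE)$p.value)
  list(cv = cv, p = p)
}
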