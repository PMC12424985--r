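#' Loess-smooth a weekly series
#'
#' Local polynomial (degree 2, tricube-weighted) regression over the span
#' fraction of nearest points, evaluated at the observed ages — the
#' standard pre-processing of weekly body-weight series before
#' trajectory summaries. Series with fewer than 5 points are passed through
#' unchanged with a flag; non-monotone ages are sorted with a warning and
#' duplicate ages averaged.
#'
#' @param age numeric ages (weeks).
#' @param value measurements at those ages.
#' @param span fraction of data in each local neighbourhood (default 1/3).
#' @param degree local polynomial degree (default 2).
#' @return Data frame `age`, `smoothed`, with attribute `passthrough` set
#'   when smoothing was skipped.
#' @export
smooth_series <- function(age, value, span = 1/3, degree = 2) {
  stopifnot(length(age) == length(value))
  if (is.unsorted(age)) {
    warning("ages not in increasing order; sorting")
    o <- order(age)
    age <- age[o]; value <- value[o]
  }
  if (anyDuplicated(age)) {
    value <- as.vector(tapply(value, age, mean))
    age <- sort(unique(age))
  }
  if (length(age) < 5) {
    out <- data.frame(age = age, smoothed = value)
    attr(out, "passthrough") <- TRUE
    return(out)
  }
  ## every neighbourhood needs at least degree + 2 points to be solvable
  span <- max(span, min(1, (degree + 2) / length(age)))
  lo <- loess(value ~ age, span = span, degree = degree, family = "gaussian",
              control = loess.control(surface = "direct"))
  out <- data.frame(age = age, smoothed = fitted(lo))
  attr(out, "passthrough") <- FALSE
  out
}

#' Lifetime weight-trajectory summaries
#'
#' Mean mass (MM) — the arithmetic mean of the smoothed series — and +AUC,
#' the trapezoidal integral of the smoothed series over the observed age
#' range with baseline zero (gram-weeks). With `positive_part = TRUE` the
#' area is instead measured above the first observed value.
#'
#' @param series data frame with columns `age` and `smoothed` (e.g. from
#'   [smooth_series()]).
#' @param positive_part integrate the excess over the first observation
#'   rather than over zero.
#' @return List `MM`, `plusAUC` (NA for a single point), `age_unit`.
#' @export
weight_summaries <- function(series, positive_part = FALSE) {
  a <- series$age; w <- series$smoothed
  stopifnot(length(a) >= 1)
  if (length(a) == 1) return(list(MM = w, plusAUC = NA_real_,
                                  age_unit = "weeks"))
  base <- if (positive_part) w[1] else 0
  y <- w - base
  auc <- sum(diff(a) * (y[-1] + y[-length(y)]) / 2)
  list(MM = mean(w), plusAUC = auc, age_unit = "weeks")
}

#' Rescale ages to proportion of life lived
#'
#' PLL = age / lifespan puts mice with different lifespans on a common
#' `[0, 1]` aging axis. Ages beyond the lifespan indicate a referential
#' inconsistency and are an error.
#'
#' @param age ages (same unit as `lifespan`).
#' @param lifespan the mouse's lifespan (> 0).
#' @return Numeric vector of PLL values in `[0, 1]`.
#' @export
to_pll <- function(age, lifespan) {
  if (lifespan <= 0) stop("lifespan must be positive")
  if (any(age > lifespan + 1e-9))
    stop("age exceeds lifespan: phenotype rows must not postdate death")
  age / lifespan
}

#' Bin measurements over equidistant PLL spans
#'
#' Assigns each measurement to one of `bins` equal spans of proportion of
#' life lived — bin i covers `[(i-1)/bins, i/bins)`, the last bin closed so
#' PLL = 1 lands in it — and returns per-bin means and standard errors,
#' optionally by group.
#'
#' @param pll PLL values in `[0, 1]`.
#' @param value measurements.
#' @param bins number of spans (default 20).
#' @param group optional grouping vector (e.g. sex or diet).
#' @return Data frame: optional `group`, `bin`, `pll_mid`, `n`, `mean`,
#'   `sem`.
#' @export
bin_means <- function(pll, value, bins = 20, group = NULL) {
  stopifnot(all(pll >= 0 & pll <= 1 + 1e-12))
  bin <- pmin(floor(pll * bins) + 1L, bins)  # terminal clamp: pll=1 -> last
  key <- if (is.null(group)) list(bin = bin) else
    list(group = group, bin = bin)
  agg <- aggregate(value, by = key, FUN = function(v)
    c(n = length(v), mean = mean(v), sem = sd(v) / sqrt(length(v))))
  out <- cbind(agg[setdiff(names(agg), "x")], as.data.frame(agg$x))
  out$pll_mid <- (out$bin - 0.5) / bins
  out[order(if (is.null(group)) out$bin else paste(out$group, out$bin)), ]
}

#' Frailty index from ordinal deficit items
#'
#' FI is the mean of the non-missing item scores at a visit; items are coded
#' 0 (deficit absent), 0.5 (mild) or 1 (severe). Visits with no scored items
#' are an error.
#'
#' @param items numeric vector of item scores in \{0, 0.5, 1\} (NAs allowed).
#' @return FI in `[0, 1]`.
#' @export
frailty_index <- function(items) {
  ok <- !is.na(items)
  if (!any(ok)) stop("all items missing at this visit")
  if (!all(items[ok] %in% c(0, 0.5, 1)))
    stop("item scores must be 0, 0.5 or 1")
  mean(items[ok])
}

#' Per-mouse frailty trajectory summaries
#'
#' FI at each visit is regressed on proportion of life lived; the OLS slope
#' is the mouse's pace of deficit accumulation per unit of life lived, and
#' the final FI (last visit before death) proxies lifetime frailty burden.
#'
#' @param assessments data frame for one mouse: `age_weeks` plus item
#'   columns (names starting `item`).
#' @param lifespan_weeks the mouse's lifespan in weeks.
#' @return List `fi` (per-visit data frame: `age_weeks`, `pll`, `fi`),
#'   `fi_slope` (NA with < 2 visits), `final_fi`.
#' @export
fi_summaries <- function(assessments, lifespan_weeks) {
  item_cols <- grep("^item", names(assessments), value = TRUE)
  if (length(item_cols) == 0) stop("no item columns (item*)")
  keep <- rowSums(!is.na(assessments[item_cols])) > 0
  if (any(!keep)) warning("dropping ", sum(!keep), " visit(s) with no items")
  a <- assessments[keep, , drop = FALSE]
  fi <- unname(apply(a[item_cols], 1, frailty_index))
  pll <- to_pll(a$age_weeks, lifespan_weeks)
  slope <- if (length(fi) >= 2 && sd(pll) > 0)
    unname(coef(lm(fi ~ pll))[2]) else NA_real_
  ord <- order(a$age_weeks)
  list(fi = data.frame(age_weeks = a$age_weeks[ord], pll = pll[ord],
                       fi = fi[ord]),
       fi_slope = slope, final_fi = fi[ord][length(fi)])
}

#' Cumulative incidence of severe health deficits
#'
#' A mouse counts as affected for an item if any visit scored it severe
#' (exactly 1; mild 0.5 counts as non-severe). Incidence is affected mice
#' over mice assessed, per strain x diet, and the IF minus AL difference
#' summarizes each strain's dietary modulation of that deficit.
#'
#' @param frailty frailty table (`mouse_id` plus `item*` columns, one row
#'   per visit).
#' @param animals animal table (`mouse_id`, `strain`, `diet`).
#' @return Data frame: `item`, `strain`, per-diet incidence columns, and
#'   `difference` (IF - AL; NA where a cell has no assessed mice).
#' @export
deficit_incidence <- function(frailty, animals) {
  item_cols <- grep("^item", names(frailty), value = TRUE)
  vals <- unlist(frailty[item_cols])
  if (!all(is.na(vals) | vals %in% c(0, 0.5, 1)))
    stop("item scores must be 0, 0.5 or 1")
  ## per-mouse: ever severe, per item
  ever <- aggregate(frailty[item_cols],
                    by = list(mouse_id = frailty$mouse_id),
                    FUN = function(v) as.numeric(any(v == 1, na.rm = TRUE)))
  d <- merge(ever, animals[, c("mouse_id", "strain", "diet")], by = "mouse_id")
  out <- do.call(rbind, lapply(item_cols, function(it) {
    inc <- tapply(d[[it]], list(d$strain, d$diet), mean)
    df <- data.frame(item = it, strain = rownames(inc))
    for (g in colnames(inc)) df[[paste0("incidence_", g)]] <- inc[, g]
    df
  }))
  if (all(c("incidence_IF", "incidence_AL") %in% names(out)))
    out$difference <- out$incidence_IF - out$incidence_AL
  rownames(out) <- NULL
  out
}
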