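#' Per-mouse body-weight traits for the biomarker screen
#'
#' Smooths each mouse's weekly body-weight series and summarizes it as mean
#' mass (MM) and +AUC, the two lifetime weight traits entered into the
#' longevity-biomarker screen in place of per-timepoint weights.
#'
#' @param phenotypes long phenotype table containing `body_weight` rows.
#' @return Data frame `mouse_id`, `MM`, `plusAUC`.
#' @export
weight_trait_table <- function(phenotypes) {
  bw <- phenotypes[phenotypes$phenotype_name == "body_weight", , drop = FALSE]
  if (nrow(bw) == 0) stop("no body_weight rows in phenotype table")
  by_mouse <- split(bw, bw$mouse_id)
  out <- lapply(names(by_mouse), function(id) {
    s <- smooth_series(by_mouse[[id]]$age_weeks, by_mouse[[id]]$value)
    ws <- weight_summaries(s)
    data.frame(mouse_id = id, MM = ws$MM, plusAUC = ws$plusAUC)
  })
  do.call(rbind, out)
}

#' Longevity-biomarker regression screen
#'
#' For each trait x timepoint, regresses lifespan on the trait adjusting for
#' diet, sex, 6-month body weight (fixed) and strain and collection batch
#' (random intercepts). Lifespan, trait and body weight are rank-normalized
#' before fitting, so the trait coefficient is a standardized beta. The
#' trait p-value comes from the F test of its term with Satterthwaite
#' denominator degrees of freedom; a fixed-effects (OLS) fallback is used
#' when the mixed fit is not estimable. Mice must be alive to be measured,
#' so each timepoint's sample is survival-conditioned by construction.
#'
#' @param phenotypes long phenotype table.
#' @param animals animal table with `lifespan_months`, `diet`, `sex`,
#'   `strain`, `bw6mo`.
#' @param traits trait names to screen; default: every phenotype except
#'   `body_weight` and `temperature`, plus the MM and +AUC weight traits
#'   when weekly weights are present.
#' @param min_n minimum complete observations per trait x timepoint
#'   (default 20).
#' @return An object of class `biomarker_screen`: data frame with `trait`,
#'   `timepoint`, `beta` (standardized), `F`, `den_df`, `p`, `q`
#'   (BH across all trait x timepoint tests), `n`, `method`.
#' @export
biomarker_screen <- function(phenotypes, animals, traits = NULL, min_n = 20) {
  all_ph <- unique(phenotypes$phenotype_name)
  if (is.null(traits))
    traits <- setdiff(all_ph, c("body_weight", "temperature"))
  ph <- phenotypes[phenotypes$phenotype_name %in% traits, , drop = FALSE]
  tests <- split(ph, list(ph$phenotype_name, ph$timepoint_index), drop = TRUE)

  wt <- if ("body_weight" %in% all_ph) weight_trait_table(phenotypes) else NULL

  screen_one <- function(d, trait, timepoint) {
    d <- merge(d, animals, by = "mouse_id")
    d <- d[complete.cases(d[, c("value", "lifespan_months", "bw6mo",
                                "diet", "sex", "strain")]), ]
    if (nrow(d) < min_n) return(NULL)
    if (sd(d$value) == 0) return(NULL)
    if (isTRUE(all.equal(rank(d$value), rank(d$bw6mo))))
      stop("aliasing: trait '", trait, "' duplicates bw6mo")
    d$y <- rank_normal(d$lifespan_months)
    d$x <- rank_normal(d$value)
    d$bw <- rank_normal(d$bw6mo)
    use_batch <- "batch" %in% names(d) && !all(is.na(d$batch)) &&
      length(unique(d$batch)) >= 2
    rand <- if (use_batch) "(1 | strain) + (1 | batch)" else "(1 | strain)"
    fm <- as.formula(paste("y ~ x + diet + sex + bw +", rand))
    res <- try({
      fit <- fit_lmm(fm, d)
      av <- stats::anova(fit$model, ddf = "Satterthwaite")
      data.frame(trait = trait, timepoint = timepoint,
                 beta = unname(lme4::fixef(fit$model)["x"]),
                 F = av["x", "F value"], den_df = av["x", "DenDF"],
                 p = av["x", "Pr(>F)"], n = nrow(d), method = "lmm")
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      fit <- lm(y ~ x + diet + sex + bw + strain, d)
      av <- stats::anova(fit)
      data.frame(trait = trait, timepoint = timepoint,
                 beta = unname(coef(fit)["x"]),
                 F = av["x", "F value"], den_df = stats::df.residual(fit),
                 p = av["x", "Pr(>F)"], n = nrow(d), method = "ols")
    } else res
  }

  rows <- lapply(tests, function(d)
    screen_one(d, d$phenotype_name[1], d$timepoint_index[1]))
  if (!is.null(wt)) {
    for (tr in c("MM", "plusAUC")) {
      d <- data.frame(mouse_id = wt$mouse_id, value = wt[[tr]],
                      batch = NA_character_)
      rows <- c(rows, list(screen_one(d, tr, 1L)))
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0) stop("no testable trait x timepoint")
  rownames(tab) <- NULL
  structure(list(table = fdr_across(tab)), class = "biomarker_screen")
}

#' Pooled FDR adjustment across biomarker tests
#'
#' One Benjamini-Hochberg pass over all trait x timepoint p-values (a single
#' pooled family, not per-trait or per-timepoint pools).
#'
#' @param results data frame with a `p` column.
#' @return The data frame with a `q` column appended.
#' @export
fdr_across <- function(results) {
  if (nrow(results) == 0) stop("empty results")
  results$q <- adjust_bh(results$p)
  results
}

#' @export
print.biomarker_screen <- function(x, ...) {
  cat("<biomarker_screen> ", nrow(x$table), " trait x timepoint tests, ",
      sum(x$table$q < 0.05), " with q < 0.05\n", sep = "")
  print(head(x$table[order(x$table$p), ], 10), digits = 3)
  invisible(x)
}
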