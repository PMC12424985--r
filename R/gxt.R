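#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their fractional ranks,
#' `qnorm((r - 3/8) / (n + 1/4))` (Blom offset), with ties given average
#' ranks and missing values preserved. Any strictly monotone transform of
#' the input yields identical output, which makes downstream model fits
#' invariant to the phenotype's measurement scale.
#'
#' @param x numeric vector (>= 3 non-missing values, not all equal).
#' @param offset rank offset (default 3/8).
#' @return Transformed vector of the same length, `NA`s preserved.
#' @export
#' @examples
#' rank_normal(c(10, 2, 7, NA, 5))
rank_normal <- function(x, offset = 3/8) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 non-missing values")
  if (length(unique(x[ok])) == 1L)
    stop("all values identical; rank-normal transform undefined")
  r <- rank(x[ok], ties.method = "average")
  out <- as.numeric(x)
  out[ok] <- qnorm((r - offset) / (n + 1 - 2 * offset))
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values (delegates to [stats::p.adjust()]), with input
#' validation.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p))) stop("p-values contain NA")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Genotype-by-treatment analysis of one phenotype
#'
#' Fits the full longitudinal mixed model on the rank-normalized outcome:
#' fixed diet x sex x timepoint interactions plus baseline (6-month) body
#' weight; random correlated strain intercept and diet slope
#' `(1 + diet | strain)` — the GxT term — plus mouse and collection-batch
#' intercepts where estimable. The GxT test drops the strain diet slope and
#' its correlation with the strain intercept (a 2-df REML likelihood-ratio
#' test against `(1 | strain)`), and `rho`, the fitted intercept-slope
#' correlation, reports whether long-lived / high-baseline strains respond
#' more or less to the intervention.
#'
#' @param phenotypes long phenotype table (`mouse_id`, `phenotype_name`,
#'   `timepoint_index`, `value`, `batch`).
#' @param animals animal table (`mouse_id`, `strain`, `sex`, `diet`,
#'   `bw6mo`).
#' @param phenotype name of the phenotype to analyze.
#' @param use_mouse,use_batch include `(1 | mouse_id)` / `(1 | batch)` when
#'   the data support them (default auto).
#' @return An object of class `gxt_result`: diet contrasts overall and
#'   within sex, GxT `statistic`/`p`, `rho`, and the full/reduced fits.
#' @export
run_gxt <- function(phenotypes, animals, phenotype,
                    use_mouse = TRUE, use_batch = TRUE) {
  ph <- phenotypes[phenotypes$phenotype_name == phenotype, , drop = FALSE]
  if (nrow(ph) == 0) stop("no rows for phenotype ", phenotype)
  d <- merge(ph, animals, by = "mouse_id")
  if (length(unique(d$diet)) < 2 || length(unique(d$strain)) < 2)
    stop("GxT needs >= 2 diets and >= 2 strains")
  d$diet <- factor(d$diet, levels = c("AL", "IF"))  # AL reference
  d$sex <- factor(d$sex)

  ## late timepoints can lose whole diet x sex cells to mortality, aliasing
  ## the three-way interaction; such timepoints are dropped with a report
  cell_n <- table(d$timepoint_index, d$diet, d$sex)
  ok_t <- apply(cell_n >= 2, 1, all)
  dropped <- rownames(cell_n)[!ok_t]
  if (length(dropped)) {
    message("dropping timepoint(s) with empty diet x sex cells: ",
            paste(dropped, collapse = ", "))
    d <- d[as.character(d$timepoint_index) %in% rownames(cell_n)[ok_t], ,
           drop = FALSE]
    if (nrow(d) == 0) stop("no timepoint has full diet x sex support")
  }
  d$timepoint <- factor(d$timepoint_index)
  d$y <- rank_normal(d$value)

  multi_t <- nlevels(d$timepoint) > 1
  fixed <- if (multi_t) "diet * sex * timepoint + bw6mo" else
    "diet * sex + bw6mo"
  rand <- "(1 + diet | strain)"
  if (use_mouse && multi_t && max(table(d$mouse_id)) >= 2)
    rand <- paste(rand, "+ (1 | mouse_id)")
  if (use_batch && !all(is.na(d$batch)) && length(unique(d$batch)) >= 2)
    rand <- paste(rand, "+ (1 | batch)")
  full_fm <- as.formula(paste("y ~", fixed, "+", rand))
  red_fm <- as.formula(paste("y ~", fixed, "+",
                             sub("(1 + diet | strain)", "(1 | strain)",
                                 rand, fixed = TRUE)))

  full <- fit_lmm(full_fm, d)
  if (stats::sigma(full$model) < 1e-8)
    stop("degenerate fit: residual variance is zero for ", phenotype)
  reduced <- fit_lmm(red_fm, d)
  lrt <- lrt_random(full, reduced)

  vc <- varcomp(full)
  rho <- vc$sdcor[vc$grp == "strain" & !is.na(vc$var2)]
  if (length(rho) == 0) rho <- NA_real_

  ctr_all <- contrast_means(full, "diet")
  ctr_sex <- contrast_means(full, "diet", by = "sex")
  structure(list(phenotype = phenotype,
                 p_diet = ctr_all$p[1],
                 diet_contrasts = ctr_all,
                 diet_contrasts_by_sex = ctr_sex,
                 gxt_statistic = lrt$statistic, gxt_df = lrt$df,
                 p_gxt = lrt$p, rho = rho,
                 fit = full, fit_reduced = reduced,
                 dropped_timepoints = dropped,
                 n_used = full$n_used),
            class = "gxt_result")
}

#' @export
print.gxt_result <- function(x, ...) {
  cat("<gxt_result> ", x$phenotype, " (n = ", x$n_used, ")\n", sep = "")
  cat(sprintf("  diet p = %.3g; GxT LRT = %.3f (df %d), p = %.3g; rho = %.3f\n",
              x$p_diet, x$gxt_statistic, x$gxt_df, x$p_gxt, x$rho))
  invisible(x)
}

#' Screen all phenotypes for diet and GxT effects
#'
#' Runs [run_gxt()] on each phenotype and applies Benjamini-Hochberg FDR
#' adjustment across phenotypes, separately for the diet contrast and the
#' GxT variance test.
#'
#' @inheritParams run_gxt
#' @param phenotype_names phenotypes to screen (default: all in the table).
#' @return List with `table` (one row per phenotype: `p_diet`, `q_diet`,
#'   `gxt_statistic`, `p_gxt`, `q_gxt`, `rho`) and `results` (the
#'   `gxt_result` objects).
#' @export
gxt_screen <- function(phenotypes, animals, phenotype_names = NULL, ...) {
  if (is.null(phenotype_names))
    phenotype_names <- unique(phenotypes$phenotype_name)
  res <- lapply(phenotype_names, function(p)
    run_gxt(phenotypes, animals, p, ...))
  names(res) <- phenotype_names
  tab <- data.frame(phenotype = phenotype_names,
                    p_diet = vapply(res, `[[`, 1, "p_diet"),
                    gxt_statistic = vapply(res, `[[`, 1, "gxt_statistic"),
                    p_gxt = vapply(res, `[[`, 1, "p_gxt"),
                    rho = vapply(res, `[[`, 1, "rho"),
                    row.names = NULL)
  tab$q_diet <- adjust_bh(tab$p_diet)
  tab$q_gxt <- adjust_bh(tab$p_gxt)
  list(table = tab, results = res)
}

#' Strain diet-effect scores from empirical-Bayes slopes
#'
#' For each phenotype fit, each strain's diet-effect score in a stratum is
#' the empirical-Bayes (BLUP) strain diet slope plus the population mean
#' diet response (IF minus AL model-based contrast) within that stratum, so
#' a score reads as "this strain's expected diet response". The scaled
#' variant z-scores each strain's scores across phenotypes within a stratum,
#' highlighting each strain's relative vulnerabilities.
#'
#' @param fits named list of `gxt_result` (or `lmm_fit`) objects, one per
#'   phenotype.
#' @param strata stratifying factor for the population contrast (default
#'   `"sex"`; `NULL` for a single overall stratum).
#' @return An object of class `diet_score_matrix`: `scores` and `scaled`,
#'   each a list (one per stratum level) of phenotype x strain matrices.
#' @export
diet_effect_scores <- function(fits, strata = "sex") {
  get_fit <- function(f) if (inherits(f, "gxt_result")) f$fit else f
  phen <- names(fits)
  if (is.null(phen)) phen <- paste0("phenotype_", seq_along(fits))
  one <- function(f) {
    fit <- get_fit(f)
    b <- blups(fit, "strain")
    slope_col <- grep("^diet", names(b), value = TRUE)
    slope_col <- slope_col[!grepl("\\.sd$", slope_col)][1]
    if (is.na(slope_col)) stop("fit has no strain diet-slope BLUPs")
    zeta <- setNames(b[[slope_col]], b$level)
    emm <- suppressMessages(emmeans::emmeans(
      fit$model, specs = ~diet, by = strata,
      lmer.df = "asymptotic", data = fit$data))
    ctr <- as.data.frame(suppressMessages(
      emmeans::contrast(emm, method = "revpairwise")))  # IF - AL
    pop <- if (is.null(strata)) c(overall = ctr$estimate[1]) else
      setNames(ctr$estimate, as.character(ctr[[strata]]))
    list(zeta = zeta, pop = pop)
  }
  parts <- lapply(fits, one)
  strains <- sort(unique(unlist(lapply(parts, function(p) names(p$zeta)))))
  strata_lev <- sort(unique(unlist(lapply(parts, function(p) names(p$pop)))))
  scores <- lapply(strata_lev, function(s) {
    m <- t(vapply(parts, function(p)
      p$zeta[strains] + if (s %in% names(p$pop)) p$pop[[s]] else NA_real_,
      numeric(length(strains))))
    dimnames(m) <- list(phen, strains)
    m
  })
  names(scores) <- strata_lev
  scaled <- lapply(scores, function(m) {
    if (nrow(m) < 2) return(m * NA)
    apply(m, 2, function(col) (col - mean(col)) / sd(col))
  })
  structure(list(scores = scores, scaled = scaled, strata = strata),
            class = "diet_score_matrix")
}

#' Cluster a diet-effect score matrix
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance) of
#' phenotypes (rows) and strains (columns). When several strata are
#' clustered for co-display, the row order is fixed from a designated
#' reference stratum and reused, so panels remain comparable. Missing
#' entries are mean-imputed with a flag; a constant matrix triggers a
#' degenerate-clustering warning and a single cluster.
#'
#' @param scores a `diet_score_matrix` or a plain phenotype x strain matrix.
#' @param k number of clusters for rows and columns (default 3).
#' @param reference_stratum stratum whose row order anchors the display
#'   (default: first).
#' @return An object of class `cluster_result`: `row_clusters`,
#'   `col_clusters`, `row_order`, `col_order`, `heights`, and for
#'   multi-stratum input the per-stratum column results.
#' @export
cluster_scores <- function(scores, k = 3, reference_stratum = NULL) {
  if (inherits(scores, "diet_score_matrix")) {
    strata <- names(scores$scaled)
    if (is.null(reference_stratum)) reference_stratum <- strata[1]
    ref <- cluster_scores(scores$scaled[[reference_stratum]], k = k)
    by_stratum <- lapply(scores$scaled, function(m)
      cluster_scores(m, k = k))
    ref$reference_stratum <- reference_stratum
    ref$by_stratum <- by_stratum
    return(ref)
  }
  m <- as.matrix(scores)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 rows and >= 2 columns")
  if (anyNA(m)) {
    warning("mean-imputing missing score entries")
    mu <- mean(m, na.rm = TRUE)
    m[is.na(m)] <- mu
  }
  if (sd(as.vector(m)) == 0) {
    warning("constant score matrix: degenerate clustering, single cluster")
    return(structure(list(
      row_clusters = setNames(rep(1L, nrow(m)), rownames(m)),
      col_clusters = setNames(rep(1L, ncol(m)), colnames(m)),
      row_order = seq_len(nrow(m)), col_order = seq_len(ncol(m)),
      heights = list(rows = numeric(0), cols = numeric(0))),
      class = "cluster_result"))
  }
  hr <- hclust(dist(m), method = "ward.D2")
  hc <- hclust(dist(t(m)), method = "ward.D2")
  structure(list(
    row_clusters = cutree(hr, k = min(k, nrow(m))),
    col_clusters = cutree(hc, k = min(k, ncol(m))),
    row_order = hr$order, col_order = hc$order,
    heights = list(rows = hr$height, cols = hc$height)),
    class = "cluster_result")
}

#' Select extreme-responder model strains
#'
#' Returns the strains with the maximum and minimum diet-effect score
#' (BLUP-based) for one phenotype — candidate mouse models of beneficial and
#' adverse intervention response. Ties are broken lexicographically by
#' strain label.
#'
#' @param scores named numeric vector of per-strain scores, or a
#'   phenotype x strain matrix with `phenotype` naming the row.
#' @param phenotype row name when `scores` is a matrix.
#' @return List with `max` and `min`, each `list(strain, score)`.
#' @export
select_model_strains <- function(scores, phenotype = NULL) {
  if (is.matrix(scores)) {
    if (is.null(phenotype)) stop("phenotype required with a score matrix")
    scores <- scores[phenotype, ]
  }
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2) stop("need scores for >= 2 strains")
  ord <- order(scores, names(scores))  # lexicographic tie-break
  lo <- ord[1]
  hi_val <- max(scores)
  hi <- which(scores == hi_val)
  hi <- hi[order(names(scores)[hi])][1]
  list(max = list(strain = names(scores)[hi], score = scores[[hi]]),
       min = list(strain = names(scores)[lo], score = scores[[lo]]))
}
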