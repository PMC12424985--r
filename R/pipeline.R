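#' Run the full analysis pipeline on a simulated cohort
#'
#' Generates a cohort from the configuration and runs every analysis stage:
#' lifespan analysis (strain medians, log-rank, stratified Cox, RMST by sex,
#' CV comparison), heritability (broad-sense, and narrow-sense with the
#' cohort's kinship matrix), the per-phenotype GxT screen with strain
#' diet-effect scores, clustering and model-strain selection, body-weight
#' and frailty trajectory summaries, the longevity-biomarker screen, and
#' the temperature inflection analysis. All randomness flows from the
#' config seed, so two runs with the same config produce identical results.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, result tables are written
#'   as CSV and headline numbers as `summary.json`.
#' @return A list of per-stage results (see the vignette for a tour).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  bundle <- simulate_cohort(config)
  an <- bundle$animals

  ## --- lifespan ---------------------------------------------------------
  km_strain <- km_fit(an, group = "strain")
  medians <- survival_quantile(km_strain, 0.5)
  q90 <- survival_quantile(km_strain, 0.9)
  lr_strain <- logrank(an, "strain")
  cox <- cox_fit(an, ~ diet * sex, strata = "strain")
  rmst_m <- rmst_diff(an[an$sex == "M", ], group = "diet")
  rmst_f <- rmst_diff(an[an$sex == "F", ], group = "diet")
  cv <- suppressWarnings(cv_compare(an))

  ## --- heritability -----------------------------------------------------
  H2 <- estimate_H2(an)
  h2 <- estimate_h2(an, bundle$kinship)

  ## --- GxT screen on the generic assay phenotypes -----------------------
  generic <- grep("^pheno_", unique(bundle$phenotypes$phenotype_name),
                  value = TRUE)
  gxt <- gxt_screen(bundle$phenotypes, an, generic)
  scores <- diet_effect_scores(gxt$results)
  clusters <- if (length(generic) >= 2 && config$n_strains >= 2)
    cluster_scores(scores) else NULL
  sel <- select_model_strains(scores$scores[[1]], generic[1])

  ## --- trajectories -----------------------------------------------------
  wt <- weight_trait_table(bundle$phenotypes)
  life_weeks <- setNames(an$lifespan_months * WEEKS_PER_MONTH, an$mouse_id)
  fi <- do.call(rbind, lapply(split(bundle$frailty, bundle$frailty$mouse_id),
    function(fa) {
      s <- fi_summaries(fa, life_weeks[[fa$mouse_id[1]]])
      data.frame(mouse_id = fa$mouse_id[1], fi_slope = s$fi_slope,
                 final_fi = s$final_fi)
    }))
  rownames(fi) <- NULL
  incidence <- deficit_incidence(bundle$frailty, an)

  ## --- biomarkers -------------------------------------------------------
  biomarkers <- biomarker_screen(bundle$phenotypes, an)

  ## --- temperature ------------------------------------------------------
  tp <- bundle$phenotypes[bundle$phenotypes$phenotype_name == "temperature", ]
  tp <- merge(tp, an, by = "mouse_id")
  tp$pll <- tp$age_weeks / (tp$lifespan_months * WEEKS_PER_MONTH)
  tp$value_t <- tp$value
  infl <- locate_inflection(tp$pll, tp$value)

  res <- list(bundle = bundle,
              lifespan = list(median_by_strain = medians, q90_by_strain = q90,
                              logrank_strain = lr_strain, cox = cox,
                              rmst_male = rmst_m, rmst_female = rmst_f,
                              cv = cv),
              heritability = list(H2 = H2, h2 = h2),
              gxt = gxt, scores = scores, clusters = clusters,
              selected_strains = sel,
              trajectories = list(weights = wt, frailty = fi,
                                  incidence = incidence),
              biomarkers = biomarkers,
              inflection = infl)
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

## plain-text export of the pipeline tables; deterministic given the results
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) write.csv(d, file.path(out_dir, f), row.names = FALSE)
  wr(res$gxt$table, "gxt_results.csv")
  wr(res$trajectories$weights, "weight_summaries.csv")
  wr(res$trajectories$frailty, "fi_summaries.csv")
  wr(res$trajectories$incidence, "incidence.csv")
  wr(res$biomarkers$table, "biomarkers.csv")
  wr(data.frame(strain = names(res$lifespan$median_by_strain),
                median = res$lifespan$median_by_strain,
                q90 = res$lifespan$q90_by_strain), "lifespan_quantiles.csv")
  for (s in names(res$scores$scores))
    wr(data.frame(phenotype = rownames(res$scores$scores[[s]]),
                  res$scores$scores[[s]], check.names = FALSE),
       paste0("scores_", s, ".csv"))
  summary <- list(
    H2 = res$heritability$H2$estimate,
    h2 = res$heritability$h2$estimate,
    rmst_diff_male = res$lifespan$rmst_male$difference,
    rmst_diff_female = res$lifespan$rmst_female$difference,
    logrank_strain_p = res$lifespan$logrank_strain$p,
    cv_wilcoxon_p = res$lifespan$cv$p,
    inflection_pll = res$inflection$pll_star,
    selected_max = res$selected_strains$max$strain,
    selected_min = res$selected_strains$min$strain)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
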