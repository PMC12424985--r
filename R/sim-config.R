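#' Simulation configuration for a strain-panel cohort
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults
#' reproduce the design of a 10-strain longitudinal fasting study: 10 inbred
#' strains x 2 sexes x 2 diets with 20 mice per cell (800 mice), lifespans
#' with about a quarter of their variance attributable to strain, a modest
#' male-specific diet benefit, and phenotypes whose strain-specific diet
#' slopes are negatively correlated with the strain intercepts.
#'
#' Lifespans are measured in months, phenotype sampling ages in weeks.
#' Under the `"gaussian"` lifespan model `lifespan_params` needs `mean`,
#' `strain_sd` and `resid_sd` (months) plus optional fixed effects
#' `sex_effect`, `diet_effect`, `sex_by_diet`; under `"gompertz"` it needs a
#' baseline hazard `rate` (per month), a `shape` (log-hazard slope per month)
#' and `strain_frailty_sd` (SD of strain log-hazard offsets).
#'
#' @param n_strains number of inbred strains (>= 2).
#' @param mice_per_cell mice per strain x sex x diet cell (>= 1).
#' @param n_phenotypes number of generic longitudinal phenotypes to simulate.
#' @param strain_sd SD of strain phenotype intercepts (phenotype SD units).
#' @param diet_slope_sd SD of strain-specific diet effects.
#' @param intercept_slope_corr correlation between strain intercepts and
#'   strain diet slopes, in `[-1, 1]`; the generative counterpart of the
#'   intercept-slope correlation rho reported by the GxT screen.
#' @param sex_effect,diet_effect,sex_by_diet fixed effects on the generic
#'   phenotypes (male, fasting-diet, and male-by-fasting contrasts).
#' @param residual_sd residual SD of the generic phenotypes.
#' @param batch_sd SD of collection-batch intercepts.
#' @param lifespan_model `"gaussian"` (matching the heritability analysis
#'   model) or `"gompertz"` (log-hazard strain frailty).
#' @param lifespan_params named list, see Details.
#' @param censoring_rate probability that a mouse is administratively
#'   censored late in life, in `[0, 1)`. Default 0: euthanized or found-dead
#'   animals are recorded as deaths.
#' @param timepoint_schedule strictly increasing ages (weeks) at which the
#'   generic phenotypes are assayed.
#' @param seed integer seed; all randomness flows from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_strains = 4, mice_per_cell = 5, seed = 1)
#' cfg$n_strains
sim_config <- function(n_strains = 10,
                       mice_per_cell = 20,
                       n_phenotypes = 4,
                       strain_sd = 1,
                       diet_slope_sd = 0.5,
                       intercept_slope_corr = -0.4,
                       sex_effect = 0.5,
                       diet_effect = -0.3,
                       sex_by_diet = 0.2,
                       residual_sd = 1,
                       batch_sd = 0.3,
                       lifespan_model = c("gaussian", "gompertz"),
                       lifespan_params = NULL,
                       censoring_rate = 0,
                       timepoint_schedule = c(45, 97, 149),
                       seed = 1L) {
  lifespan_model <- match.arg(lifespan_model)
  if (is.null(lifespan_params)) {
    lifespan_params <- if (lifespan_model == "gaussian") {
      ## mean 23 mo, total SD ~5.7 mo (CV ~ 0.25), strain share 0.25 of
      ## variance; +1.7 mo median benefit concentrated in fasting males
      list(mean = 23, strain_sd = 2.87, resid_sd = 4.97,
           sex_effect = 2, diet_effect = 0.3, sex_by_diet = 1.4)
    } else {
      list(rate = 1.4e-3, shape = 0.2, strain_frailty_sd = 0.5,
           sex_effect = -0.3, diet_effect = -0.05, sex_by_diet = -0.15)
    }
  }
  cfg <- list(n_strains = as.integer(n_strains),
              mice_per_cell = as.integer(mice_per_cell),
              n_phenotypes = as.integer(n_phenotypes),
              strain_sd = strain_sd, diet_slope_sd = diet_slope_sd,
              intercept_slope_corr = intercept_slope_corr,
              sex_effect = sex_effect, diet_effect = diet_effect,
              sex_by_diet = sex_by_diet,
              residual_sd = residual_sd, batch_sd = batch_sd,
              lifespan_model = lifespan_model,
              lifespan_params = lifespan_params,
              censoring_rate = censoring_rate,
              timepoint_schedule = as.numeric(timepoint_schedule),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_strains >= 2, cfg$mice_per_cell >= 1, cfg$n_phenotypes >= 1)
  sds <- c(cfg$strain_sd, cfg$diet_slope_sd, cfg$residual_sd, cfg$batch_sd)
  if (any(sds < 0)) stop("all SD parameters must be >= 0")
  if (abs(cfg$intercept_slope_corr) > 1)
    stop("intercept_slope_corr must lie in [-1, 1]")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    stop("censoring_rate must lie in [0, 1)")
  if (length(cfg$timepoint_schedule) < 1 ||
      is.unsorted(cfg$timepoint_schedule, strictly = TRUE))
    stop("timepoint_schedule must be strictly increasing")
  if (cfg$lifespan_model == "gompertz") {
    lp <- cfg$lifespan_params
    if (is.null(lp$rate) || is.null(lp$shape) || lp$rate <= 0 || lp$shape <= 0)
      stop("gompertz lifespan model needs positive 'rate' and 'shape'")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_strains, " strains x 2 sexes x 2 diets x ",
      x$mice_per_cell, " mice (n = ", x$n_strains * 4 * x$mice_per_cell,
      ")\n", sep = "")
  cat("  lifespan model: ", x$lifespan_model,
      "; censoring rate: ", x$censoring_rate, "\n", sep = "")
  cat("  strain SD ", x$strain_sd, ", diet-slope SD ", x$diet_slope_sd,
      ", intercept-slope corr ", x$intercept_slope_corr, "\n", sep = "")
  cat("  schedule (weeks): ", paste(x$timepoint_schedule, collapse = ", "),
      "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

## months <-> weeks on the civil calendar (365.25/12 days per month)
WEEKS_PER_MONTH <- 365.25 / 12 / 7
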