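#' Generate the animal table of a synthetic cohort
#'
#' Builds a balanced strain x sex x diet cohort with lifespans drawn under
#' the configured lifespan model. Under `"gaussian"` the lifespan is a linear
#' mixed model draw (fixed sex/diet/sex-by-diet effects, strain random
#' intercept, residual), the generative counterpart of the random-intercept
#' model used for heritability estimation. Under `"gompertz"` each strain
#' carries a log-hazard frailty offset and death times come from the Gompertz
#' inverse CDF. Administrative censoring, when requested, truncates follow-up
#' uniformly over the last 40% of a mouse's life.
#'
#' @param config a [sim_config()].
#' @return A `cohort_bundle`: list with `animals` (data frame), `kinship`,
#'   `truth` (realized strain effects and variance fractions) and `config`.
#' @export
#' @examples
#' ch <- generate_cohort(sim_config(n_strains = 4, mice_per_cell = 3, seed = 1))
#' head(ch$animals)
generate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  kinship <- generate_kinship(cfg$n_strains, seed = cfg$seed)
  strains <- rownames(kinship)

  set.seed(cfg$seed + 1L)
  cells <- expand.grid(strain = strains, sex = c("F", "M"),
                       diet = c("AL", "IF"), stringsAsFactors = FALSE)
  animals <- cells[rep(seq_len(nrow(cells)), each = cfg$mice_per_cell), ]
  n <- nrow(animals)
  animals$mouse_id <- sprintf("M%04d", seq_len(n))
  ## 4 mice per cage within strain x sex x diet
  animals$cage <- paste0(animals$strain, "_", animals$sex, "_", animals$diet,
                         "_c", ceiling(seq_len(cfg$mice_per_cell) / 4))
  is_m <- animals$sex == "M"
  is_if <- animals$diet == "IF"

  lp <- cfg$lifespan_params
  fx <- function(nm) if (is.null(lp[[nm]])) 0 else lp[[nm]]
  eta_fixed <- fx("sex_effect") * is_m + fx("diet_effect") * is_if +
    fx("sex_by_diet") * (is_m & is_if)

  if (cfg$lifespan_model == "gaussian") {
    u <- rnorm(cfg$n_strains, 0, lp$strain_sd)
    names(u) <- strains
    eps <- rnorm(n, 0, lp$resid_sd)
    death <- pmax(1, lp$mean + eta_fixed + u[animals$strain] + eps)
    realized <- c(strain_var = var(u[animals$strain]), resid_var = var(eps))
  } else {
    u <- rnorm(cfg$n_strains, 0, lp$strain_frailty_sd)
    names(u) <- strains
    eta <- eta_fixed + u[animals$strain]
    ## inverse-CDF draw: S(t) = exp(-(a e^eta / b)(e^{bt} - 1))
    uu <- runif(n)
    death <- log1p(-cfg$lifespan_params$shape * log(uu) /
                     (lp$rate * exp(eta))) / lp$shape
    death <- pmax(death, 0.5)
    realized <- c(strain_frailty_var = var(u[animals$strain]))
  }

  event <- rep(1L, n)
  time <- death
  if (cfg$censoring_rate > 0) {
    cens <- runif(n) < cfg$censoring_rate
    ctime <- death * runif(n, 0.6, 1)
    time[cens] <- ctime[cens]
    event[cens] <- 0L
  }
  animals$lifespan_months <- time
  animals$event_observed <- event

  ## 6-month body weight (grams): sexes differ, strains differ; diet has not
  ## started yet so it contributes nothing
  bw_strain <- rnorm(cfg$n_strains, 0, 2)
  names(bw_strain) <- strains
  animals$bw6mo <- 32 + 6 * is_m + bw_strain[animals$strain] + rnorm(n, 0, 2)

  rownames(animals) <- NULL
  animals <- animals[, c("mouse_id", "strain", "sex", "diet", "cage",
                         "lifespan_months", "event_observed", "bw6mo")]
  truth <- list(config = unclass(cfg),
                strain_lifespan_effect = u,
                strain_bw_offset = bw_strain,
                realized = realized)
  structure(list(animals = animals, kinship = kinship,
                 truth = truth, config = cfg),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> ", nrow(x$animals), " mice, ",
      x$config$n_strains, " strains\n", sep = "")
  if (!is.null(x$phenotypes))
    cat("  phenotypes: ", length(unique(x$phenotypes$phenotype_name)),
        " (", nrow(x$phenotypes), " rows)\n", sep = "")
  if (!is.null(x$frailty))
    cat("  frailty assessments: ", nrow(x$frailty), "\n", sep = "")
  invisible(x)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: [generate_cohort()] followed by
#' [generate_phenotypes()].
#'
#' @inheritParams generate_cohort
#' @return A `cohort_bundle` with animals, longitudinal phenotypes, weekly
#'   body weight, body temperature, frailty items, kinship and ground truth.
#' @export
simulate_cohort <- function(config) {
  generate_phenotypes(generate_cohort(config), config)
}

#' Write a cohort bundle to plain-text files
#'
#' Writes `animals.csv`, `phenotypes.csv` (long format), `frailty.csv`,
#' `kinship.csv` and `truth.json` into a directory.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$animals, file.path(dir, "animals.csv"), row.names = FALSE)
  if (!is.null(bundle$phenotypes))
    write.csv(bundle$phenotypes, file.path(dir, "phenotypes.csv"),
              row.names = FALSE)
  if (!is.null(bundle$frailty))
    write.csv(bundle$frailty, file.path(dir, "frailty.csv"), row.names = FALSE)
  write.csv(data.frame(strain = rownames(bundle$kinship), bundle$kinship,
                       check.names = FALSE),
            file.path(dir, "kinship.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
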