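#' Simulate longitudinal phenotypes onto a cohort
#'
#' Adds to the bundle (i) `n_phenotypes` generic assay phenotypes measured at
#' the scheduled ages, (ii) a week-dense body-weight series, (iii) body
#' temperature at five visit ages with a two-segment decline whose knee sits
#' at 80% of life lived, and (iv) 27 ordinal frailty items driven by a shared
#' latent deficit process increasing in proportion of life lived (PLL).
#'
#' Each generic phenotype value is
#' grand mean + sex + diet + sex-by-diet + strain intercept +
#' strain diet slope (for fasting mice) + collection-batch effect + residual,
#' with the strain (intercept, slope) pairs drawn jointly at correlation
#' `intercept_slope_corr`. Rows exist only while the mouse is alive
#' (structural attrition): a measurement at `age_weeks` requires
#' `age_weeks <= lifespan`.
#'
#' @param cohort a `cohort_bundle` from [generate_cohort()].
#' @param config the same [sim_config()] used to build the cohort.
#' @return The augmented `cohort_bundle` with elements `phenotypes`
#'   (long data frame: `mouse_id`, `phenotype_name`, `timepoint_index`,
#'   `age_weeks`, `value`, `batch`), `frailty` (wide data frame of item
#'   scores in \{0, 0.5, 1\}) and expanded `truth`.
#' @export
generate_phenotypes <- function(cohort, config = cohort$config) {
  validate_sim_config(config)
  cfg <- config
  if (length(cfg$timepoint_schedule) == 0) stop("empty timepoint schedule")
  an <- cohort$animals
  set.seed(cfg$seed + 2L)

  life_weeks <- an$lifespan_months * WEEKS_PER_MONTH
  is_m <- an$sex == "M"
  is_if <- an$diet == "IF"
  strains <- rownames(cohort$kinship)
  ns <- length(strains)
  rho <- cfg$intercept_slope_corr

  ## --- generic assay phenotypes at the scheduled ages -------------------
  sched <- cfg$timepoint_schedule
  n_b <- 3L  # collection-date batches per scheduled visit
  pheno_rows <- vector("list", cfg$n_phenotypes)
  true_int <- true_slope <- matrix(NA_real_, ns, cfg$n_phenotypes,
                                   dimnames = list(strains, NULL))
  ## batch membership: a collection date per mouse per visit, shared by assays
  batch_of <- matrix(sample.int(n_b, nrow(an) * length(sched), replace = TRUE),
                     nrow(an), length(sched))
  for (k in seq_len(cfg$n_phenotypes)) {
    z1 <- rnorm(ns); z2 <- rnorm(ns)
    a_j <- cfg$strain_sd * z1
    b_j <- cfg$diet_slope_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    names(a_j) <- names(b_j) <- strains
    true_int[, k] <- a_j
    true_slope[, k] <- b_j
    b_eff <- matrix(rnorm(n_b * length(sched), 0, cfg$batch_sd),
                    n_b, length(sched))
    rows <- lapply(seq_along(sched), function(t) {
      alive <- life_weeks >= sched[t]
      if (!any(alive)) return(NULL)
      i <- which(alive)
      bt <- batch_of[i, t]
      val <- cfg$sex_effect * is_m[i] + cfg$diet_effect * is_if[i] +
        cfg$sex_by_diet * (is_m[i] & is_if[i]) +
        a_j[an$strain[i]] + b_j[an$strain[i]] * is_if[i] +
        b_eff[cbind(bt, t)] + rnorm(length(i), 0, cfg$residual_sd)
      data.frame(mouse_id = an$mouse_id[i],
                 phenotype_name = sprintf("pheno_%02d", k),
                 timepoint_index = t, age_weeks = sched[t], value = val,
                 batch = sprintf("t%d_b%d", t, bt))
    })
    pheno_rows[[k]] <- do.call(rbind, rows)
  }
  pheno <- do.call(rbind, pheno_rows)

  ## --- weekly body weight: rise to peak at 40% PLL, gentle decline,
  ##     terminal drop over the last 10% of life ------------------------
  peak <- an$bw6mo * 1.25 * ifelse(is_if, 0.94, 1)
  bw_rows <- lapply(seq_len(nrow(an)), function(i) {
    wk <- seq(4, floor(life_weeks[i]))
    if (length(wk) == 0) return(NULL)
    p <- wk / life_weeks[i]
    w <- ifelse(p <= 0.4, peak[i] * (0.75 + 0.25 * p / 0.4),
         ifelse(p <= 0.9, peak[i] * (1 - 0.10 * (p - 0.4) / 0.5),
                          peak[i] * (0.90 - 0.15 * (p - 0.9) / 0.1)))
    data.frame(mouse_id = an$mouse_id[i], phenotype_name = "body_weight",
               timepoint_index = seq_along(wk), age_weeks = wk,
               value = w + rnorm(length(wk), 0, 0.4), batch = NA_character_)
  })
  bw <- do.call(rbind, bw_rows)

  ## --- body temperature at the five visit ages; knee at PLL = 0.8 ------
  visit_weeks <- c(21, 43, 95, 121, 147)
  t_strain <- rnorm(ns, 0, 0.15); names(t_strain) <- strains
  tmp_rows <- lapply(seq_along(visit_weeks), function(t) {
    alive <- life_weeks >= visit_weeks[t]
    if (!any(alive)) return(NULL)
    i <- which(alive)
    p <- visit_weeks[t] / life_weeks[i]
    val <- 37.5 + 0.2 * is_m[i] + t_strain[an$strain[i]] -
      0.5 * p - 4 * pmax(p - 0.8, 0) + rnorm(length(i), 0, 0.2)
    data.frame(mouse_id = an$mouse_id[i], phenotype_name = "temperature",
               timepoint_index = t, age_weeks = visit_weeks[t], value = val,
               batch = sprintf("t%d_b%d", t, batch_of[i, min(t, ncol(batch_of))]))
  })
  tmp <- do.call(rbind, tmp_rows)

  phenotypes <- rbind(pheno, bw, tmp)
  rownames(phenotypes) <- NULL

  ## --- frailty: 27 items, shared latent linear in PLL, cut into ordinal
  ##     scores {0, 0.5, 1} ----------------------------------------------
  n_items <- 27L
  loading <- runif(n_items, 0.7, 1.3)
  f_strain <- rnorm(ns, 0, 0.3); names(f_strain) <- strains
  f_mouse <- rnorm(nrow(an), 0, 0.3)
  fr_rows <- lapply(seq_along(visit_weeks), function(t) {
    alive <- life_weeks >= visit_weeks[t]
    if (!any(alive)) return(NULL)
    i <- which(alive)
    p <- visit_weeks[t] / life_weeks[i]
    lat <- -1 + 2.5 * p + f_strain[an$strain[i]] + f_mouse[i] +
      rnorm(length(i), 0, 0.2)
    items <- vapply(seq_len(n_items), function(j) {
      lj <- loading[j] * lat + rnorm(length(i), 0, 0.3)
      ifelse(lj < 0.5, 0, ifelse(lj < 1.2, 0.5, 1))
    }, numeric(length(i)))
    if (!is.matrix(items)) items <- matrix(items, nrow = length(i))
    colnames(items) <- sprintf("item%02d", seq_len(n_items))
    data.frame(mouse_id = an$mouse_id[i], visit = t,
               age_weeks = visit_weeks[t], items)
  })
  frailty <- do.call(rbind, fr_rows)
  rownames(frailty) <- NULL

  realized_corr <- if (ns >= 3) {
    mean(vapply(seq_len(cfg$n_phenotypes), function(k)
      if (sd(true_int[, k]) > 0 && sd(true_slope[, k]) > 0)
        stats::cor(true_int[, k], true_slope[, k]) else NA_real_,
      numeric(1)), na.rm = TRUE)
  } else NA_real_

  cohort$phenotypes <- phenotypes
  cohort$frailty <- frailty
  cohort$truth$strain_intercepts <- true_int
  cohort$truth$strain_diet_slopes <- true_slope
  cohort$truth$realized_intercept_slope_corr <- realized_corr
  cohort
}
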