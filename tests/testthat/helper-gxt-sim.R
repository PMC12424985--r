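# one GxT replicate at a single assay visit: simulate a cohort phenotype,
# fit the full and slope-free mixed models on the rank-normalized outcome,
# and return the variance-LRT p, fitted rho, slope BLUPs and planted slopes
gxt_replicate <- function(slope_sd, seed, mice_per_cell = 4, n_strains = 10,
                          strain_sd = 1, residual_sd = 1, rho = -0.4) {
  cfg <- sim_config(n_strains = n_strains, mice_per_cell = mice_per_cell,
                    n_phenotypes = 1, strain_sd = strain_sd,
                    diet_slope_sd = slope_sd, intercept_slope_corr = rho,
                    residual_sd = residual_sd,
                    timepoint_schedule = c(45), seed = seed)
  b <- simulate_cohort(cfg)
  d <- merge(b$phenotypes[b$phenotypes$phenotype_name == "pheno_01", ],
             b$animals, by = "mouse_id")
  d$diet <- factor(d$diet, levels = c("AL", "IF"))
  d$y <- rank_normal(d$value)
  full <- fit_lmm(y ~ diet * sex + bw6mo + (1 + diet | strain) + (1 | batch),
                  d)
  red <- fit_lmm(y ~ diet * sex + bw6mo + (1 | strain) + (1 | batch), d)
  lrt <- lrt_random(full, red)
  vc <- varcomp(full)
  rho_hat <- vc$sdcor[vc$grp == "strain" & !is.na(vc$var2)]
  bl <- blups(full, "strain")
  list(p = lrt$p, df = lrt$df, rho = rho_hat,
       blup_slopes = setNames(bl$dietIF, bl$level),
       true_slopes = b$truth$strain_diet_slopes[, 1])
}
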