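test_that("rank-normal transform matches the Blom quantile oracle", {
  x <- c(4, 1, 9)
  got <- rank_normal(x)
  expect_equal(got, qnorm((c(2, 1, 3) - 3/8) / 3.25))

  ## strictly monotone in the input among untied values
  set.seed(2)
  x2 <- rnorm(40)
  expect_identical(order(rank_normal(x2)), order(x2))

  ## monotone transforms leave the output unchanged (pipeline invariance)
  expect_equal(rank_normal(exp(x2)), rank_normal(x2))

  ## antisymmetry of the normal quantile: out(r) = -out(n + 1 - r)
  y <- rank_normal(1:9)
  expect_equal(y, -rev(y))

  ## ties share the average-rank value; NAs pass through
  z <- rank_normal(c(5, 5, 1, NA, 9))
  expect_equal(z[1], z[2])
  expect_true(is.na(z[4]))

  expect_error(rank_normal(c(1, 2)), "at least 3")
  expect_error(rank_normal(rep(7, 10)), "identical")
})

test_that("BH adjustment equals the independent step-up oracle", {
  expect_equal(adjust_bh(0.03), 0.03)  # m = 1
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(7)
  for (rep in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- adjust_bh(p)
    expect_equal(q, bh_stepup(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_false(is.unsorted(q[order(p)]))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the GxT screen recovers a planted negative intercept-slope
           correlation and flags degenerate input", {
  cfg <- sim_config(n_strains = 10, mice_per_cell = 8, n_phenotypes = 2,
                    strain_sd = 1, diet_slope_sd = 1,
                    intercept_slope_corr = -0.8, residual_sd = 0.5,
                    timepoint_schedule = c(45), seed = 19)
  b <- simulate_cohort(cfg)
  g <- run_gxt(b$phenotypes, b$animals, "pheno_01")
  expect_lt(g$rho, 0)
  expect_lt(g$p_gxt, 0.05)
  expect_equal(g$gxt_df, 2)
  expect_true(g$p_diet >= 0 && g$p_diet <= 1)
  expect_equal(nrow(g$diet_contrasts_by_sex), 2)

  ## noiseless phenotype the fixed effects fit exactly: loud failure, never
  ## silent output
  ph <- b$phenotypes[b$phenotypes$phenotype_name == "pheno_01", ]
  key <- merge(ph, b$animals)
  ph$value <- as.numeric(key$diet == "IF")
  suppressWarnings(
    expect_error(run_gxt(ph, b$animals, "pheno_01"), "degenerate|singular"))
})

test_that("gxt_screen adjusts across phenotypes with BH", {
  cfg <- sim_config(n_strains = 6, mice_per_cell = 4, n_phenotypes = 3,
                    timepoint_schedule = c(45), seed = 23)
  b <- simulate_cohort(cfg)
  scr <- gxt_screen(b$phenotypes, b$animals,
                    c("pheno_01", "pheno_02", "pheno_03"))
  expect_equal(scr$table$q_diet, bh_stepup(scr$table$p_diet))
  expect_equal(scr$table$q_gxt, bh_stepup(scr$table$p_gxt))
  expect_true(all(abs(scr$table$rho) <= 1, na.rm = TRUE))
})

test_that("diet-effect scores are BLUP plus population contrast, with the
           scaled variant z-scored within strain", {
  cfg <- sim_config(n_strains = 8, mice_per_cell = 6, n_phenotypes = 3,
                    strain_sd = 1, diet_slope_sd = 0.8,
                    timepoint_schedule = c(45), seed = 29)
  b <- simulate_cohort(cfg)
  scr <- gxt_screen(b$phenotypes, b$animals,
                    c("pheno_01", "pheno_02", "pheno_03"))
  sc <- diet_effect_scores(scr$results)
  expect_setequal(names(sc$scores), c("F", "M"))

  ## delegation identity: entry = strain slope BLUP + within-sex contrast
  fit <- scr$results$pheno_01$fit
  bl <- blups(fit, "strain")
  emm <- emmeans::emmeans(fit$model, ~ diet, by = "sex",
                          lmer.df = "asymptotic", data = fit$data)
  ctr <- as.data.frame(emmeans::contrast(emm, "revpairwise"))
  for (s in c("F", "M")) {
    manual <- setNames(bl$dietIF, bl$level) +
      ctr$estimate[ctr$sex == s]
    expect_equal(sc$scores[[s]]["pheno_01", names(manual)], manual,
                 tolerance = 1e-8)
  }

  ## scaled variant: per-strain mean 0, SD 1 across phenotypes
  z <- sc$scaled$F
  expect_equal(unname(colMeans(z)), rep(0, ncol(z)), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, ncol(z)), tolerance = 1e-12)
})

test_that("scores collapse to the population contrast under full shrinkage", {
  ## per-strain diet contrasts made exactly equal (symmetric within-cell
  ## noise), so the slope variance estimate hits the zero boundary, slope
  ## BLUPs vanish, and every strain's score is the population contrast
  ns <- 6; per <- 4
  strain <- factor(rep(sprintf("CC%02d", 1:ns), each = 2 * per))
  diet <- factor(rep(rep(c("AL", "IF"), each = per), ns),
                 levels = c("AL", "IF"))
  a <- seq(-1, 1, length.out = ns)
  delta <- 0.6
  noise <- rep(c(-0.3, 0.3, -0.1, 0.1), 2 * ns)  # cell means stay exact
  d <- data.frame(strain, diet,
                  y = a[as.integer(strain)] + delta * (diet == "IF") + noise)
  fit <- fit_lmm(y ~ diet + (1 + diet | strain), d)
  vc <- varcomp(fit)
  expect_lt(vc$vcov[vc$grp == "strain" & vc$var1 == "dietIF" &
                      is.na(vc$var2)], 1e-10)
  sc <- diet_effect_scores(list(toy = fit), strata = NULL)
  expect_equal(unname(sc$scores$overall["toy", ]), rep(delta, ns),
               tolerance = 1e-6)
})

test_that("Ward clustering recovers planted blocks deterministically", {
  set.seed(3)
  base <- matrix(0, 9, 6)
  base[1:3, ] <- rep(c(2, 0, -2), each = 3)
  base[4:6, ] <- rep(c(-2, 2, 0), each = 3)
  m <- base + matrix(rnorm(54, 0, 0.1), 9, 6)
  rownames(m) <- paste0("p", 1:9); colnames(m) <- paste0("s", 1:6)
  cl <- cluster_scores(m, k = 3)
  expect_equal(length(unique(cl$row_clusters[1:3])), 1)
  expect_equal(length(unique(cl$row_clusters[4:6])), 1)
  expect_equal(length(unique(cl$row_clusters[7:9])), 1)
  expect_equal(length(unique(cl$row_clusters)), 3)

  ## identical rows always co-cluster; repeated runs identical
  m2 <- m; m2[2, ] <- m2[1, ]
  cl2 <- cluster_scores(m2, k = 3)
  expect_equal(cl2$row_clusters[1], cl2$row_clusters[2], ignore_attr = TRUE)
  expect_identical(cluster_scores(m, k = 3), cluster_scores(m, k = 3))

  expect_warning(cluster_scores(matrix(1, 3, 3)), "degenerate")
})

test_that("model-strain selection is an argmax/argmin with lexicographic ties", {
  expect_identical(
    select_model_strains(c(A = -1, B = 0, C = 2))[c("max", "min")],
    list(max = list(strain = "C", score = 2),
         min = list(strain = "A", score = -1)))

  tie <- select_model_strains(c(B = 1, A = 1, C = 0))
  expect_equal(tie$max$strain, "A")

  set.seed(9)
  for (i in 1:20) {
    v <- setNames(rnorm(8), sample(LETTERS, 8))
    sel <- select_model_strains(v)
    expect_equal(sel$max$score, max(v))
    expect_equal(sel$min$score, min(v))
  }
})
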