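make_oneway <- function(g = 6, reps = 8, s_u = 1.3, s_e = 0.9, seed = 1,
                        mu = 5) {
  set.seed(seed)
  grp <- gl(g, reps, labels = sprintf("g%02d", seq_len(g)))
  u <- rnorm(g, 0, s_u)
  data.frame(y = mu + u[as.integer(grp)] + rnorm(g * reps, 0, s_e),
             grp = grp)
}

test_that("a formula without random terms reduces to OLS", {
  set.seed(2)
  d <- data.frame(y = rnorm(30), x = rnorm(30), f = gl(3, 10))
  fit <- fit_lmm(y ~ x + f, d)
  ols <- lm(y ~ x + f, d)
  expect_equal(coef(fit$model), coef(ols))
  expect_s3_class(fit$model, "lm")
})

test_that("balanced one-way REML matches the ANOVA mean-squares closed form", {
  for (seed in 1:4) {
    d <- make_oneway(g = 8, reps = 6, seed = seed)
    fit <- fit_lmm(y ~ 1 + (1 | grp), d)
    vc <- varcomp(fit)
    ms <- anova(lm(y ~ grp, d))
    msb <- ms["grp", "Mean Sq"]; msw <- ms["Residuals", "Mean Sq"]
    expect_equal(vc$vcov[vc$grp == "grp"], max(0, (msb - msw) / 6),
                 tolerance = 1e-8)
    expect_equal(vc$vcov[vc$grp == "Residual"], msw, tolerance = 1e-8)
  }
})

test_that("REML log-likelihood equals the dense-covariance evaluation", {
  set.seed(7)
  for (rep in 1:5) {
    g <- sample(4:8, 1); reps <- sample(4:8, 1)
    d <- make_oneway(g, reps, seed = 100 + rep)
    d$x <- rnorm(nrow(d))
    d$y <- d$y + 0.4 * d$x
    fit <- fit_lmm(y ~ x + (1 | grp), d)
    V <- dense_V_from_fit(fit)
    ll <- dense_reml_loglik(d$y, model.matrix(~x, d), V)
    expect_equal(fit$reml_loglik, ll, tolerance = 1e-6)
  }
})

test_that("dense oracle also covers correlated intercept-slope and kinship", {
  set.seed(9)
  ns <- 8; per <- 10
  d <- data.frame(strain = gl(ns, per * 2, labels = sprintf("s%d", 1:ns)),
                  diet = factor(rep(rep(c("AL", "IF"), each = per), ns)))
  a <- rnorm(ns); b <- -0.7 * a + 0.4 * rnorm(ns)
  d$y <- a[as.integer(d$strain)] +
    b[as.integer(d$strain)] * (d$diet == "IF") + rnorm(nrow(d), 0, 0.8)
  fit <- fit_lmm(y ~ diet + (1 + diet | strain), d)
  V <- dense_V_from_fit(fit)
  ll <- dense_reml_loglik(d$y, model.matrix(~diet, d), V)
  expect_equal(fit$reml_loglik, ll, tolerance = 1e-6)

  K <- generate_kinship(ns, seed = 4)
  rownames(K) <- colnames(K) <- levels(d$strain)
  kf <- fit_lmm(y ~ diet + (1 | strain), d, kinship = K,
                kinship_group = "strain")
  Vk <- dense_V_from_fit(kf, K = K)
  llk <- dense_reml_loglik(d$y, model.matrix(~diet, d), Vk)
  expect_equal(kf$reml_loglik, llk, tolerance = 1e-6)
})

test_that("rank-deficient fixed designs fail loudly, naming the alias", {
  d <- make_oneway()
  d$x1 <- rnorm(nrow(d)); d$x2 <- 2 * d$x1
  expect_error(fit_lmm(y ~ x1 + x2 + (1 | grp), d), "aliased.*x2")
})

test_that("BLUPs equal the balanced one-way shrinkage closed form", {
  d <- make_oneway(g = 7, reps = 9, seed = 5)
  fit <- fit_lmm(y ~ 1 + (1 | grp), d)
  vc <- varcomp(fit)
  s2u <- vc$vcov[vc$grp == "grp"]; s2e <- vc$vcov[vc$grp == "Residual"]
  gm <- tapply(d$y, d$grp, mean)
  shrink <- (9 * s2u / (9 * s2u + s2e)) * (gm - mean(d$y))
  b <- blups(fit, "grp")
  expect_equal(b$`(Intercept)`, as.numeric(shrink), tolerance = 1e-8)
  ## shrinkage bound: |BLUP| never exceeds the raw deviation
  expect_true(all(abs(b$`(Intercept)`) <= abs(gm - mean(d$y)) + 1e-12))
  expect_true(all(b$`(Intercept).sd` > 0))
})

test_that("BLUPs vanish at a zero variance estimate and mirror symmetric data", {
  set.seed(6)
  d <- data.frame(grp = gl(6, 10), y = rnorm(60))  # no group signal
  fit <- fit_lmm(y ~ 1 + (1 | grp), d)
  if (varcomp(fit)$vcov[1] < 1e-12)
    expect_true(all(abs(blups(fit, "grp")$`(Intercept)`) < 1e-10))

  d2 <- data.frame(grp = gl(2, 20), y = c(rnorm(20, 1), -rnorm(20, 1)))
  d2$y <- c(d2$y[1:20], -d2$y[1:20])  # exact mirror
  fit2 <- fit_lmm(y ~ 1 + (1 | grp), d2)
  b2 <- blups(fit2, "grp")$`(Intercept)`
  expect_equal(b2[1], -b2[2], tolerance = 1e-8)
  expect_error(blups(fit, "nope"), "no random term")
})

test_that("the random-effect LRT is zero for identical fits and powerful for
           a strong planted slope", {
  d <- make_oneway(g = 10, reps = 8, seed = 8)
  fit <- fit_lmm(y ~ 1 + (1 | grp), d)
  same <- lrt_random(fit, fit)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  set.seed(42)
  ns <- 10; per <- 10
  d2 <- data.frame(strain = gl(ns, per * 2), diet = factor(
    rep(rep(c("AL", "IF"), each = per), ns)))
  slopes <- rnorm(ns, 0, 2)
  d2$y <- slopes[as.integer(d2$strain)] * (d2$diet == "IF") + rnorm(nrow(d2))
  full <- fit_lmm(y ~ diet + (1 + diet | strain), d2)
  red <- fit_lmm(y ~ diet + (1 | strain), d2)
  lrt <- lrt_random(full, red)
  expect_equal(lrt$df, 2)
  expect_lt(lrt$p, 1e-3)
})

test_that("model-based mean contrasts match balance and GLS closed forms", {
  set.seed(12)
  d <- data.frame(g = gl(2, 25, labels = c("A", "B")), y = rnorm(50))
  fit <- fit_lmm(y ~ g, d)
  ctr <- contrast_means(fit, "g")
  expect_equal(ctr$estimate, mean(d$y[d$g == "A"]) - mean(d$y[d$g == "B"]),
               tolerance = 1e-10)

  ## mixed toy: contrast = c' beta, SE = sqrt(c' Cov c)
  d2 <- make_oneway(g = 6, reps = 8, seed = 3)
  d2$diet <- factor(rep(c("AL", "IF"), nrow(d2) / 2))
  d2$y <- d2$y + 0.5 * (d2$diet == "IF")
  fit2 <- fit_lmm(y ~ diet + (1 | grp), d2)
  ctr2 <- contrast_means(fit2, "diet")
  beta <- lme4::fixef(fit2$model)
  cv <- as.matrix(vcov(fit2$model))
  cc <- c(0, -1)  # AL - IF under treatment coding
  expect_equal(ctr2$estimate, sum(cc * beta), tolerance = 1e-8)
  expect_equal(ctr2$SE, sqrt(drop(t(cc) %*% cv %*% cc)), tolerance = 1e-8)

  expect_error(contrast_means(fit2, "y"), "continuous")
})

test_that("fits are invariant to row order and equivariant to scaling", {
  d <- make_oneway(g = 5, reps = 7, seed = 10)
  fit <- fit_lmm(y ~ 1 + (1 | grp), d)
  set.seed(1)
  perm <- sample(nrow(d))
  fitp <- fit_lmm(y ~ 1 + (1 | grp), d[perm, ])
  expect_equal(fit$reml_loglik, fitp$reml_loglik, tolerance = 1e-8)
  expect_equal(varcomp(fit)$vcov, varcomp(fitp)$vcov, tolerance = 1e-6)

  d3 <- d; d3$y <- 3 * d3$y
  fit3 <- fit_lmm(y ~ 1 + (1 | grp), d3)
  expect_equal(varcomp(fit3)$vcov, 9 * varcomp(fit)$vcov, tolerance = 1e-5)
})

test_that("rows with missing values are dropped and counted", {
  d <- make_oneway()
  d$y[c(3, 9)] <- NA
  fit <- fit_lmm(y ~ 1 + (1 | grp), d)
  expect_equal(fit$n_dropped, 2L)
  expect_equal(fit$n_used, nrow(d) - 2L)
})
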