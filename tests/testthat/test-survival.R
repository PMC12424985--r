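surv_df <- function(time, event = 1, ...) {
  data.frame(lifespan_months = time,
             event_observed = rep_len(event, length(time)), ...)
}

test_that("the product-limit estimate matches closed forms and hand oracles", {
  ## no censoring: S steps through 3/4, 1/2, 1/4, 0 and median = 2
  km <- km_fit(surv_df(1:4))
  expect_equal(km$table$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(unname(survival_quantile(km, 0.5)), 2)

  ## censored observation: hand product-limit
  tm <- c(2, 3, 3, 5, 8); ev <- c(1, 1, 0, 1, 1)
  km2 <- km_fit(surv_df(tm, ev))
  hand <- hand_km(tm, ev)
  got <- km2$table[km2$table$n.event > 0, c("time", "surv")]
  expect_equal(got$time, hand$time)
  expect_equal(got$surv, hand$surv)

  ## all censored: median undefined
  km3 <- km_fit(surv_df(c(5, 7, 9), 0))
  expect_true(is.na(survival_quantile(km3, 0.5)))

  ## no censoring: KM equals the empirical survivor function at event times
  set.seed(4)
  tt <- round(rexp(40, 0.1) + 1, 1)
  km4 <- km_fit(surv_df(tt))
  at <- km4$table$time[km4$table$n.event > 0]
  emp <- vapply(at, function(t) mean(tt > t), numeric(1))
  expect_equal(km4$table$surv[km4$table$n.event > 0], emp)

  expect_error(km_fit(surv_df(numeric(0))), "no observations")
})

test_that("log-rank matches the hypergeometric hand computation", {
  ## identical groups: statistic 0, p 1
  d <- surv_df(c(1, 2, 3, 4, 1, 2, 3, 4), 1,
               grp = rep(c("a", "b"), each = 4))
  lr <- logrank(d, "grp")
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  ## small two-group toy vs hand observed-expected and variance
  d2 <- surv_df(c(1, 3, 4, 6, 2, 5, 7, 8), c(1, 1, 0, 1, 1, 1, 1, 0),
                grp = rep(c("a", "b"), each = 4))
  lr2 <- logrank(d2, "grp")
  hand <- hand_logrank(d2$lifespan_months, d2$event_observed, d2$grp)
  expect_equal(lr2$statistic, unname(hand["chisq"]), tolerance = 1e-10)

  ## invariance under monotone time transform
  d3 <- d2; d3$lifespan_months <- d3$lifespan_months^2
  expect_equal(logrank(d3, "grp")$statistic, lr2$statistic)

  ## pairwise table covers all pairs with BH adjustment
  set.seed(5)
  d4 <- surv_df(rexp(60, 0.1) + 1, 1, grp = rep(c("a", "b", "c"), 20))
  pw <- logrank(d4, "grp", pairwise = TRUE)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$q, p.adjust(pw$p, "BH"))
})

test_that("Cox fits agree with the tiny partial-likelihood oracle", {
  ## 4 subjects, binary covariate, no ties
  d <- surv_df(c(1, 2, 3, 4), 1, x = c(1, 0, 1, 0))
  fit <- cox_fit(d, ~ x)
  b_hand <- hand_cox_1d(d$lifespan_months, d$event_observed, d$x)
  expect_equal(fit$coefficients$coef, b_hand, tolerance = 1e-8)
  expect_equal(fit$coefficients$HR, exp(b_hand), tolerance = 1e-8)

  ## Efron and Breslow coincide without ties
  set.seed(11)
  d2 <- surv_df(sort(runif(30, 1, 30)), 1, x = rnorm(30))
  fe <- cox_fit(d2, ~ x, ties = "efron")
  fb <- cox_fit(d2, ~ x, ties = "breslow")
  expect_equal(fe$coefficients$coef, fb$coefficients$coef, tolerance = 1e-8)

  ## single stratum equals unstratified
  d2$s <- "only"
  fs <- cox_fit(d2, ~ x, strata = "s")
  expect_equal(fs$coefficients$coef, fe$coefficients$coef, tolerance = 1e-10)

  ## cluster-robust SEs differ from model-based ones but keep the estimate
  d2$cage <- rep(1:10, 3)
  fc <- cox_fit(d2, ~ x, cluster = "cage")
  expect_equal(fc$coefficients$coef, fe$coefficients$coef, tolerance = 1e-10)
})

test_that("RMST equals direct averages and hand quadrature", {
  ## identical groups: difference 0, CI straddles 0
  d <- surv_df(rep(c(2, 4, 6, 9), 2), 1, diet = rep(c("AL", "IF"), each = 4))
  r <- rmst_diff(d, "diet")
  expect_equal(r$difference, 0)
  expect_true(r$ci[1] <= 0 && r$ci[2] >= 0)

  ## no censoring: RMST = mean(min(T, tau))
  set.seed(3)
  t1 <- round(rexp(25, 0.08) + 1, 2); t2 <- round(rexp(25, 0.06) + 1, 2)
  d2 <- surv_df(c(t1, t2), 1, diet = rep(c("AL", "IF"), each = 25))
  tau <- 15
  r2 <- rmst_diff(d2, "diet", tau = tau)
  expect_equal(unname(r2$rmst["AL"]), mean(pmin(t1, tau)), tolerance = 1e-10)
  expect_equal(unname(r2$rmst["IF"]), mean(pmin(t2, tau)), tolerance = 1e-10)
  ## tau = max event time, no censoring: RMST = sample mean
  r3 <- rmst_diff(d2, "diet", tau = min(max(t1), max(t2)))
  shorter <- if (max(t1) < max(t2)) "AL" else "IF"
  expect_equal(unname(r3$rmst[shorter]),
               mean(if (shorter == "AL") t1 else t2), tolerance = 1e-10)

  ## 4-point hand quadrature of the step function
  d4 <- surv_df(c(1, 2, 3, 4), 1, diet = "AL")
  area <- 1 * 1 + 0.75 * 1 + 0.5 * 1 + 0.25 * 1  # sum S(t_i) (t_{i+1}-t_i)
  expect_equal(unname(panelscreen:::rmst_one(
    d4$lifespan_months, d4$event_observed, 4)["rmst"]), area)

  expect_error(rmst_diff(d2, "diet", tau = 1e6), "exceeds")
})

test_that("CV comparison uses sd/mean and the signed-rank convention", {
  ## {2,4,6}: sd = 2, mean = 4, CV = 0.5
  d <- surv_df(rep(c(2, 4, 6), 2), 1,
               strain = "s1", diet = rep(c("AL", "IF"), each = 3))
  cvp <- cv_compare(d)
  expect_equal(cvp$cv$cv, c(0.5, 0.5))
  expect_equal(cvp$p, 1)  # identical per-strain CVs: all differences zero

  ## scale invariance
  d10 <- d; d10$lifespan_months <- d10$lifespan_months * 10
  expect_equal(cv_compare(d10)$cv$cv, cvp$cv$cv)

  ## cells with n < 2 are dropped with a warning
  d2 <- rbind(d, surv_df(5, 1, strain = "s2", diet = "AL"))
  expect_warning(cv_compare(d2), "n < 2")
})
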