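test_that("the local-polynomial smoother reproduces polynomials and matches
           a pointwise tricube WLS oracle", {
  a <- seq(4, 60, by = 2)
  lin <- 5 + 0.3 * a
  s <- smooth_series(a, lin)
  expect_equal(s$smoothed, lin, tolerance = 1e-10)

  s2 <- smooth_series(a, rep(7, length(a)))
  expect_equal(s2$smoothed, rep(7, length(a)), tolerance = 1e-10)

  ## noisy series: interior fitted value = tricube-weighted quadratic WLS
  set.seed(6)
  y <- 20 + 0.5 * a - 0.006 * a^2 + rnorm(length(a), 0, 0.4)
  s3 <- smooth_series(a, y)
  i <- 14
  n <- length(a); q <- floor(n / 3)
  dd <- abs(a - a[i]); nb <- order(dd)[seq_len(q)]
  w <- (1 - pmin(dd[nb] / max(dd[nb]), 1)^3)^3
  X <- cbind(1, a[nb] - a[i], (a[nb] - a[i])^2)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y[nb]))
  expect_equal(s3$smoothed[i], beta[1], tolerance = 1e-8)

  ## short series pass through flagged; unsorted input is sorted with warning
  s4 <- smooth_series(1:3, c(5, 6, 7))
  expect_true(attr(s4, "passthrough"))
  expect_warning(s5 <- smooth_series(c(3, 1, 2, 5, 4), 1:5), "sorting")
  expect_equal(s5$age, 1:5)
})

test_that("MM and +AUC follow rectangle and trapezoid closed forms", {
  ## constant weight: MM = w, area = w * span
  s <- data.frame(age = c(10, 14, 20), smoothed = c(3, 3, 3))
  ws <- weight_summaries(s)
  expect_equal(ws$MM, 3)
  expect_equal(ws$plusAUC, 3 * 10)

  ## linear ramp 0..10 over 10 weeks: exact area 50
  ramp <- data.frame(age = 0:10, smoothed = 0:10)
  expect_equal(weight_summaries(ramp)$plusAUC, 50)

  ## matches the hand trapezoid on a random series, and is additive over
  ## contiguous intervals
  set.seed(8)
  ser <- data.frame(age = sort(sample(4:80, 30)), smoothed = runif(30, 20, 40))
  auc <- weight_summaries(ser)$plusAUC
  expect_equal(auc, trapz_hand(ser$age, ser$smoothed))
  cut <- 15
  auc_a <- weight_summaries(ser[1:cut, ])$plusAUC
  auc_b <- weight_summaries(ser[cut:nrow(ser), ])$plusAUC
  expect_equal(auc_a + auc_b, auc)

  ## positive-part variant measures area above the first observation
  pp <- weight_summaries(ramp, positive_part = TRUE)
  expect_equal(pp$plusAUC, 50)  # first value is 0 here

  single <- weight_summaries(data.frame(age = 5, smoothed = 30))
  expect_equal(single$MM, 30)
  expect_true(is.na(single$plusAUC))
})

test_that("PLL rescaling and 20-bin assignment follow the boundary rules", {
  expect_equal(to_pll(c(0, 50, 100), 100), c(0, 0.5, 1))
  expect_error(to_pll(120, 100), "exceeds lifespan")
  expect_error(to_pll(10, 0), "positive")

  ## bin = floor(pll * 20) + 1 with the terminal clamp
  set.seed(4)
  pll <- c(0, runif(200), 1)
  val <- rnorm(202)
  bm <- bin_means(pll, val, bins = 20)
  oracle_bin <- pmin(floor(pll * 20) + 1, 20)
  expect_setequal(bm$bin, unique(oracle_bin))
  ## per-bin means recompute correctly and pool back to the global mean
  for (b in bm$bin) {
    expect_equal(bm$mean[bm$bin == b], mean(val[oracle_bin == b]))
  }
  expect_equal(sum(bm$mean * bm$n) / sum(bm$n), mean(val))
})

test_that("the frailty index is the mean of non-missing ordinal items", {
  expect_equal(frailty_index(rep(0, 27)), 0)
  expect_equal(frailty_index(rep(1, 27)), 1)
  expect_equal(frailty_index(c(1, 0.5, rep(0, 25))), 1.5 / 27)
  ## item order is irrelevant; an all-missing item changes nothing
  it <- c(1, 0.5, rep(0, 25))
  expect_equal(frailty_index(sample(it)), frailty_index(it))
  expect_equal(frailty_index(c(it, NA)), frailty_index(it))
  expect_error(frailty_index(c(NA, NA)), "all items missing")
  expect_error(frailty_index(c(0.3, 1)), "0, 0.5 or 1")
})

test_that("FI slopes are OLS on PLL and final FI is the last visit", {
  visits <- data.frame(age_weeks = c(20, 60, 100),
                       item01 = c(0, 0.5, 1), item02 = c(0, 0.5, 1))
  fs <- fi_summaries(visits, lifespan_weeks = 100)
  ols <- coef(lm(c(0, 0.5, 1) ~ I(c(0.2, 0.6, 1))))[2]
  expect_equal(fs$fi_slope, unname(ols))
  expect_equal(fs$final_fi, 1)

  flat <- data.frame(age_weeks = c(20, 60, 100), item01 = c(0.5, 0.5, 0.5))
  expect_equal(fi_summaries(flat, 100)$fi_slope, 0)
})

test_that("deficit incidence counts ever-severe mice and is antisymmetric in
           diet", {
  fr <- data.frame(
    mouse_id = rep(sprintf("m%d", 1:8), each = 2),
    item01 = c(1,0, 1,1, 0,1, 0,0, 1,0, 0,0, 0,0, 0,0),
    item02 = rep(0.5, 16))
  an <- data.frame(mouse_id = sprintf("m%d", 1:8), strain = "s1",
                   diet = rep(c("IF", "AL"), each = 4))
  inc <- deficit_incidence(fr, an)
  i1 <- inc[inc$item == "item01", ]
  expect_equal(i1$incidence_IF, 0.75)  # 3 of 4 IF mice ever severe
  expect_equal(i1$incidence_AL, 0.25)  # 1 of 4 AL mice
  expect_equal(i1$difference, 0.5)
  ## 0.5 scores are non-severe: item02 contributes nothing
  i2 <- inc[inc$item == "item02", ]
  expect_equal(i2$incidence_IF, 0)
  expect_equal(i2$difference, 0)

  ## swapping diet labels negates every difference
  an2 <- an; an2$diet <- ifelse(an$diet == "IF", "AL", "IF")
  inc2 <- deficit_incidence(fr, an2)
  expect_equal(inc2$difference, -inc$difference)
})
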