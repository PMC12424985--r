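# Independent oracles, kept deliberately separate from the package's own
# computational paths: dense-covariance REML evaluation, a hand-written BH
# step-up, a hand product-limit estimator, and small utilities.

# REML log-likelihood evaluated with the full n x n covariance
# V = sum_k Z_k G_k Z_k' + s2e I  (Harville form, profiling nothing)
dense_reml_loglik <- function(y, X, V) {
  n <- length(y)
  p <- qr(X)$rank
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       t(r) %*% Vi %*% r))
}

# resolve a random-slope design column (treatment-coded factor level like
# "dietIF", or a numeric covariate) to its numeric vector
slope_design <- function(d, cn) {
  for (col in names(d)) {
    v <- d[[col]]
    if (is.factor(v) || is.character(v)) {
      fv <- factor(v)
      for (lv in levels(fv))
        if (paste0(col, lv) == cn) return(as.numeric(fv == lv))
    } else if (col == cn) return(as.numeric(v))
  }
  stop("cannot resolve slope column ", cn)
}

# dense V for a fitted lmm_fit on its own data: iid intercept terms, at most
# one intercept+slope block, optionally one kinship-scaled intercept
dense_V_from_fit <- function(fit, K = NULL) {
  vc <- panelscreen::varcomp(fit)
  d <- fit$data
  n <- nrow(d)
  V <- matrix(0, n, n)
  for (g in setdiff(unique(vc$grp), "Residual")) {
    grp_col <- sub("\\..*$", "", g)  # lme4 suffixes duplicated groups
    f <- factor(d[[grp_col]])
    Z0 <- model.matrix(~ 0 + f)
    rows <- vc[vc$grp == g, ]
    cols <- rows$var1[is.na(rows$var2)]
    if (length(cols) == 1 && cols == "(Intercept)") {
      s2 <- rows$vcov[is.na(rows$var2)]
      M <- if (!is.null(K) && identical(fit$kinship_group, grp_col))
        Z0 %*% panelscreen::rescale_kinship(K, levels(f)) %*% t(Z0)
      else tcrossprod(Z0)
      V <- V + s2 * M
    } else {
      slope_name <- setdiff(cols, "(Intercept)")
      stopifnot(length(slope_name) == 1)
      Zs <- Z0 * slope_design(d, slope_name)
      s2i <- rows$vcov[rows$var1 == "(Intercept)" & is.na(rows$var2)]
      s2s <- rows$vcov[rows$var1 == slope_name & is.na(rows$var2)]
      cis <- rows$vcov[!is.na(rows$var2)]
      V <- V + s2i * tcrossprod(Z0) + s2s * tcrossprod(Zs) +
        cis * (Z0 %*% t(Zs) + Zs %*% t(Z0))
    }
  }
  V + vc$vcov[vc$grp == "Residual"] * diag(n)
}

# BH step-up, written from the definition: q_(i) = min_{j >= i} m p_(j) / j
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * ps[i] / i)
    q[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# hand product-limit estimator: returns S(t) at each unique event time
hand_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# two-group log-rank observed-expected and hypergeometric variance terms
hand_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L  # 0/1
  ut <- sort(unique(time[event == 1]))
  OE <- 0; V <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    OE <- OE + (d1 - d * n1 / n)
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  c(OE = OE, V = V, chisq = OE^2 / V)
}

# 1-covariate Cox partial-likelihood score solved by Newton (no ties)
hand_cox_1d <- function(time, event, x, beta0 = 0, iter = 50) {
  b <- beta0
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  for (it in seq_len(iter)) {
    U <- 0; I <- 0
    for (i in which(event == 1)) {
      at <- time >= time[i]
      w <- exp(b * x[at])
      xb <- sum(w * x[at]) / sum(w)
      x2b <- sum(w * x[at]^2) / sum(w)
      U <- U + (x[i] - xb)
      I <- I + (x2b - xb^2)
    }
    step <- U / I
    b <- b + step
    if (abs(step) < 1e-12) break
  }
  b
}

trapz_hand <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
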