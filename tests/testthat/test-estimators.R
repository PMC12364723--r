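test_that("IVW-MRE reproduces the hand-computed weighted mean, Q and dispersion", {
  r <- data.frame(snp = c("a", "b"), ratio = c(0.5, 1.0), se = c(0.1, 0.2),
                  weight = 1 / c(0.1, 0.2)^2)
  e <- mr_ivw(ratios = r)
  expect_equal(e$beta, 0.6)
  expect_equal(e$se_fixed, 0.0894427, tolerance = 1e-6)
  expect_equal(e$q, 5.0)
  expect_equal(e$phi, 5.0)
  expect_equal(e$se, 0.2, tolerance = 1e-6)
  expect_equal(e$q_pval, pchisq(5, 1, lower.tail = FALSE))
})

test_that("identical ratios give zero heterogeneity and the fixed-effect SE", {
  r <- data.frame(snp = letters[1:3], ratio = rep(0.7, 3),
                  se = c(0.1, 0.2, 0.3), weight = 1 / c(0.1, 0.2, 0.3)^2)
  e <- mr_ivw(ratios = r)
  expect_equal(e$beta, 0.7)
  expect_equal(e$q, 0)
  expect_equal(e$phi, 1)
  expect_equal(e$se, e$se_fixed)
})

test_that("a single ratio degrades to the Wald estimator with a flag", {
  hs <- make_hs(0.05, 0.01, 0.02, 0.015)
  e <- mr_ivw(hs)
  expect_equal(e$method, "wald")
  expect_true(e$degraded)
  expect_equal(e$beta, 0.4)
  expect_equal(e$se, 0.015 / 0.05)
})

test_that("IVW equals zero-intercept WLS of outcome on exposure effects", {
  for (case in 1:100) {
    set.seed(case)
    J <- sample(3:40, 1)
    hs <- make_hs(rnorm(J, 0.05, 0.02) + 0.02, runif(J, 0.002, 0.01),
                  rnorm(J, 0.01, 0.03), runif(J, 0.005, 0.03))
    fit <- lm(beta_out ~ 0 + beta_exp, data = hs, weights = 1 / hs$se_out^2)
    expect_equal(mr_ivw(hs)$beta, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("Cochran's Q matches the worked example and is permutation-invariant", {
  r <- data.frame(snp = c("a", "b"), ratio = c(0.5, 1.0), se = c(0.1, 0.2),
                  weight = 1 / c(0.1, 0.2)^2)
  q <- cochran_q(ratios = r)
  expect_equal(q$q, 5.0)
  expect_equal(q$df, 1)
  expect_equal(q$pval, 0.0253, tolerance = 1e-2)
  set.seed(3)
  J <- 12
  hs <- make_hs(runif(J, 0.02, 0.1), runif(J, 0.002, 0.01),
                rnorm(J, 0.02, 0.02), runif(J, 0.005, 0.03))
  perm <- sample.int(J)
  q1 <- cochran_q(hs); q2 <- cochran_q(hs[perm, ])
  expect_equal(q1$q, q2$q)
  r3 <- data.frame(ratio = rep(2, 4), se = 1, weight = 1)
  expect_equal(cochran_q(ratios = r3)$q, 0)
  expect_equal(cochran_q(ratios = r3)$pval, 1)
})

test_that("Egger recovers exact proportionality with zero intercept and RSS", {
  gx <- c(0.02, 0.05, 0.08, 0.11)
  hs <- make_hs(gx, 0.005, 0.3 * gx, 0.01)
  e <- mr_egger(hs)
  expect_equal(e$beta, 0.3, tolerance = 1e-12)
  expect_equal(e$intercept, 0, tolerance = 1e-12)
  expect_equal(e$rss, 0, tolerance = 1e-12)
})

test_that("Egger is invariant to per-SNP sign flips (orientation)", {
  set.seed(9)
  J <- 10
  hs <- make_hs(runif(J, 0.02, 0.1), runif(J, 0.002, 0.01),
                rnorm(J, 0.02, 0.02), runif(J, 0.005, 0.03))
  e1 <- mr_egger(hs)
  hs2 <- hs
  hs2$beta_exp[3] <- -hs2$beta_exp[3]
  hs2$beta_out[3] <- -hs2$beta_out[3]
  e2 <- mr_egger(hs2)
  expect_equal(e2$beta, e1$beta)
  expect_equal(e2$intercept, e1$intercept)
})

test_that("Egger matches the weighted lm oracle (slope, intercept, scaled SEs)", {
  for (case in 1:100) {
    set.seed(1000 + case)
    J <- sample(4:30, 1)
    hs <- make_hs(runif(J, 0.02, 0.1), runif(J, 0.002, 0.01),
                  rnorm(J, 0.02, 0.03), runif(J, 0.005, 0.03))
    e <- mr_egger(hs)
    fit <- lm(beta_out ~ beta_exp, data = hs, weights = 1 / hs$se_out^2)
    expect_equal(e$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(e$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
    s <- summary(fit)
    infl <- sqrt(max(1, s$sigma^2)) / s$sigma
    expect_equal(e$se, unname(s$coefficients[2, 2]) * infl, tolerance = 1e-10)
    expect_equal(e$intercept_se, unname(s$coefficients[1, 2]) * infl,
                 tolerance = 1e-10)
  }
  expect_error(mr_egger(make_hs(c(0.1, 0.2), 0.01, c(0.1, 0.2), 0.01)),
               "at least 3")
})

test_that("weighted median interpolates the cumulative-weight function", {
  r_eq <- data.frame(ratio = c(1, 2, 3), se = 1, weight = c(1, 1, 1))
  expect_equal(medimr:::weighted_median_point(r_eq$ratio, r_eq$weight), 2.0)
  expect_equal(medimr:::weighted_median_point(c(1, 2, 10), c(0.25, 0.25, 0.5)),
               4.6667, tolerance = 1e-4)
  # bootstrap SE path is seeded and reproducible
  hs <- make_hs(c(0.05, 0.06, 0.08, 0.1), 0.005,
                c(0.015, 0.02, 0.03, 0.024), 0.01)
  w1 <- mr_weighted_median(hs, n_boot = 200, seed = 4)
  w2 <- mr_weighted_median(hs, n_boot = 200, seed = 4)
  expect_equal(w1$se, w2$se)
  expect_error(mr_weighted_median(make_hs(c(0.1, 0.2), 0.01, c(0.1, 0.2), 0.01)),
               "at least 3")
})

test_that("weighted median resists just under half the weight being invalid", {
  # equal weights; 9 of 20 instruments (45% of weight) have ratios
  # shifted by +1; precise instruments so the median sits in the valid
  # cluster
  est <- sapply(1:60, function(r) {
    set.seed(r)
    J <- 20
    gx <- rep(0.08, J)
    se_y <- rep(5e-5, J)
    gy <- 0.25 * gx + rnorm(J, 0, se_y)
    bad <- 1:9
    gy[bad] <- gy[bad] + 1 * gx[bad]   # invalid: ratio shifted by +1
    hs <- make_hs(gx, 1e-4, gy, se_y)
    mr_weighted_median(hs, n_boot = 50, seed = r)$beta
  })
  mcse <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.25), 2 * mcse + 0.002)
})

test_that("MVMR with one exposure equals fixed-effect IVW and matches lm", {
  for (case in 1:100) {
    set.seed(2000 + case)
    J <- sample(5:30, 1)
    K <- sample(1:3, 1)
    X <- matrix(rnorm(J * K, 0.05, 0.03), J, K,
                dimnames = list(NULL, paste0("x", 1:K)))
    se_y <- runif(J, 0.005, 0.03)
    y <- rnorm(J, 0.02, 0.02)
    m <- mr_mvmr(X, y, se_y)
    fit <- lm(y ~ 0 + X, weights = 1 / se_y^2)
    expect_equal(m$beta, unname(coef(fit)), tolerance = 1e-10)
    if (K == 1) {
      hs <- make_hs(X[, 1], 0.001, y, se_y)
      ivw <- mr_ivw(hs)
      expect_equal(m$beta, ivw$beta, tolerance = 1e-10)
      expect_equal(m$se, ivw$se_fixed, tolerance = 1e-10)
    }
  }
  X <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10))
  expect_error(mr_mvmr(X, rnorm(5), rep(0.1, 5)), "rank-deficient")
})

test_that("log-odds estimates exponentiate to the published odds ratios", {
  expect_equal(round(exp(-0.4119), 4), 0.6624)
  expect_equal(round(exp(0.3181), 4), 1.3745)
  b <- or_ci(-0.4119, 0.124737)
  expect_equal(b$or, exp(-0.4119))
  expect_lt(b$or_lo, b$or); expect_gt(b$or_hi, b$or)
})

test_that("p-values are recoverable from OR and 95% CI at printed precision", {
  expect_equal(round(p_from_or_ci(0.6624, 0.5187, 0.8458), 5), 0.00096)
  expect_equal(round(p_from_or_ci(1.3745, 1.0680, 1.7690), 4), 0.0135)
  expect_equal(round(p_from_or_ci(1.39, 1.03, 1.88), 2), 0.03)
  expect_equal(round(p_from_or_ci(1.40, 1.08, 1.81), 2), 0.01)
  expect_equal(round(p_from_or_ci(1.31, 1.01, 1.70), 2), 0.04)
  expect_equal(round(p_from_or_ci(0.72, 0.55, 0.93), 2), 0.01)
  expect_equal(round(p_from_or_ci(1.61, 1.04, 2.51), 2), 0.03)
  expect_equal(round(p_from_or_ci(0.74, 0.58, 0.94), 2), 0.01)
  # null point with a symmetric CI has p exactly 1
  expect_equal(p_from_or_ci(1.0000001, 0.5, 2), 1, tolerance = 1e-4)
  expect_error(p_from_or_ci(0.9, 1.0, 1.2), "require")
})

test_that("estimators are equivariant to rescaling the outcome", {
  set.seed(5)
  J <- 15
  hs <- make_hs(runif(J, 0.02, 0.1), runif(J, 0.002, 0.01),
                rnorm(J, 0.02, 0.02), runif(J, 0.005, 0.03))
  c_ <- 3.7
  hs2 <- hs
  hs2$beta_out <- c_ * hs$beta_out
  hs2$se_out <- c_ * hs$se_out
  for (f in list(mr_ivw, mr_egger)) {
    e1 <- f(hs); e2 <- f(hs2)
    expect_equal(e2$beta, c_ * e1$beta, tolerance = 1e-12)
    expect_equal(e2$se, c_ * e1$se, tolerance = 1e-12)
  }
  wm1 <- mr_weighted_median(hs, n_boot = 100, seed = 2)
  wm2 <- mr_weighted_median(hs2, n_boot = 100, seed = 2)
  expect_equal(wm2$beta, c_ * wm1$beta, tolerance = 1e-12)
})

test_that("mr_result rows satisfy the OR/p internal identities", {
  hs <- make_hs(c(0.05, 0.06, 0.08), 0.005, c(0.015, 0.02, 0.03), 0.01)
  e <- mr_ivw(hs)
  expect_equal(e$pval, 2 * pnorm(-abs(e$beta / e$se)))
  expect_equal(e$or, exp(e$beta))
  expect_equal(e$or_lo, exp(e$beta - 1.959964 * e$se))
  expect_equal(e$or_hi, exp(e$beta + 1.959964 * e$se))
})
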