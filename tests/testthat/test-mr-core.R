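test_that("Wald ratios divide outcome by exposure effects", {
  w <- waldRatio(0.1, by = 0.05, seBy = 0.02)
  expect_equal(w$theta, 0.5)
  expect_equal(w$se, 0.2)
  w <- waldRatio(-0.1, by = 0.05, seBy = 0.02)
  expect_equal(w$theta, -0.5)
  expect_equal(w$se, 0.2)  # SE stays positive under sign flips
  w <- waldRatio(0.1, by = 0, seBy = 0.02)
  expect_equal(w$theta, 0)
  expect_equal(w$or, 1.0)
  expect_error(waldRatio(0, by = 0.1, seBy = 0.02), "degenerate instrument")
})

test_that("second-order Wald SE adds the exposure-side term", {
  w1 <- waldRatio(0.1, by = 0.05, seBy = 0.02, seBx = 0.03, order = 1)
  w2 <- waldRatio(0.1, by = 0.05, seBy = 0.02, seBx = 0.03, order = 2)
  expect_gt(w2$se, w1$se)
  expect_equal(w2$se, sqrt(0.02^2 / 0.1^2 + 0.05^2 * 0.03^2 / 0.1^4))
  expect_error(waldRatio(0.1, by = 0.05, seBy = 0.02, order = 2),
               "exposure-side")
})

test_that("IVW pooling matches an independent WLS oracle to 1e-10", {
  set.seed(11)
  for (rep in 1:30) {
    k <- sample(2:8, 1)
    est <- data.frame(theta = rnorm(k), se = runif(k, 0.05, 0.5))
    res <- ivw(est, mode = "fixed")
    oracle <- wls_oracle(est$theta, est$se)
    expect_equal(thetaHat(res), oracle$theta, tolerance = 1e-10)
    expect_equal(seFixed(res), oracle$se, tolerance = 1e-10)
  }
})

test_that("IVW agrees with metafor's fixed-effect meta-analysis", {
  skip_if_not_installed("metafor")
  set.seed(12)
  est <- data.frame(theta = rnorm(5), se = runif(5, 0.05, 0.5))
  fe <- metafor::rma(yi = est$theta, sei = est$se, method = "FE")
  res <- ivw(est, mode = "fixed")
  expect_equal(thetaHat(res), as.numeric(fe$beta), tolerance = 1e-8)
  expect_equal(seFixed(res), fe$se, tolerance = 1e-8)
  expect_equal(cochranQ(res)[["Q"]], fe$QE, tolerance = 1e-8)
  dl <- metafor::rma(yi = est$theta, sei = est$se, method = "DL")
  ad <- ivw(est, mode = "additive_random")
  expect_equal(thetaHat(ad), as.numeric(dl$beta), tolerance = 1e-8)
  expect_equal(seUsed(ad), dl$se, tolerance = 1e-8)
})

test_that("degenerate poolings behave as specified", {
  single <- ivw(data.frame(theta = 0.3, se = 0.1))
  expect_equal(thetaHat(single), 0.3)
  expect_equal(seUsed(single), 0.1)
  expect_true(is.na(cochranQ(single)[["Q"]]))
  equal_se <- ivw(data.frame(theta = c(0.1, 0.3), se = c(0.2, 0.2)))
  expect_equal(thetaHat(equal_se), 0.2)
  expect_error(ivw(data.frame(theta = numeric(0), se = numeric(0))),
               "empty")
})

test_that("Cochran's Q is permutation- and scale-invariant, zero iff equal", {
  set.seed(13)
  est <- data.frame(theta = rnorm(6), se = runif(6, 0.05, 0.3))
  q0 <- cochranQ(ivw(est))[["Q"]]
  perm <- est[sample(6), ]
  expect_equal(cochranQ(ivw(perm))[["Q"]], q0, tolerance = 1e-12)
  scaled <- data.frame(theta = 3.7 * est$theta, se = 3.7 * est$se)
  expect_equal(cochranQ(ivw(scaled))[["Q"]], q0, tolerance = 1e-12)
  same <- data.frame(theta = rep(0.2, 4), se = runif(4, 0.05, 0.3))
  expect_equal(cochranQ(ivw(same))[["Q"]], 0)
  expect_gt(q0, 0)
})

test_that("random-effects mode shares theta with fixed and never deflates", {
  set.seed(14)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    est <- data.frame(theta = rnorm(k, sd = 0.3), se = runif(k, 0.05, 0.4))
    fx <- ivw(est, mode = "fixed")
    re <- ivw(est, mode = "multiplicative_random")
    expect_equal(thetaHat(re), thetaHat(fx), tolerance = 1e-12)
    expect_gte(seUsed(re), seUsed(fx))
    q <- cochranQ(re)[["Q"]]
    if (q <= k - 1) {
      expect_equal(seUsed(re), seUsed(fx))  # the phi = 1 floor
    } else {
      expect_gt(seUsed(re), seUsed(fx))
    }
  }
})

test_that("leave-one-out recomputes the pooling on each k-1 subset", {
  est2 <- data.frame(rsid = c("a", "b"), theta = c(0.1, 0.5),
                     se = c(0.1, 0.2))
  loo <- leaveOneOut(est2)
  # with k = 2 each row equals the other variant's Wald estimate
  expect_equal(loo$theta, c(0.5, 0.1))
  expect_equal(loo$se, c(0.2, 0.1))
  same <- data.frame(theta = rep(0.2, 4), se = rep(0.1, 4))
  loo4 <- leaveOneOut(same)
  full <- ivw(same)
  expect_true(all(abs(loo4$theta - thetaHat(full)) < 1e-12))
  expect_equal(length(unique(round(loo4$or, 12))), 1)
  expect_error(leaveOneOut(data.frame(theta = 0.1, se = 0.1)),
               "at least 2")
})

test_that("the F-statistic is monotone in its arguments", {
  f0 <- fValue(fStatistic(0.0147, 100000, 4))
  expect_gt(fValue(fStatistic(0.0147, 200000, 4)), f0)
  expect_gt(fValue(fStatistic(0.03, 100000, 4)), f0)
  expect_lt(fValue(fStatistic(0.0147, 100000, 5)), f0)
  expect_equal(f0, (0.0147 / (1 - 0.0147)) * ((100000 - 5) / 4))
  expect_error(fStatistic(0, 1000, 4), "r2")
  expect_error(fStatistic(0.01, 5, 4), "exceed")
})

test_that("odds-ratio reports are symmetric and invert cleanly", {
  r <- reportOR(0, 0.1)
  expect_equal(r$or, 1.0)
  expect_equal(r$ci_lower * r$ci_upper, 1.0)  # symmetric on the log scale
  expect_equal(r$pval, 1.0)
  expect_error(reportOR(0.1, 0), "positive")
})

test_that("MR tables round-trip through the TSV writer", {
  est <- waldRatio(c(0.1, 0.08), by = c(0.05, -0.02),
                   seBy = c(0.02, 0.03), rsid = c("rs1", "rs2"))
  res <- ivw(est)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMrTable(res, f, outcome = "demo",
               fstat = fStatistic(0.0147, 50000, 2))
  tab <- readMrTable(f)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$or[tab$method == "ivw"], oddsRatio(res),
               tolerance = 1e-8)
  expect_equal(sort(tab$rsid[tab$method == "wald"]), c("rs1", "rs2"))
})
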