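test_that("the weighted GRS is the dosage-weighted sum", {
  G <- genotypeMatrix(matrix(c(0, 1, 2, 1), nrow = 1,
                             dimnames = list(NULL, paste0("snp", 1:4))))
  expect_equal(buildGRS(G, rep(1, 4)), 4)
  G1 <- genotypeMatrix(matrix(c(0, 1, 2), ncol = 1,
                              dimnames = list(NULL, "snp1")))
  expect_equal(buildGRS(G1, c(snp1 = 0.3)), c(0, 0.3, 0.6))
  expect_error(buildGRS(G, c(snp1 = 1)), "no weight for variant")
})

test_that("weights stated for the other allele reflect the dosage", {
  set.seed(21)
  G <- simulateGenotypes(500, c(0.2, 0.4))
  w_eff <- data.frame(rsid = c("snp1", "snp2"),
                      allele = unname(effectAllele(G)),
                      beta = c(0.5, -0.3))
  w_other <- w_eff
  w_other$allele[1] <- G@otherAllele[1]
  w_other$beta[1] <- -w_eff$beta[1]
  s1 <- buildGRS(G, w_eff)
  s2 <- buildGRS(G, w_other)
  # scores differ only by a constant shift, so association z is unchanged
  expect_equal(diff(range(s1 - s2)), 0)
  y <- 0.2 * s1 + rnorm(500)
  a1 <- associateTrait(y, s1)
  a2 <- associateTrait(y, s2)
  expect_equal(a1$z, a2$z, tolerance = 1e-10)
})

test_that("associateTrait recovers strong and null effects", {
  set.seed(22)
  x <- rnorm(200)
  fit <- associateTrait(2 * x + rnorm(200, sd = 1e-6), x)
  expect_equal(fit$beta, 2, tolerance = 1e-4)
  expect_gt(abs(fit$z), 100)
  # under the null, z is empirically standard normal
  zs <- replicate(1000, {
    g <- rbinom(150, 2, 0.3)
    associateTrait(rnorm(150), g)$z
  })
  expect_lt(abs(mean(zs)), 3 / sqrt(1000))
  expect_lt(abs(var(zs) - 1), 0.15)
  expect_error(associateTrait(rnorm(20), rep(1, 20)), "zero variance")
  expect_error(associateTrait(rnorm(5), rnorm(5)), "10 complete cases")
})

test_that("associateTrait matches lm and glm on the same data", {
  set.seed(23)
  g <- rbinom(300, 2, 0.3)
  cov1 <- rnorm(300)
  y <- 0.4 * g + 0.2 * cov1 + rnorm(300)
  mine <- associateTrait(y, g, covariates = cbind(cov1))
  ref <- summary(lm(y ~ g + cov1))$coefficients
  expect_equal(mine$beta, ref["g", "Estimate"], tolerance = 1e-10)
  expect_equal(mine$se, ref["g", "Std. Error"], tolerance = 1e-10)
  yb <- rbinom(300, 1, plogis(-1 + 0.5 * g))
  mineb <- associateTrait(yb, g, family = "binary")
  refb <- summary(glm(yb ~ g, family = binomial()))$coefficients
  expect_equal(mineb$beta, refb["g", "Estimate"], tolerance = 1e-6)
  expect_equal(mineb$se, refb["g", "Std. Error"], tolerance = 1e-6)
})

test_that("logistic slopes are recovered at scale", {
  set.seed(24)
  g <- rbinom(20000, 2, 0.3)
  y <- rbinom(20000, 1, plogis(-2 + 0.5 * g))
  fit <- associateTrait(y, g, family = "binary")
  expect_lt(abs(fit$beta - 0.5), 3 * fit$se)
})

test_that("BH q-values equal the brute-force step-up", {
  expect_equal(bhFDR(0.03), 0.03)
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(c(0.001, 1.0)), c(0.002, 1.0))
  expect_error(bhFDR(c(0.1, 1.2)), "0, 1")
  set.seed(25)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bhFDR(p), bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(bhFDR(p) >= p - 1e-15))
  }
})

test_that("BH is permutation-invariant and monotone in each p", {
  set.seed(26)
  p <- runif(20)
  q <- bhFDR(p)
  ord <- sample(20)
  expect_equal(bhFDR(p[ord]), q[ord], tolerance = 1e-12)
  for (i in c(3, 11, 17)) {
    p2 <- p
    p2[i] <- min(1, p[i] + 0.2)
    expect_true(all(bhFDR(p2) >= q - 1e-12))
  }
})

test_that("a planted GRS signal is flagged and only genuine cells pass", {
  set.seed(27)
  n <- 2000
  G <- simulateGenotypes(n, c(0.1, 0.2, 0.3, 0.4))
  w <- instrumentBetas(c(0.1, 0.2, 0.3, 0.4), 0.05)
  grs <- buildGRS(G, stats::setNames(w, colnames(dosages(G))))
  vals <- data.frame(
    hit = 0.5 * scale(grs)[, 1] + rnorm(n),
    null1 = rnorm(n), null2 = rnorm(n),
    nullbin = rbinom(n, 1, 0.3))
  traits <- traitTable(vals, c(hit = "continuous", null1 = "continuous",
                               null2 = "continuous", nullbin = "binary"))
  scan <- runScan(G, traits, stats::setNames(w, colnames(dosages(G))))
  sig <- significantCells(scan)
  expect_true(any(sig$predictor == "GRS" & sig$trait == "hit"))
  expect_true(all(sig$trait == "hit"))
  expect_gt(sig$z_aligned[sig$predictor == "GRS" & sig$trait == "hit"], 0)
  # q >= p elementwise and flags are exactly q < threshold
  tab <- scanTable(scan)
  expect_true(all(tab$qval >= tab$pval - 1e-12, na.rm = TRUE))
  expect_identical(tab$significant,
                   !is.na(tab$qval) & tab$qval < 0.05)
})

test_that("scan z-scores are invariant to relabeling effect alleles", {
  set.seed(28)
  n <- 800
  G <- simulateGenotypes(n, c(0.2, 0.4))
  w <- stats::setNames(c(0.4, -0.3), colnames(dosages(G)))
  vals <- data.frame(t1 = rnorm(n), t2 = rnorm(n))
  traits <- traitTable(vals)
  s1 <- zMatrix(runScan(G, traits, w))
  # relabel variant 1: count the other allele, negate its weight
  d2 <- dosages(G)
  d2[, 1] <- 2 - d2[, 1]
  G2 <- genotypeMatrix(d2, effectAllele = c(G@otherAllele[1],
                                            G@effectAllele[2]),
                       otherAllele = c(G@effectAllele[1], G@otherAllele[2]))
  w2 <- data.frame(rsid = names(w),
                   allele = c(G@effectAllele[1], G@effectAllele[2]),
                   beta = unname(w))
  s2 <- zMatrix(runScan(G2, traits, w2))
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("degenerate scans reduce to a single fit with identity FDR", {
  set.seed(29)
  G <- simulateGenotypes(300, 0.3)
  y <- rnorm(300)
  traits <- traitTable(data.frame(t = y))
  scan <- runScan(G, traits, c(snp1 = 0.5))
  tab <- scanTable(scan)
  direct <- associateTrait(y, dosages(G)[, 1])
  snp_row <- tab[tab$predictor == "snp1", ]
  expect_equal(snp_row$pval, direct$pval, tolerance = 1e-12)
  expect_equal(snp_row$z_aligned, direct$z, tolerance = 1e-12)
})

test_that("failed cells become missing and leave the FDR family", {
  set.seed(30)
  n <- 200
  d <- cbind(snpA = rbinom(n, 2, 0.3), snpB = rep(1, n))  # snpB monomorphic
  G <- genotypeMatrix(d)
  traits <- traitTable(data.frame(t1 = rnorm(n), t2 = rnorm(n)))
  scan <- runScan(G, traits, c(snpA = 0.5, snpB = 0.2))
  tab <- scanTable(scan)
  expect_true(all(is.na(tab$pval[tab$predictor == "snpB"])))
  expect_true(all(is.na(tab$qval[tab$predictor == "snpB"])))
  expect_false(any(tab$significant[tab$predictor == "snpB"]))
  # the family size shrinks to the cells that ran
  ran <- !is.na(tab$pval)
  expect_equal(tab$qval[ran], bh_bruteforce(tab$pval[ran]),
               tolerance = 1e-12)
})

test_that("under the global null, scans rarely flag anything", {
  set.seed(31)
  n_reps <- 150
  any_flag <- replicate(n_reps, {
    G <- simulateGenotypes(150, c(0.2, 0.3, 0.4))
    vals <- data.frame(a = rnorm(150), b = rnorm(150), c = rnorm(150),
                       d = rnorm(150), e = rnorm(150))
    scan <- runScan(G, traitTable(vals),
                    stats::setNames(c(0.3, 0.2, 0.1),
                                    colnames(dosages(G))))
    nrow(significantCells(scan)) > 0
  })
  rate <- mean(any_flag)
  # BH controls FDR at 0.05; under the global null any rejection is false,
  # so the any-flag rate is ~5% (3-SE binomial band)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_reps))
})

test_that("scan results serialise as heatmap-ready TSVs", {
  set.seed(32)
  G <- simulateGenotypes(200, c(0.2, 0.4))
  traits <- traitTable(data.frame(t1 = rnorm(200), t2 = rnorm(200)))
  scan <- runScan(G, traits, stats::setNames(c(0.4, 0.2),
                                             colnames(dosages(G))))
  f <- withr::local_tempfile(fileext = ".tsv")
  g <- withr::local_tempfile(fileext = ".tsv")
  writeScanResult(scan, f, companionPath = g)
  z <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(z$predictor, c("snp1", "snp2", "GRS"))
  cells <- read.table(g, header = TRUE, sep = "\t")
  expect_equal(nrow(cells), 6)
})
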