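#' @include pleiotropy.R scales.R
NULL

# non-palindromic allele pairs cycled over synthetic variants
.SYNTH_ALLELES <- list(c("A", "G"), c("C", "A"), c("G", "T"), c("T", "C"))

#' Construct a SimConfig
#'
#' Defaults describe a well-powered synthetic two-sample study with the
#' instrument architecture the package's MR pipeline assumes: four
#' independent variants at effect-allele frequencies 0.1/0.2/0.3/0.4 with
#' equal variance shares jointly explaining R^2 = 0.0147 of an
#' inverse-normal-transformed exposure, a 10% prevalence binary outcome,
#' no causal effect, no sample overlap, and no confounding.
#'
#' @param nExposure,nOutcome GWAS sample sizes.
#' @param eafs per-variant effect-allele frequencies in (0, 1).
#' @param r2Target total exposure variance explained, in (0, 1).
#' @param varianceShares per-variant shares of \code{r2Target}; must sum
#'   to 1 (default equal shares).
#' @param causalLogOR true causal log odds ratio per unit of transformed
#'   exposure.
#' @param prevalence target outcome case fraction.
#' @param overlapFraction fraction of the outcome sample shared with the
#'   exposure sample, in [0, 1].
#' @param confounding effect of a shared standard-normal confounder on the
#'   exposure (per SD) and on the outcome logit; 0 disables it.
#' @param seed RNG seed.
#' @return a [SimConfig-class] object.
#' @export
simConfig <- function(nExposure = 20000, nOutcome = 20000,
                      eafs = c(0.1, 0.2, 0.3, 0.4), r2Target = 0.0147,
                      varianceShares = rep(1 / length(eafs), length(eafs)),
                      causalLogOR = 0, prevalence = 0.1,
                      overlapFraction = 0, confounding = 0, seed = 1) {
  new("SimConfig", nExposure = nExposure, nOutcome = nOutcome, eafs = eafs,
      r2Target = r2Target, varianceShares = varianceShares,
      causalLogOR = causalLogOR, prevalence = prevalence,
      overlapFraction = overlapFraction, confounding = confounding,
      seed = seed)
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each dosage is the sum of two independent Bernoulli(eaf) allele draws, so
#' genotype frequencies follow Hardy-Weinberg proportions.
#'
#' @param n number of individuals.
#' @param eafs per-variant effect-allele frequencies in (0, 1).
#' @param rsid optional variant labels (default snp1, snp2, ...).
#' @param seed optional seed set before drawing; when NULL the current RNG
#'   state is used (callers doing their own seeding).
#' @return a [GenotypeMatrix-class] with non-palindromic synthetic allele
#'   labels.
#' @export
simulateGenotypes <- function(n, eafs, rsid = NULL, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (any(eafs <= 0 | eafs >= 1)) stop("eafs must lie strictly in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  k <- length(eafs)
  if (is.null(rsid)) rsid <- paste0("snp", seq_len(k))
  d <- vapply(eafs, function(f)
    stats::rbinom(n, 1L, f) + stats::rbinom(n, 1L, f), numeric(n))
  if (n == 1) d <- matrix(d, nrow = 1)
  colnames(d) <- rsid
  al <- .SYNTH_ALLELES[((seq_len(k) - 1) %% 4) + 1]
  genotypeMatrix(d, vapply(al, `[`, "", 1), vapply(al, `[`, "", 2))
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal scores \eqn{\Phi^{-1}((r_i - c)/(n + 1 - 2c))}
#' with r_i the rank (ties averaged) and c the Blom offset 3/8 by default.
#' The output preserves the input's rank order and is invariant to any
#' strictly monotone transformation of the input.
#'
#' @param values numeric vector, length >= 2, not all equal, no NAs.
#' @param offset rank offset c (default 3/8).
#' @return transformed values.
#' @examples
#' inverseNormalTransform(c(1, 2, 3))  # approx -0.8416, 0, 0.8416
#' @export
inverseNormalTransform <- function(values, offset = 3 / 8) {
  if (length(values) < 2) stop("need at least 2 values")
  if (anyNA(values)) stop("missing values not supported")
  if (max(values) == min(values))
    stop("constant input: all ranks tied, transform undefined")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - offset) / (length(values) + 1 - 2 * offset))
}

#' Per-variant effect sizes for a target variance explained
#'
#' On the unit-variance exposure scale, variant i with effect-allele
#' frequency f contributes 2 f (1 - f) beta_i^2 of variance; the betas are
#' scaled so the contributions equal \code{r2Target * varianceShares}.
#'
#' @inheritParams simConfig
#' @return numeric vector of per-variant betas.
#' @export
instrumentBetas <- function(eafs, r2Target,
                            varianceShares = rep(1 / length(eafs),
                                                 length(eafs))) {
  if (abs(sum(varianceShares) - 1) > 1e-8 || any(varianceShares <= 0))
    stop("variance shares must be positive and sum to 1")
  if (r2Target <= 0 || r2Target >= 1)
    stop("r2Target must lie strictly in (0, 1)")
  sqrt(r2Target * varianceShares / (2 * eafs * (1 - eafs)))
}

#' Simulate an inverse-normal-transformed polygenic exposure
#'
#' Builds the latent exposure sum(beta_i g_i) + (confounding * u) + noise,
#' with the noise variance chosen so the latent trait has unit variance,
#' then applies [inverseNormalTransform()] (emulating the transformation
#' GWAS of hormone levels apply before association testing).
#'
#' @param G a [GenotypeMatrix-class].
#' @param eafs,r2Target,varianceShares instrument architecture, see
#'   [instrumentBetas()].
#' @param confounder optional per-individual standard-normal confounder.
#' @param confounding its effect on the exposure (per SD).
#' @return list with \code{values} (the transformed exposure),
#'   \code{latent}, and \code{betas}.
#' @export
simulateExposure <- function(G, eafs, r2Target,
                             varianceShares = rep(1 / length(eafs),
                                                  length(eafs)),
                             confounder = NULL, confounding = 0) {
  betas <- instrumentBetas(eafs, r2Target, varianceShares)
  noise_var <- 1 - r2Target - confounding^2
  if (noise_var <= 0)
    stop("infeasible: r2Target + confounding^2 must be < 1")
  d <- dosages(G)
  latent <- drop(d %*% betas) +
    stats::rnorm(nrow(d), sd = sqrt(noise_var))
  if (!is.null(confounder)) latent <- latent + confounding * confounder
  list(values = inverseNormalTransform(latent), latent = latent,
       betas = betas)
}

# bisection for the logistic intercept hitting an expected prevalence
.solve_intercept <- function(eta, prevalence, tol = 1e-8) {
  f <- function(a) mean(stats::plogis(a + eta)) - prevalence
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) stop("cannot bracket the intercept")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a binary outcome from a logistic model
#'
#' P(y = 1) = logistic(alpha + causalLogOR * exposure + confounding * u),
#' with alpha solved by bisection (tolerance 1e-8) so the expected case
#' fraction equals \code{prevalence}.
#'
#' @param exposure per-individual exposure values (finite).
#' @param causalLogOR causal log odds ratio per exposure unit.
#' @param prevalence target case fraction in (0, 1).
#' @param confounder,confounding optional shared confounder and its effect
#'   on the logit.
#' @return list with \code{y} (0/1 vector) and \code{alpha} (the solved
#'   intercept).
#' @export
simulateBinaryOutcome <- function(exposure, causalLogOR, prevalence,
                                  confounder = NULL, confounding = 0) {
  if (any(!is.finite(exposure))) stop("exposure values must be finite")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)")
  eta <- causalLogOR * exposure
  if (!is.null(confounder)) eta <- eta + confounding * confounder
  alpha <- .solve_intercept(eta, prevalence)
  list(y = stats::rbinom(length(exposure), 1L,
                         stats::plogis(alpha + eta)),
       alpha = alpha)
}

#' Marginal per-variant GWAS on simulated data
#'
#' Regresses the phenotype on each variant's dosage separately: closed-form
#' ordinary least squares for \code{family = "linear"} (the fast path used
#' by the simulation studies, equivalent to \code{lm()}), or per-variant
#' logistic regression for \code{family = "logistic"}.
#'
#' @param G a [GenotypeMatrix-class].
#' @param phenotype per-individual trait values (0/1 for logistic).
#' @param family \code{"linear"} or \code{"logistic"}.
#' @param trait trait label for the result.
#' @param scale scale label; defaults to \code{"linear"} or
#'   \code{"log_odds"} by family.
#' @return a [GwasSumstats-class], with \code{eaf} and \code{n} filled from
#'   the genotype matrix.
#' @export
computeSumstats <- function(G, phenotype, family = c("linear", "logistic"),
                            trait = "trait", scale = NULL) {
  family <- match.arg(family)
  d <- dosages(G)
  n <- nrow(d)
  if (length(phenotype) != n)
    stop("phenotype length must match the genotype matrix")
  if (is.null(scale)) scale <- if (family == "linear") "linear" else
    "log_odds"
  if (family == "linear") {
    y <- phenotype
    gm <- colMeans(d)
    ym <- mean(y)
    sxx <- colSums(d^2) - n * gm^2
    sxy <- drop(crossprod(d, y)) - n * gm * ym
    syy <- sum(y^2) - n * ym^2
    beta <- sxy / sxx
    rss <- syy - beta * sxy
    se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
    tval <- beta / se
    pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  } else {
    fits <- lapply(seq_len(ncol(d)), function(i)
      associateTrait(phenotype, d[, i], family = "binary"))
    beta <- vapply(fits, `[[`, numeric(1), "beta")
    se <- vapply(fits, `[[`, numeric(1), "se")
    pval <- vapply(fits, `[[`, numeric(1), "pval")
  }
  pval <- pmax(pval, .Machine$double.xmin)  # keep within (0, 1]
  ea <- effectAllele(G)
  gwasSumstats(data.frame(
    rsid = colnames(d), effect_allele = unname(ea),
    other_allele = G@otherAllele, eaf = pmin(pmax(colMeans(d) / 2, 1e-12),
                                             1 - 1e-12),
    beta = beta, se = se, pval = pval, n = n, stringsAsFactors = FALSE),
    trait = trait, scale = scale, checkPvals = FALSE)
}

#' Simulate a complete two-sample GWAS pair
#'
#' Generates one synthetic exposure GWAS and one synthetic outcome GWAS
#' under a [SimConfig-class]: shared-population Hardy-Weinberg genotypes, an
#' inverse-normal-transformed polygenic exposure, a logistic binary outcome
#' at the configured prevalence, and a configurable fraction of individuals
#' appearing in both samples. The outcome GWAS is run as a linear model on
#' the 0/1 outcome and converted to the log-odds scale with
#' [linearToLogOR()] (emulating the linear-mixed-model-plus-conversion
#' pipeline of large biobank case/control GWAS); set
#' \code{outcomeFamily = "logistic"} for direct logistic fits instead.
#'
#' @param config a [SimConfig-class].
#' @param outcomeFamily \code{"linear_converted"} (default) or
#'   \code{"logistic"}.
#' @return list with \code{exposure} (an [InstrumentSet-class] whose
#'   \code{r2Total} is the realized in-sample R^2), \code{outcome} (a
#'   [GwasSumstats-class] on the log-odds scale), and \code{truth} (a list
#'   recording the generating parameters, the realized R^2 and F-statistic,
#'   realized case fraction, overlap count and seed).
#' @export
simulateTwoSample <- function(config,
                              outcomeFamily = c("linear_converted",
                                                "logistic")) {
  outcomeFamily <- match.arg(outcomeFamily)
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  nE <- config@nExposure
  nO <- config@nOutcome
  nShared <- round(config@overlapFraction * min(nE, nO))
  N <- nE + nO - nShared
  G <- simulateGenotypes(N, config@eafs)
  u <- stats::rnorm(N)
  exp_idx <- seq_len(nE)
  out_idx <- seq.int(N - nO + 1, N)

  sim_exp <- simulateExposure(G, config@eafs, config@r2Target,
                              config@varianceShares,
                              confounder = u,
                              confounding = config@confounding)
  d <- dosages(G)
  Ge <- genotypeMatrix(d[exp_idx, , drop = FALSE], G@effectAllele,
                       G@otherAllele)
  Go <- genotypeMatrix(d[out_idx, , drop = FALSE], G@effectAllele,
                       G@otherAllele)
  x_e <- inverseNormalTransform(sim_exp$latent[exp_idx])
  x_o <- inverseNormalTransform(sim_exp$latent[out_idx])

  out <- simulateBinaryOutcome(x_o, config@causalLogOR, config@prevalence,
                               confounder = u[out_idx],
                               confounding = config@confounding)
  y <- out$y

  exp_ss <- computeSumstats(Ge, x_e, family = "linear", trait = "exposure",
                            scale = "inverse_normal")
  # realized in-sample R2 from the joint fit of the transformed exposure
  Xe <- cbind(1, d[exp_idx, , drop = FALSE])
  fit <- stats::lm.fit(Xe, x_e)
  r2_real <- 1 - sum(fit$residuals^2) / sum((x_e - mean(x_e))^2)
  exposure <- instrumentSet(exp_ss, r2Total = r2_real)

  if (outcomeFamily == "linear_converted") {
    raw <- computeSumstats(Go, y, family = "linear", trait = "outcome",
                           scale = "linear")
    conv <- linearToLogOR(variants(raw)$beta, variants(raw)$se, mean(y))
    v <- variants(raw)
    v$beta <- conv$beta
    v$se <- conv$se
    outcome <- gwasSumstats(v, trait = "outcome", scale = "log_odds",
                            checkPvals = FALSE)
  } else {
    outcome <- computeSumstats(Go, y, family = "logistic",
                               trait = "outcome", scale = "log_odds")
  }

  k <- length(config@eafs)
  truth <- list(causalLogOR = config@causalLogOR,
                betas = sim_exp$betas,
                realizedR2 = r2_real,
                realizedF = fValue(fStatistic(r2_real, nE, k)),
                caseFraction = mean(y),
                alpha = out$alpha,
                nShared = nShared,
                seed = config@seed)
  list(exposure = exposure, outcome = outcome, truth = truth)
}
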