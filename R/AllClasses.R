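#' @import methods
NULL

.VALID_ALLELES <- c("A", "C", "G", "T")
.SUMSTAT_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

#' GwasSumstats: per-variant GWAS summary statistics for one trait
#'
#' Container for marginal single-variant association records (the atoms of
#' two-sample Mendelian randomization): variant identifier, alleles,
#' effect-allele frequency, effect estimate with its standard error, p-value
#' and sample size, together with trait-level metadata (trait label and the
#' scale the effect sizes are reported on).
#'
#' @slot variants data.frame with one row per variant and columns
#'   \code{rsid}, \code{chrom}, \code{pos}, \code{effect_allele},
#'   \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pval},
#'   \code{n}. \code{chrom}, \code{pos}, \code{pval} may be \code{NA}.
#' @slot trait single character label for the trait.
#' @slot scale one of \code{"linear"}, \code{"log_odds"},
#'   \code{"inverse_normal"}: the scale of \code{beta}.
#'
#' @section Validity:
#' Alleles must be single bases in A/C/G/T with effect != other allele;
#' \code{se > 0}; \code{0 < eaf < 1}; \code{pval} in (0, 1] when present;
#' \code{n} a positive count; no duplicated \code{rsid}.
#'
#' @seealso [gwasSumstats()], [readSumstats()], [harmonize()]
#' @export
setClass("GwasSumstats",
  representation(variants = "data.frame", trait = "character",
                 scale = "character"))

setValidity("GwasSumstats", function(object) {
  v <- object@variants
  msgs <- character(0)
  missing_cols <- setdiff(.SUMSTAT_COLS, names(v))
  if (length(missing_cols) > 0)
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (length(object@trait) != 1L) msgs <- c(msgs, "trait must be length 1")
  if (length(object@scale) != 1L ||
      !object@scale %in% c("linear", "log_odds", "inverse_normal"))
    msgs <- c(msgs, "scale must be one of linear, log_odds, inverse_normal")
  if (nrow(v) > 0) {
    if (anyDuplicated(v$rsid))
      msgs <- c(msgs, "duplicate rsid in variant table")
    bad <- !(v$effect_allele %in% .VALID_ALLELES) |
           !(v$other_allele %in% .VALID_ALLELES)
    if (any(bad))
      msgs <- c(msgs, paste0("invalid alleles for: ",
                             paste(v$rsid[bad], collapse = ", ")))
    same <- !bad & v$effect_allele == v$other_allele
    if (any(same))
      msgs <- c(msgs, paste0("effect allele equals other allele for: ",
                             paste(v$rsid[same], collapse = ", ")))
    if (any(!is.na(v$eaf) & (v$eaf <= 0 | v$eaf >= 1)))
      msgs <- c(msgs, "eaf must lie strictly in (0, 1)")
    if (any(is.na(v$se) | v$se <= 0))
      msgs <- c(msgs, "se must be positive")
    if (any(!is.na(v$pval) & (v$pval <= 0 | v$pval > 1)))
      msgs <- c(msgs, "pval must lie in (0, 1]")
    if (any(!is.na(v$n) & v$n <= 0))
      msgs <- c(msgs, "n must be a positive count")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' InstrumentSet: exposure instruments plus total variance explained
#'
#' A [GwasSumstats-class] for the exposure together with the total proportion
#' of exposure variance the instruments explain (R^2), which drives the
#' weak-instrument F-statistic.
#'
#' @slot r2Total proportion of exposure variance explained, in (0, 1).
#' @seealso [instrumentSet()], [fStatistic()]
#' @export
setClass("InstrumentSet", contains = "GwasSumstats",
  representation(r2Total = "numeric"))

setValidity("InstrumentSet", function(object) {
  if (length(object@r2Total) != 1L || is.na(object@r2Total) ||
      object@r2Total <= 0 || object@r2Total >= 1)
    return("r2Total must be a single value strictly in (0, 1)")
  if (nrow(object@variants) < 1L)
    return("an instrument set needs at least one variant")
  TRUE
})

#' HarmonizedPairs: exposure/outcome records aligned to a common effect allele
#'
#' Result of [harmonize()]: one row per exposure instrument matched in the
#' outcome summary statistics, with the action taken (\code{none},
#' \code{flipped}, \code{dropped_palindromic}, \code{dropped_mismatch}) and,
#' for retained rows, outcome beta/eaf re-expressed for the exposure's effect
#' allele.
#'
#' @slot pairs data.frame with columns \code{rsid}, \code{palindromic},
#'   \code{action}, exposure columns (\code{beta_exposure},
#'   \code{se_exposure}, \code{eaf_exposure}, \code{effect_allele},
#'   \code{other_allele}) and outcome columns (\code{beta_outcome},
#'   \code{se_outcome}, \code{eaf_outcome}, \code{pval_outcome},
#'   \code{n_outcome}).
#' @slot unmatched rsids of instruments absent from the outcome data.
#' @slot exposureTrait,outcomeTrait trait labels carried over from the inputs.
#' @export
setClass("HarmonizedPairs",
  representation(pairs = "data.frame", unmatched = "character",
                 exposureTrait = "character", outcomeTrait = "character"))

setValidity("HarmonizedPairs", function(object) {
  p <- object@pairs
  ok_actions <- c("none", "flipped", "dropped_palindromic", "dropped_mismatch")
  if (nrow(p) > 0 && !all(p$action %in% ok_actions))
    return("unknown harmonization action")
  TRUE
})

#' StudyMeta: case/control composition of a binary-trait GWAS
#'
#' Case and control counts for one outcome data source. The case fraction
#' mu = nCases / (nCases + nControls) is the quantity needed to convert
#' linear-mixed-model effect estimates on a 0/1 trait to the log-odds scale.
#'
#' @slot nCases,nControls positive integer counts.
#' @seealso [studyMeta()], [linearToLogOR()]
#' @export
setClass("StudyMeta", representation(nCases = "numeric", nControls = "numeric"))

setValidity("StudyMeta", function(object) {
  if (length(object@nCases) != 1L || length(object@nControls) != 1L ||
      is.na(object@nCases) || is.na(object@nControls) ||
      object@nCases < 1 || object@nControls < 1 ||
      object@nCases != round(object@nCases) ||
      object@nControls != round(object@nControls))
    return("nCases and nControls must be positive integers")
  TRUE
})

#' IVWResult: pooled causal estimate with heterogeneity diagnostics
#'
#' Result of [ivw()]: the inverse-variance weighted pooled log-odds causal
#' estimate, its fixed-effect standard error, the multiplicative
#' random-effects inflation factor phi = max(1, sqrt(Q / (k - 1))), the SE
#' actually used, odds-ratio scale CI and p-value, Cochran's Q with df and
#' upper-tail chi-square p, and the per-variant Wald estimates that entered.
#'
#' @slot thetaHat pooled estimate on the log-odds scale.
#' @slot seFixed fixed-effect SE, 1/sqrt(sum of weights).
#' @slot phi SE inflation factor actually applied (1 in fixed mode).
#' @slot seUsed SE used for CI and p (seFixed * phi, or DL for additive mode).
#' @slot or,ciLower,ciUpper,pval odds-ratio scale summaries.
#' @slot Q,qDf,qPval Cochran's Q, its df (k - 1) and p; all NA when k = 1.
#' @slot k number of variants pooled.
#' @slot mode \code{"fixed"}, \code{"multiplicative_random"} or
#'   \code{"additive_random"}.
#' @slot level confidence level used.
#' @slot estimates the per-variant Wald estimate table (see [waldRatio()]).
#' @export
setClass("IVWResult",
  representation(thetaHat = "numeric", seFixed = "numeric", phi = "numeric",
                 seUsed = "numeric", or = "numeric", ciLower = "numeric",
                 ciUpper = "numeric", pval = "numeric", Q = "numeric",
                 qDf = "numeric", qPval = "numeric", k = "numeric",
                 mode = "character", level = "numeric",
                 estimates = "data.frame"))

setValidity("IVWResult", function(object) {
  msgs <- character(0)
  if (!is.na(object@Q) && object@Q < 0) msgs <- c(msgs, "Q must be >= 0")
  if (object@seUsed < object@seFixed - 1e-12)
    msgs <- c(msgs, "seUsed cannot be smaller than seFixed")
  if (object@k >= 1 && nrow(object@estimates) > 0) {
    th <- object@estimates$theta
    if (object@thetaHat < min(th) - 1e-12 || object@thetaHat > max(th) + 1e-12)
      msgs <- c(msgs, "pooled estimate must lie within the per-variant range")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' FStat: instrument-strength F-statistic
#'
#' F = (R^2 / (1 - R^2)) * ((n - k - 1) / k), the approximate first-stage
#' F-statistic from the proportion of exposure variance explained (R^2), a
#' sample size n and the number of instruments k. Values well above 10
#' indicate strong instruments.
#'
#' @slot value the F-statistic.
#' @slot r2,n,k the inputs it was computed from.
#' @seealso [fStatistic()]
#' @export
setClass("FStat", representation(value = "numeric", r2 = "numeric",
                                 n = "numeric", k = "numeric"))

#' GenotypeMatrix: individual-level allele dosages
#'
#' Individuals x variants matrix of effect-allele dosages in [0, 2] with the
#' effect (counted) and other allele recorded per variant.
#'
#' @slot dosages numeric matrix, rows = individuals, columns = variants
#'   (column names are the variant labels, unique).
#' @slot effectAllele,otherAllele character vectors, one entry per variant.
#' @seealso [genotypeMatrix()], [simulateGenotypes()], [buildGRS()]
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", effectAllele = "character",
                 otherAllele = "character"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  msgs <- character(0)
  if (is.null(colnames(d)) || anyDuplicated(colnames(d)))
    msgs <- c(msgs, "dosage columns must carry unique variant labels")
  if (length(object@effectAllele) != ncol(d) ||
      length(object@otherAllele) != ncol(d))
    msgs <- c(msgs, "one effect and other allele per variant required")
  rng <- suppressWarnings(range(d, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    msgs <- c(msgs, "dosages must lie within [0, 2]")
  if (length(msgs) == 0) TRUE else msgs
})

#' TraitTable: per-individual trait values with family metadata
#'
#' @slot values data.frame, one column per trait, one row per individual.
#' @slot family named character vector over the traits, each
#'   \code{"continuous"} or \code{"binary"}; binary traits must be coded 0/1.
#' @seealso [traitTable()], [runScan()]
#' @export
setClass("TraitTable",
  representation(values = "data.frame", family = "character"))

setValidity("TraitTable", function(object) {
  msgs <- character(0)
  if (!identical(sort(names(object@family)), sort(names(object@values))))
    msgs <- c(msgs, "family must be named by the trait columns")
  if (!all(object@family %in% c("continuous", "binary")))
    msgs <- c(msgs, "family entries must be 'continuous' or 'binary'")
  for (tr in names(object@family)[object@family == "binary"]) {
    y <- object@values[[tr]]
    if (!all(is.na(y) | y %in% c(0, 1)))
      msgs <- c(msgs, paste0("binary trait '", tr, "' must be coded 0/1"))
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' ScanResult: predictor x trait association scan
#'
#' Result of [runScan()]: one cell per (predictor, trait) pair, where the
#' predictors are each variant's dosage and the weighted genetic risk score
#' ("GRS"). Each cell carries the regression slope, its SE, the z-score
#' aligned with the direction of higher genetically predicted exposure, the
#' p-value and the Benjamini-Hochberg q-value, plus a significance flag at
#' the configured FDR threshold. Cells whose fit failed are missing and are
#' excluded from the FDR family.
#'
#' @slot results long-format data.frame with columns \code{predictor},
#'   \code{trait}, \code{beta}, \code{se}, \code{z_aligned}, \code{pval},
#'   \code{qval}, \code{significant}, \code{converged}.
#' @slot predictors,traits the row/column labels of the scan grid.
#' @slot fdrThreshold significance threshold on the q-value.
#' @slot fdrScope \code{"global"} (one family over all cells) or
#'   \code{"per_predictor"}.
#' @seealso [runScan()], [zMatrix()], [writeScanResult()]
#' @export
setClass("ScanResult",
  representation(results = "data.frame", predictors = "character",
                 traits = "character", fdrThreshold = "numeric",
                 fdrScope = "character"))

setValidity("ScanResult", function(object) {
  r <- object@results
  ok <- is.na(r$qval) | is.na(r$pval) | r$qval >= r$pval - 1e-12
  if (!all(ok)) return("q-values cannot be smaller than p-values")
  flag_ok <- is.na(r$qval) | (r$significant == (r$qval < object@fdrThreshold))
  if (!all(flag_ok, na.rm = TRUE))
    return("significance flags inconsistent with the FDR threshold")
  TRUE
})

#' SimConfig: parameters of the synthetic two-sample GWAS generator
#'
#' Describes one simulated study: exposure- and outcome-GWAS sample sizes,
#' per-variant effect-allele frequencies, total exposure variance explained
#' by the instruments (with per-variant shares), the true causal log odds
#' ratio per unit of inverse-normal-transformed exposure, the outcome
#' prevalence, the fraction of the outcome sample shared with the exposure
#' sample, an optional shared-confounder effect, and the RNG seed.
#'
#' @slot nExposure,nOutcome sample sizes of the two GWASs.
#' @slot eafs per-variant effect-allele frequencies in (0, 1).
#' @slot r2Target total exposure variance explained, in (0, 1).
#' @slot varianceShares per-variant shares of r2Target, summing to 1.
#' @slot causalLogOR true causal effect, log-odds per 1 unit of
#'   inverse-normal-transformed exposure.
#' @slot prevalence target outcome case fraction, in (0, 1).
#' @slot overlapFraction fraction of the outcome sample shared with the
#'   exposure sample, in [0, 1].
#' @slot confounding effect of a shared standard-normal confounder on both
#'   the exposure (per SD) and the outcome logit; 0 disables it.
#' @slot seed integer RNG seed.
#' @seealso [simConfig()], [simulateTwoSample()]
#' @export
setClass("SimConfig",
  representation(nExposure = "numeric", nOutcome = "numeric",
                 eafs = "numeric", r2Target = "numeric",
                 varianceShares = "numeric", causalLogOR = "numeric",
                 prevalence = "numeric", overlapFraction = "numeric",
                 confounding = "numeric", seed = "numeric"))

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (object@nExposure < 2 || object@nOutcome < 2)
    msgs <- c(msgs, "sample sizes must be at least 2")
  if (any(object@eafs <= 0 | object@eafs >= 1))
    msgs <- c(msgs, "eafs must lie strictly in (0, 1)")
  if (object@r2Target <= 0 || object@r2Target >= 1)
    msgs <- c(msgs, "r2Target must lie strictly in (0, 1)")
  if (length(object@varianceShares) != length(object@eafs))
    msgs <- c(msgs, "one variance share per variant required")
  if (abs(sum(object@varianceShares) - 1) > 1e-8 ||
      any(object@varianceShares <= 0))
    msgs <- c(msgs, "variance shares must be positive and sum to 1")
  if (object@prevalence <= 0 || object@prevalence >= 1)
    msgs <- c(msgs, "prevalence must lie strictly in (0, 1)")
  if (object@overlapFraction < 0 || object@overlapFraction > 1)
    msgs <- c(msgs, "overlapFraction must lie in [0, 1]")
  if (length(msgs) == 0) TRUE else msgs
})
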