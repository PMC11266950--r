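#' @include sumstats.R
NULL

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.isPalindromic <- function(ea, oa) .COMPLEMENT[ea] == oa

#' Harmonize outcome summary statistics to the exposure's effect alleles
#'
#' In two-sample Mendelian randomization the exposure and outcome effect
#' sizes for a variant must refer to the same allele before a Wald ratio can
#' be formed. For each exposure instrument matched by rsid in the outcome
#' data this function decides one of four actions:
#' \describe{
#'   \item{none}{allele pairs already identical.}
#'   \item{flipped}{outcome effect/other alleles are swapped relative to the
#'     exposure (possibly after strand complementing): the outcome beta is
#'     negated and its eaf replaced by 1 - eaf.}
#'   \item{dropped_palindromic}{A/T or C/G variant whose strand cannot be
#'     resolved: dropped when either study's effect-allele frequency lies
#'     within \code{palindromeEafWindow} of 0.5, or when either frequency is
#'     missing; otherwise the variant is aligned by frequency (the outcome
#'     orientation making the frequencies fall on the same side of 0.5 is
#'     chosen) and retained.}
#'   \item{dropped_mismatch}{alleles irreconcilable even after strand
#'     complementing.}
#' }
#' Non-palindromic variants with a missing frequency are harmonized from the
#' allele letters alone. Instruments absent from the outcome data are
#' reported via [unmatched()].
#'
#' @param exposure an [InstrumentSet-class] or [GwasSumstats-class] with the
#'   exposure associations.
#' @param outcome a [GwasSumstats-class] (or data.frame coercible via
#'   [gwasSumstats()]) with the outcome associations.
#' @param palindromeEafWindow half-width of the ambiguity window around an
#'   allele frequency of 0.5 for palindromic variants (default 0.08).
#' @return a [HarmonizedPairs-class] object.
#' @examples
#' exp <- instrumentSet(data.frame(rsid = "rs1", effect_allele = "A",
#'   other_allele = "G", eaf = 0.2, beta = 0.1, se = 0.01), r2Total = 0.01)
#' out <- gwasSumstats(data.frame(rsid = "rs1", effect_allele = "G",
#'   other_allele = "A", eaf = 0.8, beta = -0.05, se = 0.02))
#' pairsTable(harmonize(exp, out))  # action "flipped", beta_outcome 0.05
#' @export
harmonize <- function(exposure, outcome, palindromeEafWindow = 0.08) {
  if (!is(exposure, "GwasSumstats"))
    stop("exposure must be a GwasSumstats or InstrumentSet")
  if (is.data.frame(outcome))
    outcome <- gwasSumstats(outcome, trait = "outcome", checkPvals = FALSE)
  ev <- variants(exposure)
  ov <- variants(outcome)
  if (anyDuplicated(ev$rsid))
    stop("ambiguity error: duplicate rsid in exposure input")
  if (anyDuplicated(ov$rsid))
    stop("ambiguity error: duplicate rsid in outcome input")

  idx <- match(ev$rsid, ov$rsid)
  unmatched <- ev$rsid[is.na(idx)]
  keep <- !is.na(idx)
  ev <- ev[keep, , drop = FALSE]
  ovm <- ov[idx[keep], , drop = FALSE]

  n <- nrow(ev)
  action <- character(n)
  pal <- logical(n)
  beta_o <- ovm$beta
  eaf_o <- ovm$eaf
  for (i in seq_len(n)) {
    ea <- ev$effect_allele[i]; oa <- ev$other_allele[i]
    eb <- ovm$effect_allele[i]; ob <- ovm$other_allele[i]
    pal[i] <- .isPalindromic(ea, oa)
    if (pal[i]) {
      if (!setequal(c(eb, ob), c(ea, oa))) {
        action[i] <- "dropped_mismatch"
        next
      }
      if (is.na(ev$eaf[i]) || is.na(ovm$eaf[i]) ||
          abs(ev$eaf[i] - 0.5) < palindromeEafWindow ||
          abs(ovm$eaf[i] - 0.5) < palindromeEafWindow) {
        action[i] <- "dropped_palindromic"
        next
      }
      # letter-based candidate, then frequency concordance decides strand
      cand <- if (eb == ea) "none" else "flipped"
      eaf_aligned <- if (cand == "none") ovm$eaf[i] else 1 - ovm$eaf[i]
      if (sign(eaf_aligned - 0.5) != sign(ev$eaf[i] - 0.5))
        cand <- if (cand == "none") "flipped" else "none"
      action[i] <- cand
    } else {
      if (eb == ea && ob == oa) action[i] <- "none"
      else if (eb == oa && ob == ea) action[i] <- "flipped"
      else {
        ebc <- .COMPLEMENT[eb]; obc <- .COMPLEMENT[ob]
        if (ebc == ea && obc == oa) action[i] <- "none"
        else if (ebc == oa && obc == ea) action[i] <- "flipped"
        else action[i] <- "dropped_mismatch"
      }
    }
    if (action[i] == "flipped") {
      beta_o[i] <- -beta_o[i]
      eaf_o[i] <- 1 - eaf_o[i]
    }
  }

  pairs <- data.frame(
    rsid = ev$rsid, effect_allele = ev$effect_allele,
    other_allele = ev$other_allele, palindromic = pal, action = action,
    beta_exposure = ev$beta, se_exposure = ev$se, eaf_exposure = ev$eaf,
    beta_outcome = beta_o, se_outcome = ovm$se, eaf_outcome = eaf_o,
    pval_outcome = ovm$pval, n_outcome = ovm$n,
    stringsAsFactors = FALSE)
  new("HarmonizedPairs", pairs = pairs, unmatched = unmatched,
      exposureTrait = traitName(exposure), outcomeTrait = traitName(outcome))
}

#' Retained pairs of a harmonization
#'
#' @param x a [HarmonizedPairs-class] object.
#' @return the rows of [pairsTable()] whose action is \code{none} or
#'   \code{flipped}.
#' @export
retainedPairs <- function(x) {
  p <- pairsTable(x)
  p[p$action %in% c("none", "flipped"), , drop = FALSE]
}

#' Re-expressed outcome records after harmonization
#'
#' Rebuilds a [GwasSumstats-class] holding the retained outcome records on
#' the exposure's allele orientation; harmonizing these against the same
#' exposure is a no-op (idempotence).
#'
#' @param x a [HarmonizedPairs-class] object.
#' @return a [GwasSumstats-class] of the retained outcome associations.
#' @export
harmonizedOutcome <- function(x) {
  p <- retainedPairs(x)
  gwasSumstats(data.frame(
    rsid = p$rsid, effect_allele = p$effect_allele,
    other_allele = p$other_allele, eaf = p$eaf_outcome,
    beta = p$beta_outcome, se = p$se_outcome, pval = p$pval_outcome,
    n = p$n_outcome, stringsAsFactors = FALSE),
    trait = x@outcomeTrait, scale = "log_odds", checkPvals = FALSE)
}
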