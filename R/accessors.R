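#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("variants", "GwasSumstats", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("nVariants", "GwasSumstats", function(x) nrow(x@variants))

#' @rdname accessors
#' @export
setMethod("traitName", "GwasSumstats", function(x) x@trait)

#' @rdname accessors
#' @export
setMethod("effectScale", "GwasSumstats", function(x) x@scale)

#' @rdname accessors
#' @export
setMethod("r2Total", "InstrumentSet", function(x) x@r2Total)

#' @rdname accessors
#' @export
setMethod("pairsTable", "HarmonizedPairs", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("unmatched", "HarmonizedPairs", function(x) x@unmatched)

#' @rdname accessors
#' @export
setMethod("caseFraction", "StudyMeta",
          function(x) x@nCases / (x@nCases + x@nControls))

#' @rdname accessors
#' @export
setMethod("nTotal", "StudyMeta", function(x) x@nCases + x@nControls)

#' @rdname accessors
#' @export
setMethod("thetaHat", "IVWResult", function(x) x@thetaHat)

#' @rdname accessors
#' @export
setMethod("seUsed", "IVWResult", function(x) x@seUsed)

#' @rdname accessors
#' @export
setMethod("seFixed", "IVWResult", function(x) x@seFixed)

#' @rdname accessors
#' @export
setMethod("oddsRatio", "IVWResult", function(x) x@or)

#' @rdname accessors
#' @export
setMethod("confInt", "IVWResult",
          function(x) c(lower = x@ciLower, upper = x@ciUpper))

#' @rdname accessors
#' @export
setMethod("pValue", "IVWResult", function(x) x@pval)

#' @rdname accessors
#' @export
setMethod("cochranQ", "IVWResult",
          function(x) c(Q = x@Q, df = x@qDf, pval = x@qPval))

#' @rdname accessors
#' @export
setMethod("estimates", "IVWResult", function(x) x@estimates)

#' @rdname accessors
#' @export
setMethod("fValue", "FStat", function(x) x@value)

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @rdname accessors
#' @export
setMethod("effectAllele", "GenotypeMatrix", function(x) {
  stats::setNames(x@effectAllele, colnames(x@dosages))
})

#' @rdname accessors
#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) ncol(x@dosages))

#' @rdname accessors
#' @export
setMethod("scanTable", "ScanResult", function(x) x@results)

.scan_matrix <- function(x, col) {
  m <- matrix(NA_real_, nrow = length(x@predictors),
              ncol = length(x@traits),
              dimnames = list(x@predictors, x@traits))
  r <- x@results
  m[cbind(match(r$predictor, x@predictors), match(r$trait, x@traits))] <-
    r[[col]]
  m
}

#' @rdname accessors
#' @export
setMethod("zMatrix", "ScanResult", function(x) .scan_matrix(x, "z_aligned"))

#' @rdname accessors
#' @export
setMethod("qMatrix", "ScanResult", function(x) .scan_matrix(x, "qval"))

#' @rdname accessors
#' @export
setMethod("significantCells", "ScanResult", function(x) {
  r <- x@results
  r[!is.na(r$significant) & r$significant,
    c("predictor", "trait", "z_aligned", "pval", "qval")]
})

setMethod("show", "GwasSumstats", function(object) {
  cat(sprintf("%s: %d variant(s), trait '%s' [%s scale]\n",
              class(object), nrow(object@variants), object@trait,
              object@scale))
  if (nrow(object@variants) > 0)
    print(utils::head(object@variants, 5), row.names = FALSE)
  if (nrow(object@variants) > 5) cat("...\n")
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet: k = %d instrument(s) for '%s', R2 = %.4g\n",
              nrow(object@variants), object@trait, object@r2Total))
  print(utils::head(object@variants, 5), row.names = FALSE)
})

setMethod("show", "HarmonizedPairs", function(object) {
  tab <- table(factor(object@pairs$action,
                      levels = c("none", "flipped", "dropped_palindromic",
                                 "dropped_mismatch")))
  cat(sprintf("HarmonizedPairs: '%s' -> '%s', %d matched pair(s)\n",
              object@exposureTrait, object@outcomeTrait,
              nrow(object@pairs)))
  cat(sprintf("  actions: %s\n",
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  if (length(object@unmatched) > 0)
    cat("  unmatched instruments:",
        paste(object@unmatched, collapse = ", "), "\n")
})

setMethod("show", "StudyMeta", function(object) {
  cat(sprintf("StudyMeta: %d cases / %d controls (case fraction %.4f)\n",
              object@nCases, object@nControls, caseFraction(object)))
})

setMethod("show", "IVWResult", function(object) {
  cat(sprintf("IVW (%s), k = %d: OR %.3f [%g%% CI %.3f-%.3f], p = %.3g\n",
              object@mode, object@k, object@or, 100 * object@level,
              object@ciLower, object@ciUpper, object@pval))
  if (!is.na(object@Q))
    cat(sprintf("  Cochran's Q = %.3f (df %d, p = %.3g), phi = %.3f\n",
                object@Q, object@qDf, object@qPval, object@phi))
})

setMethod("show", "FStat", function(object) {
  cat(sprintf("F-statistic %.1f (R2 = %.4g, n = %d, k = %d)\n",
              object@value, object@r2, object@n, object@k))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individual(s) x %d variant(s)\n",
              nrow(object@dosages), ncol(object@dosages)))
})

setMethod("show", "TraitTable", function(object) {
  cat(sprintf("TraitTable: %d individual(s) x %d trait(s) (%d binary)\n",
              nrow(object@values), ncol(object@values),
              sum(object@family == "binary")))
})

setMethod("show", "ScanResult", function(object) {
  sig <- significantCells(object)
  cat(sprintf(
    "ScanResult: %d predictor(s) x %d trait(s), FDR < %g (%s family)\n",
    length(object@predictors), length(object@traits),
    object@fdrThreshold, object@fdrScope))
  cat(sprintf("  %d significant cell(s)\n", nrow(sig)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: n_exposure = %d, n_outcome = %d, %d variant(s), ",
    "R2 = %.4g\n  causal log-OR = %.3g, prevalence = %.3g, overlap = %.3g, ",
    "confounding = %.3g, seed = %d\n"),
    object@nExposure, object@nOutcome, length(object@eafs), object@r2Target,
    object@causalLogOR, object@prevalence, object@overlapFraction,
    object@confounding, object@seed))
})
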