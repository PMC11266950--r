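#' @include mr-core.R
NULL

#' Construct a GenotypeMatrix
#'
#' @param dosages individuals x variants numeric matrix of effect-allele
#'   dosages in [0, 2]; column names are the variant labels.
#' @param effectAllele,otherAllele per-variant alleles (recycled defaults
#'   "A"/"G" are placeholders for purely synthetic genotypes).
#' @return a [GenotypeMatrix-class] object.
#' @export
genotypeMatrix <- function(dosages, effectAllele = NULL, otherAllele = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  if (is.null(effectAllele)) effectAllele <- rep("A", ncol(dosages))
  if (is.null(otherAllele)) otherAllele <- rep("G", ncol(dosages))
  new("GenotypeMatrix", dosages = dosages,
      effectAllele = as.character(effectAllele),
      otherAllele = as.character(otherAllele))
}

#' Construct a TraitTable
#'
#' @param values data.frame of per-individual trait values, one column per
#'   trait.
#' @param family named character vector ("continuous"/"binary") over the
#'   trait columns; a single unnamed value is recycled.
#' @return a [TraitTable-class] object.
#' @export
traitTable <- function(values, family = "continuous") {
  values <- as.data.frame(values)
  if (is.null(names(family)) && length(family) == 1L)
    family <- stats::setNames(rep(family, ncol(values)), names(values))
  new("TraitTable", values = values, family = family)
}

#' Weighted genetic risk score
#'
#' score_j = sum_i w_i g_ij over the variants, with each weight first
#' aligned to the allele the dosage counts: a weight stated for a variant's
#' other allele is applied to the reflected dosage 2 - g (equivalently, the
#' weight is negated up to a constant shift, which association z-scores are
#' invariant to). No normalisation by the weight sum is applied, since it
#' only rescales the score.
#'
#' @param G a [GenotypeMatrix-class].
#' @param weights data.frame with columns \code{rsid}, \code{allele},
#'   \code{beta} (the per-variant exposure effects), or a named numeric
#'   vector already aligned to G's effect alleles.
#' @return numeric vector of per-individual scores.
#' @export
buildGRS <- function(G, weights) {
  d <- dosages(G)
  ids <- colnames(d)
  if (is.numeric(weights)) {
    if (is.null(names(weights)) && length(weights) == ncol(d))
      names(weights) <- ids
    weights <- data.frame(rsid = names(weights),
                          allele = effectAllele(G)[names(weights)],
                          beta = as.numeric(weights),
                          stringsAsFactors = FALSE)
  }
  miss <- setdiff(ids, weights$rsid)
  if (length(miss) > 0)
    stop("no weight for variant(s): ", paste(miss, collapse = ", "))
  w <- weights[match(ids, weights$rsid), , drop = FALSE]
  ea <- effectAllele(G)
  score <- numeric(nrow(d))
  for (i in seq_along(ids)) {
    g <- d[, i]
    if (identical(w$allele[i], ea[[ids[i]]])) {
      score <- score + w$beta[i] * g
    } else {
      score <- score + w$beta[i] * (2 - g)
    }
  }
  unname(score)
}

#' Single-predictor association fit
#'
#' Fits trait ~ predictor (+ covariates) with a linear model for continuous
#' traits or a logistic model for binary traits, and reports the
#' predictor's slope, SE, z = beta/se and two-sided normal p-value.
#' Non-convergent logistic fits are returned flagged
#' (\code{converged = FALSE}) so callers can exclude them from FDR
#' correction.
#'
#' @param y trait values (0/1 for binary).
#' @param x predictor: a dosage vector or a genetic risk score.
#' @param covariates optional numeric matrix/data.frame of adjustment
#'   covariates.
#' @param family \code{"continuous"} or \code{"binary"}.
#' @return list(beta, se, z, pval, n, converged).
#' @export
associateTrait <- function(y, x, covariates = NULL,
                           family = c("continuous", "binary")) {
  family <- match.arg(family)
  X <- cbind(intercept = 1, x = x)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  ok <- stats::complete.cases(X, y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  if (length(y) < 10)
    stop("fewer than 10 complete cases")
  if (stats::var(X[, "x"]) == 0)
    stop("degenerate design: predictor has zero variance")
  if (family == "continuous") {
    fit <- stats::lm.fit(X, y)
    if (fit$rank < ncol(X))
      stop("degenerate design: collinear predictors")
    rss <- sum(fit$residuals^2)
    df <- length(y) - fit$rank
    XtX_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(rss / df * XtX_inv[2, 2])
    beta <- fit$coefficients[["x"]]
    converged <- TRUE
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    beta <- fit$coefficients[["x"]]
    cov_un <- chol2inv(chol(crossprod(sqrt(fit$weights) * X)))
    se <- sqrt(cov_un[2, 2])
    converged <- fit$converged && is.finite(beta) && is.finite(se) &&
      abs(beta) < 20
  }
  z <- beta / se
  list(beta = beta, se = se, z = z,
       pval = 2 * stats::pnorm(-abs(z)), n = length(y),
       converged = converged)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: with the p-values sorted ascending,
#' q_(i) = min over j >= i of p_(j) m / j, capped at 1, returned in the
#' input order. Missing p-values (e.g. failed fits) propagate as missing
#' and do not count towards the family size m.
#'
#' @param pvals numeric vector of p-values in [0, 1] (NAs allowed).
#' @return q-values in the input order.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFDR <- function(pvals) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Variant-and-GRS phenome scan for pleiotropy
#'
#' Tests each variant's dosage, and the weighted genetic risk score built
#' from the exposure weights, against every trait in \code{traits}
#' (linear or logistic per the trait's family), producing a predictor x
#' trait grid of z-scores aligned with the direction of higher genetically
#' predicted exposure: for a variant whose (allele-aligned) exposure weight
#' is negative, the sign of z is flipped, so +z always means
#' "exposure-raising genotype associates positively with the trait". The
#' GRS already points in the exposure-raising direction. FDR correction is
#' applied across all cells jointly (default) or per predictor; failed or
#' non-convergent cells are missing and excluded from the family.
#'
#' @param G a [GenotypeMatrix-class].
#' @param traits a [TraitTable-class].
#' @param weights per-variant exposure weights, as in [buildGRS()].
#' @param covariates optional covariate matrix passed to every fit.
#' @param fdrThreshold significance threshold on q (default 0.05).
#' @param fdrScope \code{"global"} or \code{"per_predictor"}.
#' @param grsLabel label of the risk-score row (default "GRS").
#' @return a [ScanResult-class] object.
#' @export
runScan <- function(G, traits, weights, covariates = NULL,
                    fdrThreshold = 0.05,
                    fdrScope = c("global", "per_predictor"),
                    grsLabel = "GRS") {
  fdrScope <- match.arg(fdrScope)
  d <- dosages(G)
  ids <- colnames(d)
  if (is.numeric(weights)) {
    if (is.null(names(weights)) && length(weights) == ncol(d))
      names(weights) <- ids
    weights <- data.frame(rsid = names(weights),
                          allele = effectAllele(G)[names(weights)],
                          beta = as.numeric(weights),
                          stringsAsFactors = FALSE)
  }
  w <- weights[match(ids, weights$rsid), , drop = FALSE]
  ea <- effectAllele(G)
  # alignment factor: +1 if counting the dosage allele raises the exposure
  aligned_w <- ifelse(w$allele == ea[ids], w$beta, -w$beta)
  grs <- buildGRS(G, weights)
  predictors <- c(ids, grsLabel)
  pred_x <- c(lapply(seq_along(ids), function(i) d[, i]), list(grs))
  align <- c(sign(aligned_w), 1)
  trait_vals <- traits@values
  fam <- traits@family

  rows <- list()
  for (p in seq_along(predictors)) {
    for (tr in names(trait_vals)) {
      res <- tryCatch(
        associateTrait(trait_vals[[tr]], pred_x[[p]],
                       covariates = covariates, family = fam[[tr]]),
        error = function(e) NULL)
      failed <- is.null(res) || !res$converged
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = predictors[p], trait = tr,
        beta = if (failed) NA_real_ else res$beta,
        se = if (failed) NA_real_ else res$se,
        z_aligned = if (failed) NA_real_ else align[p] * res$z,
        pval = if (failed) NA_real_ else res$pval,
        converged = !failed, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$qval <- NA_real_
  if (fdrScope == "global") {
    res$qval <- bhFDR(res$pval)
  } else {
    for (p in predictors) {
      sel <- res$predictor == p
      res$qval[sel] <- bhFDR(res$pval[sel])
    }
  }
  res$significant <- !is.na(res$qval) & res$qval < fdrThreshold
  new("ScanResult", results = res, predictors = predictors,
      traits = names(trait_vals), fdrThreshold = fdrThreshold,
      fdrScope = fdrScope)
}

#' Write a scan result as heatmap-ready TSVs
#'
#' Writes the predictor x trait matrix of aligned z-scores to \code{path},
#' and a long-format companion table (predictor, trait, beta, se, z, p, q,
#' significance flag) to \code{companionPath} when given.
#'
#' @param x a [ScanResult-class].
#' @param path output TSV for the z matrix.
#' @param companionPath optional output TSV for the cell-level table.
#' @return \code{path}, invisibly.
#' @export
writeScanResult <- function(x, path, companionPath = NULL) {
  z <- zMatrix(x)
  utils::write.table(data.frame(predictor = rownames(z), z,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(companionPath))
    utils::write.table(scanTable(x), companionPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
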