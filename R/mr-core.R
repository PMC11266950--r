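#' @include harmonize.R
NULL

#' Odds-ratio scale report for a log-odds estimate
#'
#' @param theta estimate(s) on the log-odds scale.
#' @param se positive standard error(s).
#' @param level confidence level (default 0.95; the normal quantile at 95%
#'   is 1.959964).
#' @return data.frame with columns \code{or}, \code{ci_lower},
#'   \code{ci_upper}, \code{pval}: \code{or = exp(theta)}, CI =
#'   \code{exp(theta +/- z se)}, two-sided normal p.
#' @export
reportOR <- function(theta, se, level = 0.95) {
  if (any(is.na(se) | se <= 0)) stop("se must be positive")
  z <- stats::qnorm((1 + level) / 2)
  data.frame(or = exp(theta), ci_lower = exp(theta - z * se),
             ci_upper = exp(theta + z * se),
             pval = 2 * stats::pnorm(-abs(theta / se)))
}

#' Per-variant Wald ratio causal estimates
#'
#' The Wald ratio estimate of the causal effect from a single instrument is
#' theta = beta_outcome / beta_exposure with first-order delta-method
#' standard error se = se_outcome / |beta_exposure| (the default, which
#' ignores exposure-side uncertainty). The second-order option adds the
#' exposure term:
#' \deqn{se^2 = se_{by}^2 / b_x^2 + b_y^2 se_{bx}^2 / b_x^4.}
#'
#' @param x a [HarmonizedPairs-class] (its retained pairs are used), or a
#'   numeric vector of exposure effects \code{bx}.
#' @param by,seBy outcome effects and their SEs (when \code{x} is numeric).
#' @param seBx exposure-side SEs, needed only for \code{order = 2}.
#' @param rsid optional variant labels.
#' @param order delta-method order, 1 (default) or 2.
#' @param level confidence level for the OR-scale CI.
#' @return data.frame with one row per variant: \code{rsid}, \code{theta},
#'   \code{se}, \code{or}, \code{ci_lower}, \code{ci_upper}, \code{pval}.
#' @examples
#' waldRatio(0.1, by = 0.05, seBy = 0.02)  # theta 0.5, se 0.2
#' @export
waldRatio <- function(x, by = NULL, seBy = NULL, seBx = NULL, rsid = NULL,
                      order = 1, level = 0.95) {
  if (is(x, "HarmonizedPairs")) {
    p <- retainedPairs(x)
    bx <- p$beta_exposure
    by <- p$beta_outcome
    seBy <- p$se_outcome
    if (is.null(seBx)) seBx <- p$se_exposure
    if (is.null(rsid)) rsid <- p$rsid
  } else {
    bx <- as.numeric(x)
  }
  if (any(bx == 0))
    stop("degenerate instrument: exposure effect is zero")
  if (is.null(rsid)) rsid <- paste0("snp", seq_along(bx))
  theta <- by / bx
  se <- seBy / abs(bx)
  if (order == 2) {
    if (is.null(seBx))
      stop("second-order delta method needs exposure-side SEs")
    se <- sqrt(seBy^2 / bx^2 + by^2 * seBx^2 / bx^4)
  } else if (order != 1) stop("order must be 1 or 2")
  cbind(data.frame(rsid = as.character(rsid), theta = theta, se = se,
                   stringsAsFactors = FALSE),
        reportOR(theta, se, level = level))
}

.as_estimates <- function(x) {
  if (is(x, "HarmonizedPairs")) x <- waldRatio(x)
  if (!is.data.frame(x) || !all(c("theta", "se") %in% names(x)))
    stop("estimates must be a data.frame with columns theta and se ",
         "(see waldRatio()) or a HarmonizedPairs")
  if (nrow(x) == 0) stop("empty input: no estimates to pool")
  if (any(is.na(x$se) | x$se <= 0)) stop("all se must be positive")
  if (is.null(x$rsid)) x$rsid <- paste0("snp", seq_len(nrow(x)))
  x
}

#' Inverse-variance weighted pooling of Wald ratio estimates
#'
#' Pools per-variant causal estimates theta_i with weights w_i = 1/se_i^2:
#' \deqn{\hat\theta = \sum w_i \theta_i / \sum w_i, \qquad
#'       se_{fixed} = 1/\sqrt{\sum w_i},}
#' and measures heterogeneity with Cochran's
#' \deqn{Q = \sum w_i (\theta_i - \hat\theta)^2}
#' on k - 1 degrees of freedom. In the default multiplicative random-effects
#' mode the fixed-effect SE is inflated by phi = max(1, sqrt(Q / (k - 1))),
#' so under-dispersion never deflates the SE (phi floors at 1); this matches
#' the behaviour of the standard two-sample MR IVW with multiplicative
#' random effects. An additive DerSimonian-Laird mode
#' (\code{"additive_random"}) is provided but not the default. With a single
#' estimate the Wald estimate is returned as the pooled result and Q is
#' reported absent (NA).
#'
#' Confidence intervals and p-values use the normal reference distribution.
#'
#' @param x per-variant estimates: the data.frame returned by [waldRatio()]
#'   (columns \code{theta}, \code{se}, optionally \code{rsid}) or a
#'   [HarmonizedPairs-class].
#' @param mode \code{"multiplicative_random"} (default), \code{"fixed"}, or
#'   \code{"additive_random"}.
#' @param level confidence level (default 0.95).
#' @return an [IVWResult-class] object.
#' @examples
#' est <- data.frame(theta = c(0.1, 0.3), se = c(0.1, 0.1))
#' oddsRatio(ivw(est))  # exp(0.2)
#' @export
ivw <- function(x, mode = c("multiplicative_random", "fixed",
                            "additive_random"),
                level = 0.95) {
  mode <- match.arg(mode)
  est <- .as_estimates(x)
  k <- nrow(est)
  w <- 1 / est$se^2
  theta_hat <- sum(w * est$theta) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  if (k == 1) {
    Q <- NA_real_; q_df <- NA_real_; q_p <- NA_real_
    phi <- 1
    se_used <- se_fixed
  } else {
    Q <- sum(w * (est$theta - theta_hat)^2)
    q_df <- k - 1
    q_p <- stats::pchisq(Q, df = q_df, lower.tail = FALSE)
    if (mode == "multiplicative_random") {
      phi <- max(1, sqrt(Q / (k - 1)))
      se_used <- se_fixed * phi
    } else if (mode == "fixed") {
      phi <- 1
      se_used <- se_fixed
    } else {
      tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
      w_star <- 1 / (est$se^2 + tau2)
      theta_hat <- sum(w_star * est$theta) / sum(w_star)
      se_used <- sqrt(1 / sum(w_star))
      phi <- se_used / se_fixed
    }
  }
  rep_or <- reportOR(theta_hat, se_used, level = level)
  new("IVWResult", thetaHat = theta_hat, seFixed = se_fixed, phi = phi,
      seUsed = se_used, or = rep_or$or, ciLower = rep_or$ci_lower,
      ciUpper = rep_or$ci_upper, pval = rep_or$pval, Q = Q, qDf = q_df,
      qPval = q_p, k = k, mode = if (k == 1) "wald" else mode,
      level = level, estimates = est)
}

#' Leave-one-out sensitivity analysis
#'
#' Repeats the IVW pooling k times, each time excluding one variant and
#' recomputing the pooled estimate, Cochran's Q and the SE inflation on the
#' remaining k - 1. Influential or pleiotropic variants show up as
#' exclusions that move the pooled estimate.
#'
#' @inheritParams ivw
#' @return data.frame with one row per excluded variant: \code{excluded},
#'   \code{k}, \code{theta}, \code{se}, \code{or}, \code{ci_lower},
#'   \code{ci_upper}, \code{pval}, \code{Q}, \code{phi}. The full
#'   [IVWResult-class] objects are attached as the \code{"details"}
#'   attribute (a named list).
#' @export
leaveOneOut <- function(x, mode = c("multiplicative_random", "fixed",
                                    "additive_random"),
                        level = 0.95) {
  mode <- match.arg(mode)
  est <- .as_estimates(x)
  k <- nrow(est)
  if (k < 2) stop("leave-one-out needs at least 2 estimates")
  details <- lapply(seq_len(k), function(i)
    ivw(est[-i, , drop = FALSE], mode = mode, level = level))
  names(details) <- est$rsid
  out <- data.frame(
    excluded = est$rsid,
    k = k - 1L,
    theta = vapply(details, thetaHat, numeric(1)),
    se = vapply(details, seUsed, numeric(1)),
    or = vapply(details, oddsRatio, numeric(1)),
    ci_lower = vapply(details, function(r) confInt(r)[["lower"]], numeric(1)),
    ci_upper = vapply(details, function(r) confInt(r)[["upper"]], numeric(1)),
    pval = vapply(details, pValue, numeric(1)),
    Q = vapply(details, function(r) cochranQ(r)[["Q"]], numeric(1)),
    phi = vapply(details, function(r) r@phi, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "details") <- details
  out
}

#' Instrument-strength F-statistic
#'
#' Approximate first-stage F-statistic from summary quantities:
#' \deqn{F = \frac{R^2}{1 - R^2} \cdot \frac{n - k - 1}{k},}
#' with R^2 the proportion of exposure variance explained by the k
#' instruments and n a sample size. F is strictly increasing in n and R^2
#' and decreasing in k.
#'
#' Which n to use is a modelling choice exposed to the caller: the textbook
#' convention is the exposure-GWAS sample size, but some published analyses
#' pair the discovery R^2 with each outcome GWAS's sample size instead;
#' both are supported, simply by passing the corresponding \code{n}.
#'
#' @param r2 proportion of variance explained, in (0, 1).
#' @param n sample size, must exceed k + 1.
#' @param k number of instruments, >= 1.
#' @return an [FStat-class] object.
#' @examples
#' fValue(fStatistic(0.0147, 149752, 4))  # 558.5
#' @export
fStatistic <- function(r2, n, k) {
  if (length(r2) != 1 || is.na(r2) || r2 <= 0 || r2 >= 1)
    stop("r2 must lie strictly in (0, 1)")
  if (length(k) != 1 || is.na(k) || k < 1 || k != round(k))
    stop("k must be a positive integer")
  if (length(n) != 1 || is.na(n) || n <= k + 1)
    stop("n must exceed k + 1")
  new("FStat", value = (r2 / (1 - r2)) * ((n - k - 1) / k),
      r2 = r2, n = n, k = k)
}

#' Write / read an MR results table
#'
#' Serialises an IVW result and its per-variant Wald estimates as a TSV
#' mirroring the familiar published layout: one IVW row (with the
#' instrument-strength F-statistic, if supplied) followed by one row per
#' Wald ratio estimate; columns outcome, method, f_statistic, or, ci_lower,
#' ci_upper, pval, plus Q and phi on the IVW row. \code{readMrTable()} reads
#' it back for regression tests.
#'
#' @param result an [IVWResult-class].
#' @param path output file.
#' @param outcome outcome label for the first column.
#' @param fstat optional [FStat-class] for the IVW row.
#' @return \code{path} invisibly (writer); a data.frame (reader).
#' @export
writeMrTable <- function(result, path, outcome = "outcome", fstat = NULL) {
  est <- estimates(result)
  num <- function(z) ifelse(is.na(z), "NA",
                            format(z, digits = 10, trim = TRUE))
  ivw_row <- data.frame(
    outcome = outcome, method = "ivw", rsid = "NA",
    f_statistic = if (is.null(fstat)) "NA" else num(fValue(fstat)),
    or = num(oddsRatio(result)), ci_lower = num(result@ciLower),
    ci_upper = num(result@ciUpper), pval = num(pValue(result)),
    Q = num(result@Q), phi = num(result@phi), stringsAsFactors = FALSE)
  wald_rows <- data.frame(
    outcome = outcome, method = "wald", rsid = est$rsid,
    f_statistic = "NA", or = num(est$or), ci_lower = num(est$ci_lower),
    ci_upper = num(est$ci_upper), pval = num(est$pval), Q = "NA",
    phi = "NA", stringsAsFactors = FALSE)
  utils::write.table(rbind(ivw_row, wald_rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMrTable
#' @export
readMrTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}
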