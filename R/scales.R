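#' @include sumstats.R
NULL

#' Convert linear-scale effect estimates on a binary trait to log odds ratios
#'
#' Large-cohort GWAS of binary traits are often run with linear mixed models
#' (e.g. BOLT-LMM) on the 0/1 phenotype; the resulting effect estimates live
#' on the linear probability scale. For a trait with case fraction
#' mu, the standard approximation divides both the estimate and its standard
#' error by mu(1 - mu):
#' \deqn{\beta' = \beta / (\mu(1-\mu)), \qquad se' = se / (\mu(1-\mu)).}
#' The conversion is linear, and the scaling factor 1/(mu(1-mu)) is smallest
#' (equal to 4) at mu = 0.5.
#'
#' @param beta,se linear-scale effect estimate(s) and standard error(s);
#'   vectors are converted elementwise.
#' @param meta a [StudyMeta-class] with the case/control counts, or a single
#'   numeric case fraction mu in (0, 1).
#' @return list with components \code{beta} and \code{se} on the log-odds
#'   scale.
#' @examples
#' linearToLogOR(0.01, 0.005, 0.5)          # beta 0.04, se 0.02
#' linearToLogOR(0.01, 0.005, studyMeta(11802, 137950))
#' @export
linearToLogOR <- function(beta, se, meta) {
  mu <- if (is(meta, "StudyMeta")) caseFraction(meta) else as.numeric(meta)
  if (length(mu) != 1L || is.na(mu) || mu <= 0 || mu >= 1)
    stop("case fraction must lie strictly in (0, 1)")
  fac <- 1 / (mu * (1 - mu))
  list(beta = beta * fac, se = se * fac)
}

#' Back-derive a log-scale standard error from a printed OR confidence
#' interval
#'
#' Published tables usually print an odds ratio with its confidence
#' interval but not the underlying standard error. Assuming the interval was
#' built as exp(theta +/- z * se), the SE is recovered as
#' \deqn{se = (\log U - \log L) / (2 z),}
#' with z the standard-normal quantile at (1 + level)/2 (1.959964 at 95%).
#' Composing this with CI construction is the identity on se, so printed
#' per-variant ORs and CIs can be used as inputs to [ivw()] with no loss
#' beyond the table's rounding.
#'
#' @param orLower,orUpper positive CI bounds on the OR scale (vectorised).
#' @param level confidence level of the printed interval (default 0.95).
#' @return standard error(s) on the log-odds scale.
#' @examples
#' seFromCI(0.82, 1.37)  # ~ 0.1309
#' @export
seFromCI <- function(orLower, orUpper, level = 0.95) {
  if (any(is.na(orLower) | is.na(orUpper) | orLower <= 0 | orUpper <= 0))
    stop("CI bounds must be positive")
  if (any(orUpper <= orLower))
    stop("degenerate interval: upper bound must exceed lower bound")
  if (level <= 0 || level >= 1) stop("level must lie strictly in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  (log(orUpper) - log(orLower)) / (2 * z)
}
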