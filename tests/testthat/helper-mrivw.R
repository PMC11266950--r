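# shared fixtures and independent oracles

`%||%` <- function(a, b) if (is.null(a)) b else a

make_variants <- function(rsid = c("rs1", "rs2", "rs3", "rs4"),
                          ea = c("A", "C", "G", "T"),
                          oa = c("G", "A", "T", "C"),
                          eaf = c(0.1, 0.2, 0.3, 0.4),
                          beta = c(0.10, 0.08, -0.06, 0.05),
                          se = c(0.01, 0.012, 0.011, 0.013),
                          n = 7049) {
  k <- length(rsid)
  data.frame(rsid = rsid, chrom = as.character(seq_len(k)),
             pos = seq_len(k) * 1000L, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pval = 2 * pnorm(-abs(beta / se)), n = n,
             stringsAsFactors = FALSE)
}

published_wald <- function(outcome) {
  tab <- read.table(publishedFixture("estimates"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE, na.strings = "NA")
  tab[tab$outcome == outcome & tab$method == "wald", , drop = FALSE]
}

published_ivw_row <- function(outcome) {
  tab <- read.table(publishedFixture("estimates"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE, na.strings = "NA")
  tab[tab$outcome == outcome & tab$method == "ivw", , drop = FALSE]
}

# literal Benjamini-Hochberg step-up, independent of p.adjust
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# weighted least squares of theta on a constant via explicit matrix algebra
wls_oracle <- function(theta, se) {
  W <- diag(1 / se^2, nrow = length(se))
  X <- matrix(1, nrow = length(theta), ncol = 1)
  xtwx_inv <- solve(t(X) %*% W %*% X)
  est <- xtwx_inv %*% t(X) %*% W %*% theta
  list(theta = drop(est), se = sqrt(drop(xtwx_inv)))
}
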