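#' Wakefield approximate Bayes factor (log scale)
#'
#' With V = se^2, r = W / (V + W) and z = beta / se, the log approximate
#' Bayes factor for association at one SNP is
#' lABF = 0.5 * log(1 - r) + z^2 * r / 2.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), all positive.
#' @param W prior variance of the true effect; default (0.15)^2 in
#'   phenotype-SD units for quantitative traits (use (0.2)^2 on the log-odds
#'   scale for case-control traits).
#' @return numeric vector of log ABFs.
#' @export
wakefield_labf <- function(beta, se, W = 0.15^2) {
  if (any(se <= 0)) stop("nonpositive standard error")
  r <- W / (se^2 + W)
  z <- beta / se
  0.5 * log(1 - r) + z^2 * r / 2
}

#' Single-causal-variant Bayesian colocalization
#'
#' Enumerates the five hypotheses of the approximate-Bayes-factor coloc
#' model over two aligned summary-stat sets (no causal variant; causal in
#' study 1 only; study 2 only; two distinct causal variants; one shared
#' causal variant) with per-SNP prior p1, p2 and shared prior p12, summing
#' the SNP configurations in log space.
#'
#' @param stats1,stats2 data.frames with columns \code{snp}, \code{beta},
#'   \code{se}, allele-harmonized (see \code{\link{harmonize_alleles}}).
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param W1,W2 Wakefield prior variances for the two studies.
#' @return list of class \code{coloc_result} with pp0..pp4, n_snps and the
#'   priors; posteriors sum to 1 within 1e-9, and pp3 = 0 when only one SNP
#'   is shared.
#' @export
coloc_abf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      W1 = 0.15^2, W2 = 0.15^2) {
  common <- intersect(stats1$snp, stats2$snp)
  if (!length(common)) stop("empty SNP intersection")
  s1 <- stats1[match(common, stats1$snp), ]
  s2 <- stats2[match(common, stats2$snp), ]
  l1 <- wakefield_labf(s1$beta, s1$se, W = W1)
  l2 <- wakefield_labf(s2$beta, s2$se, W = W2)
  lse1 <- logsumexp(l1)
  lse2 <- logsumexp(l2)
  lse12 <- logsumexp(l1 + l2)
  lh <- c(h0 = 0,
          h1 = log(p1) + lse1,
          h2 = log(p2) + lse2,
          h3 = NA_real_,
          h4 = log(p12) + lse12)
  # H3: sum over ordered pairs i != j = (sum_i ABF1_i)(sum_j ABF2_j) - sum_i ABF1_i ABF2_i
  tot <- lse1 + lse2
  if (lse12 >= tot) {
    if (length(common) > 1)
      warning("numerically negative H3 mass clamped at 0")
    lh["h3"] <- -Inf
  } else {
    lh["h3"] <- tot + log1p(-exp(lse12 - tot))
  }
  lh["h3"] <- log(p1) + log(p2) + lh["h3"]
  pp <- exp(lh - logsumexp(lh))
  structure(list(pp0 = pp[["h0"]], pp1 = pp[["h1"]], pp2 = pp[["h2"]],
                 pp3 = pp[["h3"]], pp4 = pp[["h4"]],
                 n_snps = length(common), p1 = p1, p2 = p2, p12 = p12),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "coloc (%d SNPs): PP0=%.3f PP1=%.3f PP2=%.3f PP3=%.3f PP4=%.3f\n",
    x$n_snps, x$pp0, x$pp1, x$pp2, x$pp3, x$pp4))
  invisible(x)
}
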