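#' Summary-based Mendelian randomization at the top instrument
#'
#' Mendelian-randomization effect of exposure on outcome from two summary
#' statistics at one SNP: b_xy = b_zy / b_zx, with the SMR statistic
#' T = z_zx^2 * z_zy^2 / (z_zx^2 + z_zy^2) referred to chi-squared(1) and a
#' delta-method standard error.
#'
#' @param b_zx,se_zx SNP effect and SE on the exposure.
#' @param b_zy,se_zy SNP effect and SE on the outcome.
#' @return list (b_xy, se_xy, T_smr, p).
#' @export
smr_test <- function(b_zx, se_zx, b_zy, se_zy) {
  if (b_zx == 0) stop("b_zx = 0: no instrument")
  stopifnot(se_zx > 0, se_zy > 0)
  z_zx <- b_zx / se_zx
  z_zy <- b_zy / se_zy
  b_xy <- b_zy / b_zx
  T_smr <- if (z_zy == 0) 0 else
    z_zx^2 * z_zy^2 / (z_zx^2 + z_zy^2)
  p <- stats::pchisq(T_smr, df = 1, lower.tail = FALSE)
  se_xy <- if (b_zy == 0) abs(se_zy / b_zx) else
    sqrt(b_xy^2 * (se_zy^2 / b_zy^2 + se_zx^2 / b_zx^2))
  list(b_xy = b_xy, se_xy = se_xy, T_smr = T_smr, p = min(p, 1))
}

#' HEIDI heterogeneity test (heterogeneity in dependent instruments)
#'
#' Tests whether per-SNP Mendelian-randomization estimates across a locus are
#' homogeneous, as expected under a single shared causal variant
#' (causality/pleiotropy), versus heterogeneous as under linkage. Up to
#' \code{max_snps} SNPs with exposure p < \code{p_exp_max} and r-squared with
#' the top SNP inside \code{r2_range} are used; for each,
#' d_i = b_xy(i) - b_xy(top), with the covariance of d obtained from LD and
#' the per-SNP sampling variances by the delta method. The statistic
#' sum (d_i / sd(d_i))^2 is referred to a Satterthwaite two-moment
#' approximation of the correlated chi-squared sum (eigenvalues of the
#' correlation matrix of d).
#'
#' @param exposure,outcome aligned summary-stat data.frames (snp, beta, se, p
#'   for the exposure).
#' @param R signed LD correlation matrix over the union of SNPs (dimnames =
#'   SNP ids).
#' @param top_snp id of the top exposure SNP (the SMR instrument).
#' @param p_exp_max exposure p-value eligibility bound (default 1.57e-3).
#' @param r2_range admissible r-squared with the top SNP (default
#'   [0.05, 0.9]).
#' @param max_snps maximum number of SNPs beside the top SNP (default 20).
#' @return list (p_heidi, n_snps, reason); p_heidi is NA with a reason code
#'   when fewer than 3 eligible SNPs remain.
#' @export
heidi_test <- function(exposure, outcome, R, top_snp,
                       p_exp_max = 1.57e-3, r2_range = c(0.05, 0.9),
                       max_snps = 20) {
  stopifnot(top_snp %in% exposure$snp, top_snp %in% colnames(R))
  common <- intersect(exposure$snp, outcome$snp)
  e <- exposure[match(common, exposure$snp), ]
  o <- outcome[match(common, outcome$snp), ]
  if (!"p" %in% names(e)) e$p <- 2 * stats::pnorm(-abs(e$beta / e$se))
  r_top <- R[common, top_snp]
  elig <- which(common != top_snp &
                  e$p < p_exp_max &
                  r_top^2 >= r2_range[1] & r_top^2 <= r2_range[2])
  if (length(elig) < 3)
    return(list(p_heidi = NA_real_, n_snps = length(elig),
                reason = "fewer than 3 eligible SNPs"))
  if (length(elig) > max_snps)
    elig <- elig[order(e$p[elig])][seq_len(max_snps)]
  sel <- c(match(top_snp, common), elig)
  bx <- e$beta[sel]; sx <- e$se[sel]
  by <- o$beta[sel]; sy <- o$se[sel]
  Rs <- R[common[sel], common[sel]]
  b_xy <- by / bx
  m <- length(sel)
  # delta-method covariance of the per-SNP b_xy vector; exposure and outcome
  # samples are independent, so the two pieces add
  C <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in i:m) {
    v <- Rs[i, j] * sy[i] * sy[j] / (bx[i] * bx[j]) +
      b_xy[i] * b_xy[j] * Rs[i, j] * sx[i] * sx[j] / (bx[i] * bx[j])
    C[i, j] <- C[j, i] <- v
  }
  # d = b_xy(i) - b_xy(top), i > 1
  A <- cbind(-1, diag(m - 1))
  Vd <- A %*% C %*% t(A)
  d <- b_xy[-1] - b_xy[1]
  sd_d <- sqrt(diag(Vd))
  if (any(sd_d <= 0)) {
    ok <- sd_d > 0
    if (sum(ok) < 3)
      return(list(p_heidi = NA_real_, n_snps = sum(ok),
                  reason = "degenerate d variances"))
    d <- d[ok]; Vd <- Vd[ok, ok, drop = FALSE]; sd_d <- sd_d[ok]
  }
  stat <- sum((d / sd_d)^2)
  corr_d <- Vd / tcrossprod(sd_d)
  lam <- eigen(corr_d, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  s1 <- sum(lam); s2 <- sum(lam^2)
  if (s2 == 0) return(list(p_heidi = 1, n_snps = length(d), reason = NA))
  a <- s2 / s1
  nu <- s1^2 / s2
  p <- stats::pchisq(stat / a, df = nu, lower.tail = FALSE)
  list(p_heidi = min(max(p, .Machine$double.xmin), 1), n_snps = length(d),
       reason = NA_character_)
}

#' SMR and HEIDI for two molecular traits (mediation analysis)
#'
#' Runs \code{\link{smr_test}} at the exposure's top SNP and
#' \code{\link{heidi_test}} over the locus, with a mediation verdict: SMR
#' p < 0.05 and HEIDI p >= 0.05.
#'
#' @param exposure,outcome summary-stat data.frames (snp, beta, se, p),
#'   allele-harmonized.
#' @param R signed LD correlation matrix over the locus SNPs.
#' @param top_snp instrument SNP; default the exposure's smallest p.
#' @param instrument_p_max maximum exposure p for the instrument (default
#'   5e-8; relax to the study's cis-significance threshold as appropriate).
#' @param smr_alpha,heidi_alpha decision thresholds for the mediation verdict.
#' @return list of class \code{smr_result}: exposure/outcome fields, b_xy,
#'   se_xy, T_smr, p_smr, p_heidi, n_snps_heidi, mediation (logical).
#' @export
smr_two_molecular <- function(exposure, outcome, R, top_snp = NULL,
                              instrument_p_max = 5e-8,
                              smr_alpha = 0.05, heidi_alpha = 0.05) {
  if (!"p" %in% names(exposure))
    exposure$p <- 2 * stats::pnorm(-abs(exposure$beta / exposure$se))
  if (is.null(top_snp)) top_snp <- exposure$snp[which.min(exposure$p)]
  ei <- match(top_snp, exposure$snp)
  oi <- match(top_snp, outcome$snp)
  if (is.na(oi)) stop("top SNP absent from outcome stats")
  if (exposure$p[ei] > instrument_p_max)
    warning("instrument p = ", signif(exposure$p[ei], 3),
            " exceeds instrument_p_max")
  smr <- smr_test(exposure$beta[ei], exposure$se[ei],
                  outcome$beta[oi], outcome$se[oi])
  hd <- heidi_test(exposure, outcome, R, top_snp)
  mediation <- !is.na(smr$p) && smr$p < smr_alpha &&
    !is.na(hd$p_heidi) && hd$p_heidi >= heidi_alpha
  structure(list(top_snp = top_snp, b_xy = smr$b_xy, se_xy = smr$se_xy,
                 T_smr = smr$T_smr, p_smr = smr$p,
                 p_heidi = hd$p_heidi, n_snps_heidi = hd$n_snps,
                 heidi_reason = hd$reason, mediation = mediation),
            class = "smr_result")
}

#' @export
print.smr_result <- function(x, ...) {
  cat(sprintf(
    "SMR at %s: b_xy=%.3f (se %.3f), p_smr=%.3g, p_heidi=%s, mediation=%s\n",
    x$top_snp, x$b_xy, x$se_xy, x$p_smr,
    ifelse(is.na(x$p_heidi), "NA", sprintf("%.3g", x$p_heidi)),
    x$mediation))
  invisible(x)
}
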