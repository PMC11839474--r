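# Independent oracles used across tests. These deliberately re-derive
# quantities from first principles (plain loops, textbook formulas) so the
# vectorized package implementations are checked against a second route.

# TMM scale factors from the published definition: trimmed mean of M-values
# with 30% M-trim and 5% A-trim against a reference sample, weighted by
# inverse asymptotic variances.
oracle_tmm_factors <- function(counts, lib = colSums(counts)) {
  # reference = sample whose 75th count-fraction percentile is closest to
  # the mean; factors centered to a unit geometric mean
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    quantile(counts[, j], 0.75) / lib[j], numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    if (j == ref) 1 else
      oracle_tmm_factor(counts[, j], counts[, ref], lib[j], lib[ref]),
    numeric(1))
  f / exp(mean(log(f)))
}

oracle_tmm_factor <- function(obs, ref, lib_obs, lib_ref,
                              logratio_trim = 0.3, sum_trim = 0.05,
                              weighted = FALSE) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / lib_obs) / (ref / lib_ref))
  A <- 0.5 * (log2(obs / lib_obs) + log2(ref / lib_ref))
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (weighted) 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  else 2^mean(M[keep])
}

# Brute-force coloc posterior enumeration: every causal configuration listed
# explicitly in plain (non-log) arithmetic.
oracle_coloc <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  b1 <- exp(labf1); b2 <- exp(labf2)
  m <- length(b1)
  s0 <- 1
  s1 <- sum(p1 * b1)
  s2 <- sum(p2 * b2)
  s3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    s3 <- s3 + p1 * p2 * b1[i] * b2[j]
  s4 <- sum(p12 * b1 * b2)
  s <- c(s0, s1, s2, s3, s4)
  s / sum(s)
}

# OLS by explicit normal equations.
oracle_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(sigma2 * solve(XtX)))
  tt <- beta / se
  list(beta = as.vector(beta), se = as.vector(se), t = as.vector(tt),
       p = as.vector(2 * pt(-abs(tt), df = df)))
}

# Small complete study used by several integration tests: genotypes, counts
# with one planted cis effect, covariates, windows.
make_study <- function(seed, n = 604, n_snps = 60, var_frac = 0.04,
                       n_features = 30, causal_idx = 25,
                       mediation = NULL, within_block_r = 0.8) {
  panel <- simulate_genotypes(n, n_snps, block_size = 10,
                              within_block_r = within_block_r, seed = seed)
  truth <- sim_truth(
    data.frame(feature = "mir-1", snp = panel$snps$snp[causal_idx],
               var_frac = var_frac),
    mediation_map = mediation, seed = seed)
  sim <- simulate_mirna_counts(panel, truth, n_features = n_features,
                               seed = mirqtl:::derive_seed(seed, 1))
  em <- normalize_log2(sim$expr)
  # batch + the hidden-factor scores (the stand-in for estimated SVs in the
  # full pipeline)
  covars <- cbind(stats::model.matrix(~ batch, sim$covariates), sim$factors)
  colnames(covars)[ncol(covars) - 2:0] <- paste0("F", 1:3)
  rownames(covars) <- sim$covariates$sample
  windows <- build_cis_windows(
    data.frame(mature_id = rownames(em$values),
               precursor_id = rownames(em$values),
               chrom = "1", start = 170000L, end = 170100L, strand = "+",
               stringsAsFactors = FALSE))
  list(panel = panel, truth = sim$truth, expr = em, covars = covars,
       windows = windows, raw = sim$expr)
}
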