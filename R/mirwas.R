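#' Cis SNP-based heritability by single-component REML
#'
#' Fits y ~ N(mu, sigma_g^2 K + sigma_e^2 I) where K is the genomic
#' relationship matrix of the standardized cis dosages, by restricted maximum
#' likelihood on the eigenrotated (centered) data, and tests h2 = 0 by a
#' likelihood-ratio test against the boundary null, p = 0.5 * P(chisq(1) >
#' LRT) (the 0.5*chi2(0) + 0.5*chi2(1) mixture).
#'
#' @param dosage samples x SNPs cis dosage matrix (>= 2 SNPs).
#' @param y expression vector (residualized for covariates).
#' @return list (h2, sigma_g2, sigma_e2, p, converged).
#' @export
estimate_cis_h2 <- function(dosage, y) {
  stopifnot(ncol(dosage) >= 2, nrow(dosage) == length(y),
            length(y) >= 100)
  G <- scale(dosage)
  G <- G[, apply(dosage, 2, stats::var) > 0, drop = FALSE]
  K <- tcrossprod(G) / ncol(G)
  n <- length(y)
  yc <- y - mean(y)
  M <- diag(n) - 1 / n
  eg <- eigen(M %*% K %*% M, symmetric = TRUE)
  # one df absorbed by the mean; keep the n-1 rotated contrasts
  keep <- seq_len(n - 1)
  lam <- eg$values[keep]
  ys <- as.vector(crossprod(eg$vectors[, keep], yc))
  reml_ll <- function(h2) {
    v <- h2 * lam + (1 - h2)
    if (any(v <= 0)) return(-Inf)
    sp2 <- mean(ys^2 / v)
    -0.5 * (sum(log(v)) + (n - 1) * log(sp2) + (n - 1))
  }
  opt <- stats::optimize(reml_ll, c(0, 1 - 1e-6), maximum = TRUE)
  h2 <- opt$maximum
  ll1 <- opt$objective
  ll0 <- reml_ll(0)
  lrt <- max(0, 2 * (ll1 - ll0))
  p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  converged <- is.finite(ll1)
  if (lrt < 1e-8) h2 <- 0  # boundary estimate
  v <- h2 * lam + (1 - h2)
  sp2 <- mean(ys^2 / v)
  list(h2 = h2, sigma_g2 = h2 * sp2, sigma_e2 = (1 - h2) * sp2,
       p = min(p, 1), converged = converged)
}

#' Fit cis expression weight models and pick the most predictive
#'
#' Candidate models: \code{top1} (all-zero weights except the most
#' significant cis SNP, weighted by its marginal beta), \code{lasso} and
#' \code{enet} (elastic net, mixing 0.5), the latter two with the penalty
#' chosen by cross-validation. The model with the highest out-of-fold
#' R-squared is selected; ties go to top1. If no model achieves a positive
#' cv R-squared the miRNA is excluded (model "none").
#'
#' @param dosage samples x SNPs cis dosage matrix.
#' @param y expression vector (residualized).
#' @param folds number of cross-validation folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param h2,h2_p optional heritability estimate/p to record (the h2 gate
#'   p < 0.01 is applied by the caller; see \code{\link{estimate_cis_h2}}).
#' @return list of class \code{twas_model}: model label, weights (named by
#'   SNP), cv_r2 per candidate, h2, h2_p.
#' @export
fit_weight_models <- function(dosage, y, folds = 5, seed = 1L,
                              h2 = NA_real_, h2_p = NA_real_) {
  n <- length(y)
  stopifnot(nrow(dosage) == n)
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(folds), n))
    oof <- function(fit_fun) {
      pred <- numeric(n)
      for (f in seq_len(folds)) {
        tr <- foldid != f
        pred[!tr] <- fit_fun(dosage[tr, , drop = FALSE], y[tr],
                             dosage[!tr, , drop = FALSE])
      }
      1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    }
    top1_fit <- function(Xtr, ytr, Xte) {
      b <- marginal_betas(Xtr, ytr)
      j <- which.max(abs(b$t))
      Xte[, j] * b$beta[j] + mean(ytr) - mean(Xtr[, j]) * b$beta[j]
    }
    glmnet_fit <- function(alpha) function(Xtr, ytr, Xte) {
      cv <- glmnet::cv.glmnet(Xtr, ytr, alpha = alpha, nfolds = 5)
      as.vector(stats::predict(cv, Xte, s = "lambda.min"))
    }
    cv_r2 <- c(top1 = oof(top1_fit),
               lasso = oof(glmnet_fit(1)),
               enet = oof(glmnet_fit(0.5)))
    if (all(cv_r2 <= 0)) {
      return(structure(list(model = "none", weights = NULL, cv_r2 = cv_r2,
                            h2 = h2, h2_p = h2_p), class = "twas_model"))
    }
    best <- names(cv_r2)[order(-cv_r2, c(1, 2, 3))][1]  # ties -> top1
    w <- stats::setNames(numeric(ncol(dosage)), colnames(dosage))
    if (best == "top1") {
      b <- marginal_betas(dosage, y)
      j <- which.max(abs(b$t))
      w[j] <- b$beta[j]
    } else {
      cv <- glmnet::cv.glmnet(dosage, y, alpha = ifelse(best == "lasso",
                                                        1, 0.5), nfolds = 5)
      co <- as.vector(stats::coef(cv, s = "lambda.min"))[-1]
      w[] <- co
    }
    structure(list(model = best, weights = w, cv_r2 = cv_r2,
                   h2 = h2, h2_p = h2_p), class = "twas_model")
  })
}

marginal_betas <- function(X, y) {
  xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  beta <- as.vector(crossprod(xc, yc)) / pmax(sxx, .Machine$double.eps)
  n <- length(y)
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / (n - 2) / pmax(sxx, .Machine$double.eps))
  list(beta = beta, t = ifelse(se > 0, beta / se, 0))
}

#' TWAS-style weighted-z association of a model with a GWAS
#'
#' z = w' z_gwas / sqrt(w' R w) with R the LD correlation matrix on the model
#' SNPs; two-sided normal p. A numerically nonpositive denominator is
#' ridge-regularized (+1e-3 on the diagonal) with a warning.
#'
#' @param model a \code{twas_model} (or a named weight vector).
#' @param gwas summary-stat data.frame with snp and z, allele-harmonized to
#'   the weights.
#' @param R signed LD correlation matrix over the model SNPs.
#' @return list (z, p).
#' @export
twas_associate <- function(model, gwas, R) {
  w <- if (inherits(model, "twas_model")) model$weights else model
  if (is.null(w)) stop("model has no weights (excluded miRNA)")
  snps <- names(w)[w != 0]
  if (!length(snps)) stop("all-zero weight vector")
  z <- gwas$z[match(snps, gwas$snp)]
  if (anyNA(z)) stop("GWAS z missing for model SNP(s)")
  ww <- w[snps]
  Rs <- R[snps, snps, drop = FALSE]
  denom <- as.numeric(t(ww) %*% Rs %*% ww)
  if (denom <= 0) {
    warning("nonpositive w'Rw; ridge-regularizing the LD matrix")
    denom <- as.numeric(t(ww) %*% (Rs + diag(1e-3, length(ww))) %*% ww)
  }
  zt <- sum(ww * z) / sqrt(denom)
  list(z = zt, p = 2 * stats::pnorm(-abs(zt)))
}

#' Four-criteria causal-miRNA screen
#'
#' Flags a (miRNA, trait) pair as consistent with a causal role when all of:
#' miRWAS FDR < 0.05; coloc PP.H4 > 0.5 (strict); SMR p < 0.05; and HEIDI
#' p >= 0.05. A missing component fails the flag with a reason code.
#'
#' @param mirwas data.frame (mirna, trait, z, p, fdr).
#' @param coloc data.frame (mirna, trait, pp4).
#' @param smr data.frame (mirna, trait, p_smr, p_heidi).
#' @return data.frame keyed by (mirna, trait) with the four component values,
#'   \code{causal} flag and \code{reason}.
#' @export
causal_screen <- function(mirwas, coloc, smr) {
  key <- function(d) paste(d$mirna, d$trait, sep = "\r")
  out <- mirwas[, c("mirna", "trait", "z", "p", "fdr")]
  out$pp4 <- coloc$pp4[match(key(out), key(coloc))]
  i <- match(key(out), key(smr))
  out$p_smr <- smr$p_smr[i]
  out$p_heidi <- smr$p_heidi[i]
  crit <- cbind(fdr = !is.na(out$fdr) & out$fdr < 0.05,
                pp4 = !is.na(out$pp4) & out$pp4 > 0.5,
                smr = !is.na(out$p_smr) & out$p_smr < 0.05,
                heidi = !is.na(out$p_heidi) & out$p_heidi >= 0.05)
  out$causal <- rowSums(crit) == 4L
  out$reason <- apply(crit, 1, function(r)
    if (all(r)) NA_character_ else
      paste("fails:", paste(colnames(crit)[!r], collapse = ",")))
  out
}
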