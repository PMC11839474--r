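#' Pairwise LD as squared dosage correlation
#'
#' Composite LD: the squared Pearson correlation of the two SNPs' dosage
#' vectors (no phasing required).
#'
#' @param panel a \code{\link{variant_panel}}.
#' @param snp_i,snp_j SNP ids.
#' @return r-squared in [0, 1]; NA for a monomorphic SNP.
#' @export
ld_r2 <- function(panel, snp_i, snp_j) {
  x <- panel$dosage[, snp_i]
  y <- panel$dosage[, snp_j]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Dosage correlation matrix over a SNP set
#' @param panel a \code{\link{variant_panel}}.
#' @param snps SNP ids (default all).
#' @return correlation matrix (signed r, not r-squared).
#' @export
ld_matrix <- function(panel, snps = NULL) {
  d <- if (is.null(snps)) panel$dosage else panel$dosage[, snps, drop = FALSE]
  stats::cor(d)
}

#' Greedy LD clumping of significant miR-QTLs
#'
#' Repeatedly takes the remaining SNP with the smallest p-value as index and
#' absorbs remaining SNPs with r-squared >= \code{r2_max} AND distance <=
#' \code{radius_kb} of the index. Ties on p are broken by smaller genomic
#' position.
#'
#' @param records QTL records for one miRNA (columns snp, pos, p), already
#'   restricted to the significant set.
#' @param panel a \code{\link{variant_panel}} containing the records' SNPs.
#' @param r2_max clump r-squared bound (default 0.5).
#' @param radius_kb clump radius in kb (default 250).
#' @return list of clumps, each with \code{index}, \code{members} (character,
#'   excluding the index) and per-member \code{r2} and \code{distance_bp}.
#' @export
clump <- function(records, panel, r2_max = 0.5, radius_kb = 250) {
  if (!nrow(records)) return(list())
  stopifnot(all(c("snp", "pos", "p") %in% names(records)))
  R <- ld_matrix(panel, records$snp)
  remaining <- seq_len(nrow(records))
  out <- list()
  while (length(remaining)) {
    pr <- records$p[remaining]
    best <- remaining[order(pr, records$pos[remaining])][1]
    r2 <- R[match(records$snp[best], rownames(R)),
            match(records$snp[remaining], colnames(R))]^2
    dist <- abs(records$pos[remaining] - records$pos[best])
    absorb <- remaining[r2 >= r2_max & dist <= radius_kb * 1000 &
                          remaining != best]
    keep_r2 <- r2[match(absorb, remaining)]
    keep_d <- dist[match(absorb, remaining)]
    out[[length(out) + 1L]] <- list(
      index = records$snp[best],
      members = records$snp[absorb],
      r2 = unname(keep_r2), distance_bp = unname(keep_d))
    remaining <- setdiff(remaining, c(best, absorb))
  }
  out
}

#' Stepwise conditional analysis over index miR-QTLs
#'
#' Starting from the index SNP with the lowest marginal p-value, refits each
#' remaining index SNP with the current independent set as extra covariates.
#' If more than one remains significant at \code{threshold}, the best-ranked
#' one joins the set and the round repeats; if exactly one remains, it joins
#' and the procedure stops; if none, the procedure stops.
#'
#' @param y expression vector for the miRNA (normalized log2-CPM).
#' @param panel a \code{\link{variant_panel}} (samples aligned with y).
#' @param covariates samples x k model matrix.
#' @param index_snps data.frame (snp, p) of index miR-QTLs, any order.
#' @param threshold conditional significance threshold on p; by default the
#'   caller passes the study's cis-significance threshold.
#' @return character vector of conditionally independent SNP ids, in
#'   selection order.
#' @export
conditional_scan <- function(y, panel, covariates, index_snps, threshold) {
  stopifnot(nrow(index_snps) >= 1)
  ord <- order(index_snps$p)
  snps <- index_snps$snp[ord]
  indep <- snps[1]
  remaining <- setdiff(snps, indep)
  X0 <- cbind(1, as.matrix(covariates))
  while (length(remaining)) {
    pv <- vapply(remaining, function(s) {
      X <- cbind(X0, panel$dosage[, indep, drop = FALSE])
      if (qr(cbind(X, panel$dosage[, s]))$rank <= qr(X)$rank) {
        warning("SNP ", s, " collinear with the independent set; skipped")
        return(NA_real_)
      }
      cond_p(y, panel$dosage[, s], X)
    }, numeric(1))
    sig <- which(!is.na(pv) & pv < threshold)
    if (length(sig) == 0) break
    add <- remaining[sig[1]]  # remaining is ordered by marginal rank
    indep <- c(indep, add)
    remaining <- setdiff(remaining, add)
    if (length(sig) == 1) break
  }
  indep
}

# p-value of a dosage coefficient given a covariate matrix (with intercept)
cond_p <- function(y, dosage, X) {
  qr_x <- qr(X)
  yr <- qr.resid(qr_x, y)
  xr <- qr.resid(qr_x, dosage)
  sxx <- sum(xr^2)
  if (sxx <= 0) return(NA_real_)
  beta <- sum(xr * yr) / sxx
  df <- length(y) - qr_x$rank - 1L
  rss <- sum(yr^2) - beta * sum(xr * yr)
  se <- sqrt(max(rss, 0) / df / sxx)
  if (se == 0) return(0)
  2 * stats::pt(-abs(beta / se), df = df)
}
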