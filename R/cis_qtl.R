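#' Build cis test windows around miRNA precursors
#'
#' Per mature miRNA, the union of its precursor intervals padded
#' symmetrically by \code{pad} bases, merged so a SNP falling in the padding
#' of multiple precursors is tested only once. Windows are clamped at
#' position 1. Precursors without coordinates exclude the miRNA (logged in
#' the \code{excluded} attribute).
#'
#' @param annotation a miRNA coordinate table
#'   (\code{\link{read_mirna_annotation}} schema).
#' @param pad padding in bases (default 500 kb).
#' @return data.frame (mature_id, chrom, start, end), possibly several merged
#'   regions per miRNA, with excluded mature ids in
#'   \code{attr(, "excluded")}.
#' @export
build_cis_windows <- function(annotation, pad = 500000L) {
  stopifnot(all(c("mature_id", "precursor_id", "chrom", "start", "end") %in%
                  names(annotation)))
  ok <- !(is.na(annotation$chrom) | is.na(annotation$start) |
            is.na(annotation$end))
  excluded <- setdiff(annotation$mature_id, annotation$mature_id[ok])
  ann <- annotation[ok, , drop = FALSE]
  out <- do.call(rbind, lapply(split(ann, ann$mature_id), function(d) {
    do.call(rbind, lapply(split(d, d$chrom), function(dc) {
      r <- IRanges::reduce(IRanges::IRanges(pmax(1L, dc$start - pad),
                                            dc$end + pad))
      data.frame(mature_id = dc$mature_id[1], chrom = dc$chrom[1],
                 start = IRanges::start(r), end = IRanges::end(r),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Additive linear-model cis-QTL scan
#'
#' For every (SNP, miRNA) pair whose SNP falls in the miRNA's cis window,
#' fits normalized expression ~ dosage + covariates by OLS and tests the
#' dosage coefficient with a two-sided t test on n - p degrees of freedom.
#' Computation residualizes both expression and dosage on the covariates
#' (Frisch-Waugh), which reproduces the full-model coefficient, standard
#' error and t exactly. All tested pairs are returned with Storey q-values
#' computed from the full set of p-values.
#'
#' @param panel a QC'd \code{\link{variant_panel}}.
#' @param em an \code{\link{expression_matrix}} tagged log2cpm, rows keyed by
#'   mature miRNA id.
#' @param covariates samples x k numeric model matrix (an intercept is added
#'   if absent); pruned with \code{\link{vif_prune}}.
#' @param windows cis windows from \code{\link{build_cis_windows}}.
#' @param vif_max VIF bound passed to the covariate pruning (default 500).
#' @return data.frame of QTL records (mirna, snp, chrom, pos, a1, a2, beta,
#'   se, t, p, q, n) with the Storey pi0 estimate in \code{attr(, "pi0")} and
#'   the monomorphic-SNP skip count in \code{attr(, "n_monomorphic")}.
#' @export
scan_cis <- function(panel, em, covariates, windows, vif_max = 500) {
  stopifnot(inherits(panel, "variant_panel"),
            inherits(em, "expression_matrix"), em$tag == "log2cpm")
  samples <- intersect(colnames(em$values), rownames(panel$dosage))
  if (length(samples) < 10) stop("fewer than 10 shared samples")
  Y <- em$values[, samples, drop = FALSE]
  D <- panel$dosage[samples, , drop = FALSE]
  X <- as.matrix(covariates)
  if (!is.null(rownames(X)) && all(samples %in% rownames(X)))
    X <- X[samples, , drop = FALSE]
  else if (nrow(X) != length(samples))
    stop("covariate rows must match or be keyed by sample id")
  if (!any(apply(X, 2, function(v) all(v == v[1]))))
    X <- cbind(`(Intercept)` = 1, X)
  X <- vif_prune(X, vif_max = vif_max)
  n <- length(samples)
  p_cov <- ncol(X)
  df <- n - p_cov - 1L
  qr_x <- qr(X)
  Yr <- t(qr.resid(qr_x, t(Y)))
  mono <- apply(D, 2, stats::var) == 0
  Dr <- qr.resid(qr_x, D)
  recs <- vector("list", nrow(Y))
  n_mono <- 0L
  for (i in seq_len(nrow(Y))) {
    mir <- rownames(Y)[i]
    w <- windows[windows$mature_id == mir, , drop = FALSE]
    if (!nrow(w)) next
    in_win <- rep(FALSE, nrow(panel$snps))
    for (k in seq_len(nrow(w)))
      in_win <- in_win | (panel$snps$chrom == w$chrom[k] &
                            panel$snps$pos >= w$start[k] &
                            panel$snps$pos <= w$end[k])
    idx <- which(in_win & !mono)
    n_mono <- n_mono + sum(in_win & mono)
    if (!length(idx)) next
    y <- Yr[i, ]
    xr <- Dr[, idx, drop = FALSE]
    sxx <- colSums(xr^2)
    if (sum(y^2) <= 1e-12 * n) {  # expression constant given covariates
      beta <- rep(0, length(idx)); se <- rep(0, length(idx))
      tt <- rep(0, length(idx)); pv <- rep(1, length(idx))
    } else {
      sxy <- as.vector(crossprod(xr, y))
      beta <- sxy / sxx
      rss <- sum(y^2) - beta * sxy
      sigma2 <- pmax(rss, 0) / df
      se <- sqrt(sigma2 / sxx)
      tt <- ifelse(se > 0, beta / se, 0)
      pv <- 2 * stats::pt(-abs(tt), df = df)
    }
    recs[[i]] <- data.frame(
      mirna = mir, snp = panel$snps$snp[idx],
      chrom = panel$snps$chrom[idx], pos = panel$snps$pos[idx],
      a1 = panel$snps$alt[idx], a2 = panel$snps$ref[idx],
      beta = beta, se = se, t = tt, p = pmin(pmax(pv, .Machine$double.xmin), 1),
      n = n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) stop("no testable SNP-miRNA pairs")
  rownames(out) <- NULL
  qv <- storey_qvalues(out$p)
  out$q <- qv$q
  attr(out, "pi0") <- qv$pi0
  attr(out, "n_monomorphic") <- n_mono
  out
}

#' Storey q-values with smoother-based pi0 estimation
#'
#' pi0 is estimated on the lambda grid 0.05, 0.10, ..., 0.95 with a natural
#' cubic smoothing spline (df = 3) evaluated at the largest lambda, clipped
#' to (0, 1]; q-values follow the step-up rule
#' q_i = min over j with p_(j) >= p_(i) of pi0 * m * p_(j) / j. With fewer
#' than 100 p-values, pi0 falls back to 1 (plain Benjamini-Hochberg) with a
#' warning.
#'
#' @param p vector of p-values in (0, 1].
#' @return list with \code{q} (same order as \code{p}) and \code{pi0}.
#' @export
storey_qvalues <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  m <- length(p)
  if (m < 100) {
    if (m > 1) warning("fewer than 100 p-values; using pi0 = 1")
    pi0 <- 1
  } else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / (m:1)))[ro]
  list(q = q, pi0 = pi0)
}

#' Fraction of expression variance explained by one SNP
#'
#' Fits the (pre-residualized) expression on SNP dosage plus genetic PCs and
#' reports Var(beta * dosage) / Var(outcome).
#'
#' @param y residualized expression vector (non-genetic covariates and SVs
#'   already removed).
#' @param dosage SNP dosage vector.
#' @param pcs optional samples x k matrix of genetic PCs.
#' @return variance fraction in [0, 1]; 0 when the outcome has no variance.
#' @export
variance_explained <- function(y, dosage, pcs = NULL) {
  vy <- stats::var(y)
  if (vy == 0) return(0)
  X <- cbind(1, dosage, pcs)
  beta <- qr.coef(qr(X), y)[2]
  if (is.na(beta)) return(0)
  min(1, stats::var(beta * dosage) / vy)
}
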