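#' Filter lowly expressed miRNAs
#'
#' Keeps features observed at >= \code{min_rpm} reads per million in at least
#' \code{min_frac} of samples (both thresholds inclusive). RPM is computed
#' against the stored library sizes (total mapped reads), falling back to
#' column sums.
#'
#' @param em an \code{\link{expression_matrix}} of raw counts.
#' @param min_rpm RPM threshold (default 1).
#' @param min_frac minimum fraction of samples at or above the threshold
#'   (default 0.5).
#' @return the filtered \code{expression_matrix}.
#' @export
filter_low_expression <- function(em, min_rpm = 1, min_frac = 0.5) {
  stopifnot(inherits(em, "expression_matrix"), em$tag == "counts")
  lib <- if (!is.null(em$lib_sizes)) em$lib_sizes else colSums(em$values)
  if (any(lib <= 0)) stop("zero library size")
  rpm <- sweep(em$values, 2, lib / 1e6, "/")
  keep <- rowMeans(rpm >= min_rpm) >= min_frac
  subset_features(em, keep)
}

subset_features <- function(em, keep) {
  expression_matrix(em$values[keep, , drop = FALSE], tag = em$tag,
                    lib_sizes = em$lib_sizes,
                    features = if (!is.null(em$features))
                      em$features[keep, , drop = FALSE])
}

#' Deduplicate miRNAs quantified from multiple precursors
#'
#' When one mature miRNA id appears on several precursors, keeps the entry
#' with the highest total count across samples; ties are broken by the
#' lexicographically smallest precursor id (with a warning).
#'
#' @param em an \code{\link{expression_matrix}} whose \code{features} table
#'   has \code{mature_id} and \code{precursor_id} columns.
#' @return an \code{expression_matrix} with one row per mature id.
#' @export
dedup_multi_precursor <- function(em) {
  stopifnot(inherits(em, "expression_matrix"), !is.null(em$features),
            all(c("mature_id", "precursor_id") %in% names(em$features)))
  tot <- rowSums(em$values)
  keep <- logical(nrow(em$values))
  tied <- character(0)
  for (m in unique(em$features$mature_id)) {
    rows <- which(em$features$mature_id == m)
    best <- rows[tot[rows] == max(tot[rows])]
    if (length(best) > 1) {
      tied <- c(tied, m)
      best <- best[order(em$features$precursor_id[best])][1]
    }
    keep[best] <- TRUE
  }
  if (length(tied))
    warning("total-count tie broken by precursor id for: ",
            paste(tied, collapse = ", "))
  out <- subset_features(em, keep)
  rownames(out$values) <- out$features$mature_id
  out
}

#' TMM-normalized log2 counts per million
#'
#' Library-size normalization by edgeR's trimmed mean of M-values followed by
#' the log2-CPM transform with a prior count of 0.5. The trimmed mean is
#' unweighted by default so normalized values are exactly invariant to a
#' uniform rescaling of one sample's counts; set \code{weighted = TRUE} for
#' edgeR's precision-weighted variant.
#'
#' @param em an \code{\link{expression_matrix}} of raw counts.
#' @param prior_count prior count added before the log transform.
#' @param weighted use precision weights in the trimmed mean (default FALSE).
#' @return an \code{expression_matrix} tagged \code{"log2cpm"}; the TMM scale
#'   factors are attached as attribute \code{"norm_factors"}.
#' @export
normalize_log2 <- function(em, prior_count = 0.5, weighted = FALSE) {
  stopifnot(inherits(em, "expression_matrix"), em$tag == "counts")
  if (any(colSums(em$values) == 0)) stop("all-zero sample")
  # library size = total mapped reads where known, not the analyzed subset's
  # column sum
  dge <- edgeR::DGEList(counts = em$values)
  if (!is.null(em$lib_sizes)) dge$samples$lib.size <- em$lib_sizes
  dge <- edgeR::calcNormFactors(dge, method = "TMM",
                                doWeighting = weighted)
  lg <- edgeR::cpm(dge, log = TRUE, prior.count = prior_count)
  out <- expression_matrix(lg, tag = "log2cpm", lib_sizes = em$lib_sizes,
                           features = em$features)
  attr(out, "norm_factors") <- dge$samples$norm.factors
  out
}

#' Remove outlier samples by batch-wise metrics or expression PCA
#'
#' \code{batch_metric} mode iteratively drops samples farther than
#' \code{sd_limit} (default 5) standard deviations from the within-batch mean
#' of any supplied metric until no sample is dropped; a batch shrinking below
#' three samples stops iterating with a warning. \code{pca} mode computes the
#' first two principal components of the normalized expression and drops
#' samples beyond \code{sd_limit} (default 4) SD of either PC in a single
#' pass (set \code{iterate = TRUE} for until-stable behaviour), then
#' recomputes the PCs once for reporting.
#'
#' @param x for \code{batch_metric}: data.frame of numeric metrics with
#'   rownames = sample ids; for \code{pca}: an \code{expression_matrix}
#'   tagged log2cpm.
#' @param mode "batch_metric" or "pca".
#' @param batch factor of batch labels (batch_metric mode).
#' @param sd_limit SD cutoff; defaults to 5 (batch_metric) / 4 (pca).
#' @param iterate pca mode: iterate until stable instead of one pass.
#' @return list with \code{retained} and \code{removed} sample ids (and, in
#'   pca mode, the reporting \code{pcs}).
#' @export
remove_outlier_samples <- function(x, mode = c("batch_metric", "pca"),
                                   batch = NULL, sd_limit = NULL,
                                   iterate = FALSE) {
  mode <- match.arg(mode)
  if (mode == "batch_metric") {
    if (is.null(sd_limit)) sd_limit <- 5
    stopifnot(is.data.frame(x), !is.null(rownames(x)), !is.null(batch),
              length(batch) == nrow(x))
    if (any(table(batch) < 3)) stop("need >= 3 samples per batch")
    keep <- rep(TRUE, nrow(x))
    names(keep) <- rownames(x)
    repeat {
      drop_now <- rep(FALSE, nrow(x))
      for (b in unique(batch)) {
        rows <- which(keep & batch == b)
        if (length(rows) < 3) {
          warning("batch ", b, " below 3 samples; stopped iterating it")
          next
        }
        for (j in seq_along(x)) {
          v <- x[rows, j]
          s <- stats::sd(v)
          if (is.na(s) || s == 0) next
          drop_now[rows[abs(v - mean(v)) > sd_limit * s]] <- TRUE
        }
      }
      if (!any(drop_now)) break
      keep[drop_now] <- FALSE
    }
    list(retained = rownames(x)[keep], removed = rownames(x)[!keep])
  } else {
    if (is.null(sd_limit)) sd_limit <- 4
    stopifnot(inherits(x, "expression_matrix"), x$tag == "log2cpm")
    vals <- x$values
    keep <- rep(TRUE, ncol(vals))
    names(keep) <- colnames(vals)
    repeat {
      pc <- stats::prcomp(t(vals[, keep, drop = FALSE]), center = TRUE,
                          scale. = FALSE)$x[, 1:2, drop = FALSE]
      out <- abs(scale(pc)) > sd_limit
      bad <- rowSums(out, na.rm = TRUE) > 0
      keep[names(which(keep))[bad]] <- FALSE
      if (!iterate || !any(bad)) break
    }
    pcs <- stats::prcomp(t(vals[, keep, drop = FALSE]), center = TRUE,
                         scale. = FALSE)$x[, 1:2, drop = FALSE]
    list(retained = names(keep)[keep], removed = names(keep)[!keep],
         pcs = pcs)
  }
}

#' Estimate surrogate variables by residual SVD
#'
#' Regresses the known covariates out of the expression matrix and takes the
#' top \code{n_sv} right singular vectors of the residual as sample-level
#' surrogate variables (variance-scaled). By construction the SVs are
#' orthogonal to the known-covariate column space and to each other.
#'
#' @param em an \code{\link{expression_matrix}} tagged log2cpm, or a plain
#'   features x samples matrix.
#' @param covariates numeric model matrix (samples x k), typically including
#'   an intercept.
#' @param n_sv number of surrogate variables (default 15); must be smaller
#'   than n_samples - rank(covariates).
#' @return samples x n_sv matrix of surrogate variables, each with sample
#'   variance 1.
#' @export
estimate_surrogate_variables <- function(em, covariates, n_sv = 15) {
  vals <- if (inherits(em, "expression_matrix")) em$values else em
  X <- as.matrix(covariates)
  qr_x <- qr(X)
  if (n_sv >= ncol(vals) - qr_x$rank)
    stop("n_sv must be < n_samples - rank(covariates)")
  resid <- t(qr.resid(qr_x, t(vals)))
  sv <- svd(resid, nu = 0, nv = n_sv)$v
  sv <- scale(sv, center = TRUE, scale = TRUE)[, , drop = FALSE]
  colnames(sv) <- paste0("SV", seq_len(n_sv))
  rownames(sv) <- colnames(vals)
  sv
}

#' Residualize values on covariates by OLS
#'
#' Ordinary least-squares residuals per feature; collinear covariate columns
#' are dropped with a warning (QR pivoting), mirroring the multicollinearity
#' handling needed when genotype platform and genetic PCs overlap.
#'
#' @param values numeric matrix features x samples, or a vector.
#' @param covariates numeric model matrix samples x k.
#' @return residual matrix (or vector) orthogonal to the retained covariates.
#' @export
residualize <- function(values, covariates) {
  vec <- is.null(dim(values))
  Y <- if (vec) matrix(values, nrow = 1) else values
  X <- as.matrix(covariates)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    warning("dropped collinear covariate column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
    qr_x <- qr(X)
  }
  R <- t(qr.resid(qr_x, t(Y)))
  if (vec) as.vector(R) else R
}

#' Drop covariate columns with excessive variance inflation
#'
#' Iteratively removes the non-intercept column with the largest variance
#' inflation factor until all VIFs fall at or below \code{vif_max}
#' (default 500). Exactly collinear columns are removed first via QR.
#'
#' @param X numeric model matrix (samples x k) including an intercept column
#'   of ones.
#' @param vif_max VIF bound.
#' @return the pruned model matrix; dropped columns are reported in a warning.
#' @export
vif_prune <- function(X, vif_max = 500) {
  X <- as.matrix(X)
  qr_x <- qr(X)
  dropped <- character(0)
  if (qr_x$rank < ncol(X)) {
    bad <- qr_x$pivot[(qr_x$rank + 1):ncol(X)]
    dropped <- colnames(X)[bad]
    X <- X[, -bad, drop = FALSE]
  }
  is_icpt <- apply(X, 2, function(v) all(v == v[1]))
  repeat {
    idx <- which(!is_icpt)
    if (length(idx) < 2) break
    vifs <- vapply(idx, function(j) {
      ssr <- sum(stats::lm.fit(X[, -j, drop = FALSE], X[, j])$residuals^2)
      sst <- sum((X[, j] - mean(X[, j]))^2)
      if (ssr <= 0 || sst == 0) Inf else sst / ssr
    }, numeric(1))
    if (max(vifs) <= vif_max) break
    worst <- idx[which.max(vifs)]
    dropped <- c(dropped, colnames(X)[worst])
    is_icpt <- is_icpt[-worst]
    X <- X[, -worst, drop = FALSE]
  }
  if (length(dropped))
    warning("dropped high-VIF / collinear covariate(s): ",
            paste(dropped, collapse = ", "))
  X
}
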