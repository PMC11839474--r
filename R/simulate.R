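#' Simulate LD-structured diploid genotypes
#'
#' Draws haplotypes per LD block from a Gaussian copula with exchangeable
#' latent correlation \code{within_block_r}, thresholded at allele-frequency
#' quantiles, and sums two haplotypes per sample into an additive dosage.
#' Blocks are mutually independent, which is sufficient structure to exercise
#' clumping, conditional analysis, colocalization and HEIDI without a
#' coalescent simulation.
#'
#' @param n_samples number of diploid samples (>= 2).
#' @param n_snps number of SNPs.
#' @param block_size SNPs per LD block; a value larger than \code{n_snps}
#'   yields a single block.
#' @param within_block_r latent pairwise correlation within a block, in
#'   [0, 1). Note the realized haplotypic (binary-scale) correlation is
#'   attenuated relative to this latent value.
#' @param maf_range interval within (0, 0.5] from which alt-allele
#'   frequencies are drawn uniformly.
#' @param chrom chromosome label for all SNPs (GRCh37-style, e.g. "1").
#' @param pos_start,pos_step genomic position of the first SNP and spacing
#'   between consecutive SNPs (bp).
#' @param seed integer seed; identical calls with identical seeds return
#'   bit-identical panels.
#' @return a \code{\link{variant_panel}}.
#' @export
simulate_genotypes <- function(n_samples, n_snps, block_size = 10,
                               within_block_r = 0.8,
                               maf_range = c(0.05, 0.5),
                               chrom = "1", pos_start = 100000L,
                               pos_step = 2500L, seed = 1L) {
  if (n_samples < 2) stop("n_samples must be at least 2")
  stopifnot(n_snps >= 1, block_size >= 1,
            within_block_r >= 0, within_block_r < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  with_seed(seed, {
    n_hap <- 2L * n_samples
    block <- rep(seq_len(ceiling(n_snps / block_size)),
                 each = block_size)[seq_len(n_snps)]
    # one alt-allele frequency per block (so the pairwise haplotypic
    # correlation target is attainable exactly), latent correlation inverted
    # numerically so the thresholded binary alleles correlate at
    # within_block_r
    freq <- numeric(n_snps)
    hap <- matrix(0L, n_hap, n_snps)
    for (b in unique(block)) {
      cols <- which(block == b)
      f <- stats::runif(1, maf_range[1], maf_range[2])
      freq[cols] <- f
      rho <- latent_rho(within_block_r, f)
      common <- stats::rnorm(n_hap)
      z <- sqrt(rho) * common +
        sqrt(1 - rho) * matrix(stats::rnorm(n_hap * length(cols)), n_hap)
      hap[, cols] <- (z < stats::qnorm(f)) + 0L
    }
    dosage <- hap[seq(1, n_hap, by = 2), , drop = FALSE] +
      hap[seq(2, n_hap, by = 2), , drop = FALSE]
    storage.mode(dosage) <- "double"
    alleles <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"),
                      ncol = 2, byrow = TRUE)
    pick <- sample.int(4L, n_snps, replace = TRUE)
    snps <- data.frame(
      snp = sprintf("rs%06d", seq_len(n_snps)),
      chrom = chrom,
      pos = pos_start + (seq_len(n_snps) - 1L) * pos_step,
      ref = alleles[pick, 1], alt = alleles[pick, 2],
      stringsAsFactors = FALSE)
    rownames(dosage) <- sprintf("S%04d", seq_len(n_samples))
    colnames(dosage) <- snps$snp
    variant_panel(snps, dosage)
  })
}

# Latent Gaussian correlation giving binary (phi) correlation r_target for
# two equal-frequency thresholded variables; solved by bisection on the
# bivariate-normal orthant probability.
latent_rho <- function(r_target, f) {
  if (r_target <= 0) return(0)
  q <- stats::qnorm(f)
  p11 <- function(rho) {
    stats::integrate(function(z)
      stats::dnorm(z) * stats::pnorm((q - rho * z) / sqrt(1 - rho^2)),
      -Inf, q, rel.tol = 1e-10)$value
  }
  phi <- function(rho) (p11(rho) - f^2) / (f * (1 - f))
  lo <- 0; hi <- 1 - 1e-9
  if (phi(hi) <= r_target) return(hi)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (phi(mid) < r_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate negative-binomial miRNA counts with planted cis effects
#'
#' Per-feature log2 relative abundance is baseline + planted SNP effects +
#' batch offsets + three hidden Gaussian factors + white noise; counts are
#' drawn negative-binomially (Var = mu + mu^2 * dispersion) against per-sample
#' library sizes. Planted effects are calibrated against the realized
#' non-genetic variance so the genetic variance fraction on the log2 scale
#' equals \code{var_frac} in-sample; the calibrated allelic effect is written
#' back into the returned truth object.
#'
#' @param panel a \code{\link{variant_panel}} providing dosages.
#' @param truth a \code{\link{sim_truth}}; every causal SNP must exist in
#'   \code{panel}, and the variance fractions of one feature must sum to < 1.
#' @param n_features total number of features; features absent from the causal
#'   map are simulated as nulls. Defaults to the causal features only.
#' @param n_batches number of library-preparation batches.
#' @param libsize_range range of per-sample library sizes (reads), drawn
#'   uniformly.
#' @param dispersion negative-binomial dispersion (Var = mu + mu^2 *
#'   dispersion); 0 gives Poisson counts. This layer models technical
#'   overdispersion of the counting process only -- biological variability
#'   is carried explicitly by the batch/hidden-factor/noise terms -- so the
#'   default is a technical-scale 0.05.
#' @param batch_sd,factor_sd,noise_sd standard deviations (log2 scale) of the
#'   batch offsets, the three hidden-factor contributions, and white noise.
#' @param base_range range of baseline log2-RPM values.
#' @param seed integer seed.
#' @return list with \code{expr} (an \code{\link{expression_matrix}} of raw
#'   counts), \code{truth} (with calibrated betas and realized variance
#'   fractions), \code{covariates} (data.frame with the batch factor) and
#'   \code{factors} (the hidden factor scores, for oracle checks).
#' @export
simulate_mirna_counts <- function(panel, truth, n_features = NULL,
                                  n_batches = 4,
                                  libsize_range = c(13.2e6, 37.4e6),
                                  dispersion = 0.05,
                                  batch_sd = 0.3, factor_sd = 0.4,
                                  noise_sd = 0.5,
                                  base_range = c(2, 9), seed = 1L) {
  stopifnot(inherits(panel, "variant_panel"), inherits(truth, "sim_truth"))
  cm <- truth$causal_map
  missing_snp <- setdiff(cm$snp, panel$snps$snp)
  if (length(missing_snp))
    stop("causal SNP(s) not in panel: ", paste(missing_snp, collapse = ", "))
  tot <- tapply(cm$var_frac, cm$feature, sum)
  if (any(tot >= 1))
    stop("per-feature variance fractions must sum to < 1")
  feats <- unique(cm$feature)
  if (is.null(n_features)) n_features <- length(feats)
  if (n_features < length(feats)) stop("n_features smaller than causal map")
  feats <- c(feats, sprintf("null-mir-%03d",
                            seq_len(n_features - length(feats))))
  n <- nrow(panel$dosage)
  with_seed(seed, {
    lib <- round(stats::runif(n, libsize_range[1], libsize_range[2]))
    batch <- factor(sample(rep_len(seq_len(n_batches), n)))
    fac <- matrix(stats::rnorm(n * 3), n, 3)  # k = 3 hidden factors
    base <- stats::runif(length(feats), base_range[1], base_range[2])
    eta <- matrix(0, n, length(feats),
                  dimnames = list(rownames(panel$dosage), feats))
    cm$beta <- rep(NA_real_, nrow(cm))
    cm$realized_var_frac <- rep(NA_real_, nrow(cm))
    for (j in seq_along(feats)) {
      f <- feats[j]
      boff <- stats::rnorm(n_batches, 0, batch_sd)[batch]
      load <- stats::rnorm(3, 0, factor_sd)
      struct <- boff + as.vector(fac %*% load)  # removed by covariates/SVs
      eps <- stats::rnorm(n, 0, noise_sd)
      rows <- which(cm$feature == f)
      g <- 0
      # expected log2-scale variance added by NB count sampling (delta
      # method): var(ln X) ~ 1/mu + dispersion, converted to log2
      mu0 <- lib * 2^(base[j] + struct + eps) / 1e6
      v_count <- mean(1 / mu0 + dispersion) / log(2)^2
      if (length(rows)) {
        dos <- panel$dosage[, cm$snp[rows], drop = FALSE]
        # orthogonalize the noise against the causal dosages so the planted
        # variance fraction is exact in-sample
        eps <- stats::lm.fit(cbind(1, dos), eps)$residuals
        sgn <- sample(c(-1, 1), length(rows), replace = TRUE)
        # variance fractions are defined on the covariate-residualized
        # scale (the paper's unit), so the denominator is the white-noise
        # plus count-sampling variance; batch and hidden-factor variance
        # are absorbed by covariates/SVs downstream
        vfr <- cm$var_frac[rows]
        ve <- stats::var(eps) + v_count
        beta <- numeric(length(rows))
        for (k in seq_along(rows)) {
          vd <- stats::var(dos[, k])
          beta[k] <- if (vfr[k] > 0 && vd > 0)
            sgn[k] * sqrt(vfr[k] / (1 - sum(vfr)) * ve / vd) else 0
        }
        g <- as.vector(dos %*% beta)
        cm$beta[rows] <- beta
        tv <- stats::var(g + eps) + v_count
        for (k in seq_along(rows))
          cm$realized_var_frac[rows[k]] <-
            stats::var(dos[, k] * beta[k]) / tv
      }
      eta[, j] <- base[j] + g + struct + eps
    }
    mu <- 2^eta * (lib / 1e6)  # eta is log2 RPM; rows are samples
    cnt <- if (dispersion > 0)
      stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion)
    else stats::rpois(length(mu), as.vector(mu))
    counts <- t(matrix(cnt, nrow = n))
    dimnames(counts) <- list(feats, rownames(panel$dosage))
    truth$causal_map <- cm
    expr <- expression_matrix(
      counts, tag = "counts", lib_sizes = lib,
      features = data.frame(mature_id = feats, precursor_id = feats,
                            stringsAsFactors = FALSE))
    list(expr = expr, truth = truth,
         covariates = data.frame(sample = rownames(panel$dosage),
                                 batch = batch,
                                 stringsAsFactors = FALSE),
         factors = fac)
  })
}

#' Simulate GWAS summary z-scores over a locus
#'
#' Draws the per-SNP z-score vector from the multivariate normal implied by
#' the panel's LD matrix, z ~ N(R ncp, R), where the non-centrality ncp
#' carries the scenario's true effect: \code{mediated} places the trait's
#' causal SNP on the miRNA's causal SNP with standardized effect
#' (mediation effect) x sqrt(var_frac); \code{pleiotropy} places an
#' independent direct effect on the same SNP; \code{linkage} places it on a
#' correlated but distinct SNP; \code{null} has no effect.
#'
#' @param panel a \code{\link{variant_panel}} (defines the LD matrix).
#' @param truth a \code{\link{sim_truth}} whose first causal-map row (or the
#'   row for \code{feature}) identifies the exposure SNP.
#' @param scenario one of "mediated", "pleiotropy", "linkage", "null".
#' @param n_gwas GWAS sample size (drives the non-centrality).
#' @param feature which causal feature of the truth to use; default first.
#' @param direct_effect standardized per-allele trait effect used by the
#'   pleiotropy and linkage scenarios.
#' @param linkage_r2 admissible r-squared range to the exposure SNP when
#'   picking the linkage scenario's causal SNP.
#' @param seed integer seed.
#' @return data.frame (snp, chrom, pos, a1, a2, beta, se, z, p, n) with a1 =
#'   alt allele; beta/se on the standardized-genotype scale implied by z and
#'   the allele frequency.
#' @export
simulate_gwas_summary <- function(panel, truth,
                                  scenario = c("mediated", "pleiotropy",
                                               "linkage", "null"),
                                  n_gwas = 50000, feature = NULL,
                                  direct_effect = 0.02,
                                  linkage_r2 = c(0.3, 0.95), seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(panel, "variant_panel"))
  R <- stats::cor(panel$dosage)
  m <- ncol(R)
  ncp <- numeric(m)
  if (scenario != "null") {
    cm <- truth$causal_map
    if (!is.null(feature)) cm <- cm[cm$feature == feature, , drop = FALSE]
    if (!nrow(cm)) stop("no causal SNP in truth for the requested scenario")
    exp_idx <- match(cm$snp[1], panel$snps$snp)
    if (is.na(exp_idx)) stop("exposure SNP not in panel")
    if (scenario == "mediated") {
      med <- truth$mediation_map
      if (is.null(med) || !nrow(med)) stop("mediated scenario needs a mediation_map")
      if (!is.null(feature)) med <- med[med$feature == feature, , drop = FALSE]
      b_x <- sign(cm$beta[1]) * sqrt(cm$var_frac[1])
      if (is.na(b_x)) b_x <- sqrt(cm$var_frac[1])
      b <- med$effect[1] * b_x
      ncp[exp_idx] <- sqrt(n_gwas) * b
    } else if (scenario == "pleiotropy") {
      ncp[exp_idx] <- sqrt(n_gwas) * direct_effect
    } else {  # linkage
      r2 <- R[, exp_idx]^2
      cand <- which(r2 >= linkage_r2[1] & r2 <= linkage_r2[2] &
                      seq_len(m) != exp_idx)
      if (!length(cand))
        stop("no SNP with r2 in [", linkage_r2[1], ", ", linkage_r2[2],
             "] with the exposure SNP")
      pick <- cand[which.max(r2[cand])]
      ncp[pick] <- sqrt(n_gwas) * direct_effect
    }
  }
  with_seed(seed, {
    z <- rmvnorm1(as.vector(R %*% ncp), R)
    f <- colMeans(panel$dosage) / 2
    se <- 1 / sqrt(2 * f * (1 - f) * n_gwas)
    data.frame(snp = panel$snps$snp, chrom = panel$snps$chrom,
               pos = panel$snps$pos,
               a1 = panel$snps$alt, a2 = panel$snps$ref,
               beta = z * se, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)), n = n_gwas,
               stringsAsFactors = FALSE)
  })
}

#' Simulate regulatory annotation intervals with a planted odds ratio
#'
#' Assigns interval membership per SNP so that, within every MAF stratum, the
#' odds of a miR-QTL SNP overlapping an interval versus a non-QTL SNP equal
#' \code{target_or}, then merges member SNP positions into genomic intervals.
#'
#' @param snps a \code{\link{variant_panel}} or a data.frame with columns
#'   \code{snp}, \code{chrom}, \code{pos}, \code{maf}.
#' @param qtl_snps character vector of miR-QTL SNP ids (non-empty).
#' @param target_or stratum-constant odds ratio (> 0).
#' @param strata MAF bin edges; defaults to the three bins
#'   (0-0.1), [0.1-0.2), [0.2-0.5].
#' @param base_rate overlap probability for non-QTL SNPs in every stratum.
#' @param seed integer seed.
#' @return list with \code{intervals} (data.frame chrom/start/end, 1-based
#'   inclusive) and \code{member} (logical vector over SNPs, the planted
#'   membership used to build them).
#' @export
simulate_annotations <- function(snps, qtl_snps, target_or,
                                 strata = c(0, 0.1, 0.2, 0.5),
                                 base_rate = 0.3, seed = 1L) {
  if (inherits(snps, "variant_panel")) {
    snps <- data.frame(snp = snps$snps$snp, chrom = snps$snps$chrom,
                       pos = snps$snps$pos, maf = snps$snps$maf,
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("snp", "chrom", "pos", "maf") %in% names(snps)))
  if (length(qtl_snps) == 0) stop("qtl_snps must be non-empty")
  if (target_or <= 0) stop("target_or must be positive")
  is_qtl <- snps$snp %in% qtl_snps
  p1 <- target_or * base_rate / (1 - base_rate) /
    (1 + target_or * base_rate / (1 - base_rate))
  with_seed(seed, {
    pr <- ifelse(is_qtl, p1, base_rate)
    member <- stats::runif(nrow(snps)) < pr
    iv <- do.call(rbind, lapply(split(snps[member, , drop = FALSE],
                                      snps$chrom[member]), function(d) {
      if (!nrow(d)) return(NULL)
      r <- IRanges::reduce(IRanges::IRanges(d$pos, d$pos))
      data.frame(chrom = d$chrom[1], start = IRanges::start(r),
                 end = IRanges::end(r), stringsAsFactors = FALSE)
    }))
    rownames(iv) <- NULL
    list(intervals = iv, member = member)
  })
}
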