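#' Flag SNPs overlapping a set of genomic intervals
#'
#' Membership is inclusive at both interval ends (internal 1-based inclusive
#' convention).
#'
#' @param snps data.frame with \code{chrom} and \code{pos}, or a
#'   \code{\link{variant_panel}}.
#' @param intervals data.frame with chrom, start, end (1-based inclusive);
#'   may be empty.
#' @return logical vector, one element per SNP.
#' @export
overlap_flags <- function(snps, intervals) {
  if (inherits(snps, "variant_panel")) snps <- snps$snps
  if (is.null(intervals) || nrow(intervals) == 0)
    return(rep(FALSE, nrow(snps)))
  stopifnot(all(intervals$start <= intervals$end))
  flags <- rep(FALSE, nrow(snps))
  for (ch in unique(snps$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (!nrow(iv)) next
    rows <- which(snps$chrom == ch)
    ir <- IRanges::IRanges(iv$start, iv$end)
    qr <- IRanges::IRanges(snps$pos[rows], snps$pos[rows])
    flags[rows] <- IRanges::overlapsAny(qr, ir)
  }
  flags
}

#' Build MAF-stratified 2x2 tables for enrichment testing
#'
#' @param is_qtl logical vector: is the SNP a miR-QTL?
#' @param in_interval logical vector: does the SNP overlap the annotation?
#' @param maf per-SNP minor allele frequency.
#' @param strata MAF bin edges; default the three bins (0-0.1), [0.1-0.2),
#'   [0.2-0.5].
#' @return 2 x 2 x K array of counts (rows: QTL yes/no; cols: overlap
#'   yes/no), strata with empty margins retained.
#' @export
stratified_tables <- function(is_qtl, in_interval, maf,
                              strata = c(0, 0.1, 0.2, 0.5)) {
  stopifnot(length(is_qtl) == length(in_interval),
            length(maf) == length(is_qtl))
  bin <- cut(maf, breaks = strata, include.lowest = FALSE, right = FALSE)
  bin[maf == strata[length(strata)]] <- levels(bin)[nlevels(bin)]
  tabs <- array(0, dim = c(2, 2, nlevels(bin)),
                dimnames = list(qtl = c("yes", "no"),
                                overlap = c("yes", "no"),
                                stratum = levels(bin)))
  for (k in seq_len(nlevels(bin))) {
    rows <- which(as.integer(bin) == k)
    tabs[, , k] <- c(sum(is_qtl[rows] & in_interval[rows]),
                     sum(!is_qtl[rows] & in_interval[rows]),
                     sum(is_qtl[rows] & !in_interval[rows]),
                     sum(!is_qtl[rows] & !in_interval[rows]))
  }
  tabs
}

#' Cochran-Mantel-Haenszel test with common odds ratio
#'
#' Mantel-Haenszel common OR = sum(a_k d_k / n_k) / sum(b_k c_k / n_k), CMH
#' chi-squared without continuity correction, and a 95% CI from the
#' Robins-Breslow-Greenland variance of log OR. Reduces exactly to the
#' single-table MH estimator with one stratum. A zero denominator yields a
#' +Inf sentinel OR with a warning.
#'
#' @param tables 2 x 2 x K array (see \code{\link{stratified_tables}}) or a
#'   single 2 x 2 matrix.
#' @return list (or, ci (length 2), statistic, p).
#' @export
cmh_test <- function(tables) {
  if (is.matrix(tables)) tables <- array(tables, dim = c(2, 2, 1))
  a <- tables[1, 1, ]; b <- tables[2, 1, ]
  c_ <- tables[1, 2, ]; d <- tables[2, 2, ]
  n <- a + b + c_ + d
  use <- n > 0
  a <- a[use]; b <- b[use]; c_ <- c_[use]; d <- d[use]; n <- n[use]
  num <- sum(a * d / n)
  den <- sum(b * c_ / n)
  if (den == 0) {
    warning("zero MH denominator: odds ratio returned as +Inf")
    or <- Inf
    ci <- c(NA_real_, NA_real_)
  } else {
    or <- num / den
    # Robins-Breslow-Greenland variance of log(OR_MH)
    P <- (a + d) / n; Q <- (b + c_) / n
    Rk <- a * d / n; Sk <- b * c_ / n
    v <- sum(P * Rk) / (2 * sum(Rk)^2) +
      sum(P * Sk + Q * Rk) / (2 * sum(Rk) * sum(Sk)) +
      sum(Q * Sk) / (2 * sum(Sk)^2)
    ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * sqrt(v))
  }
  m1 <- (a + b) * (a + c_) / n
  v1 <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * pmax(n - 1, 1))
  stat <- if (sum(v1) > 0) sum(a - m1)^2 / sum(v1) else 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(or = or, ci = ci, statistic = stat, p = p)
}

#' Chi-squared test of cross-study eMiR sharing
#'
#' Reconstructs the 2x2 table (shared; study-A only; study-B only; neither)
#' from the printed counts and applies the chi-squared test of independence
#' with Yates continuity correction.
#'
#' @param both_tested miRNAs tested in both studies.
#' @param emirs_a,emirs_b eMiR counts among those, per study.
#' @param shared miRNAs that are eMiRs in both.
#' @return list (statistic, p, table).
#' @export
sharing_chi2 <- function(both_tested, emirs_a, emirs_b, shared) {
  stopifnot(shared <= min(emirs_a, emirs_b),
            emirs_a <= both_tested, emirs_b <= both_tested)
  tab <- matrix(c(shared, emirs_a - shared,
                  emirs_b - shared,
                  both_tested - emirs_a - emirs_b + shared),
                2, 2, byrow = TRUE,
                dimnames = list(a = c("eMiR", "not"), b = c("eMiR", "not")))
  if (any(tab < 0)) stop("negative reconstructed cell")
  ct <- stats::chisq.test(tab, correct = TRUE)
  list(statistic = unname(ct$statistic), p = unname(ct$p.value), table = tab)
}

#' Storey pi1 replication statistic
#'
#' Fraction of true positives among replication p-values of discovery hits,
#' pi1 = 1 - pi0 with pi0 from \code{\link{storey_qvalues}}.
#'
#' @param p replication p-values for the discovery top hits (>= 50 required).
#' @return list (pi1, n, reason); pi1 is NA with a reason below 50 p-values.
#' @export
pi1 <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 50)
    return(list(pi1 = NA_real_, n = length(p),
                reason = "fewer than 50 replication p-values"))
  pi0 <- suppressWarnings(storey_qvalues(p)$pi0)
  list(pi1 = 1 - pi0, n = length(p), reason = NA_character_)
}

#' Positional statistics of index miR-QTLs
#'
#' Classifies each index miR-QTL relative to its miRNA's precursor(s) in the
#' gene's transcriptional orientation: upstream, downstream, within the
#' precursor, or ambiguous (between/among multiple precursors); the up/down
#' imbalance is tested with an exact two-sided binomial test at p = 0.5
#' (minimum-likelihood two-sided rule), and |distance to TSS| is correlated
#' with the association p-value by Spearman rank correlation with average
#' ranks.
#'
#' @param qtls data.frame (mirna, snp, pos, p) of index miR-QTLs.
#' @param annotation miRNA coordinate table (multiple precursors per mature
#'   id allowed).
#' @param strand_aware classify relative to the miRNA gene's strand (default
#'   TRUE); FALSE uses the genomic-left convention.
#' @return list with counts (upstream, downstream, within, ambiguous),
#'   binomial_p, spearman_rho, spearman_p, and the per-QTL classification
#'   data.frame.
#' @export
position_stats <- function(qtls, annotation, strand_aware = TRUE) {
  cls <- character(nrow(qtls))
  dist <- rep(NA_real_, nrow(qtls))
  for (i in seq_len(nrow(qtls))) {
    prec <- annotation[annotation$mature_id == qtls$mirna[i], , drop = FALSE]
    if (!nrow(prec)) { cls[i] <- "ambiguous"; next }
    pos <- qtls$pos[i]
    within <- any(pos >= prec$start & pos <= prec$end)
    if (within) { cls[i] <- "within"; next }
    side <- ifelse(pos < prec$start, "left", "right")
    if (length(unique(side)) > 1) { cls[i] <- "ambiguous"; next }
    strand <- prec$strand[1]
    up <- if (strand_aware && strand == "-") side[1] == "right"
    else side[1] == "left"
    cls[i] <- if (up) "upstream" else "downstream"
    tss <- if (strand == "-" && strand_aware) max(prec$end) else
      min(prec$start)
    dist[i] <- abs(pos - tss)
  }
  n_up <- sum(cls == "upstream"); n_down <- sum(cls == "downstream")
  binom_p <- if (n_up + n_down > 0)
    stats::binom.test(n_up, n_up + n_down, 0.5)$p.value else NA_real_
  ok <- cls %in% c("upstream", "downstream")
  if (sum(ok) >= 3) {
    rho <- stats::cor(rank(dist[ok]), rank(qtls$p[ok]))
    sp <- suppressWarnings(
      stats::cor.test(dist[ok], qtls$p[ok], method = "spearman"))
    spearman_p <- sp$p.value
  } else {
    rho <- NA_real_; spearman_p <- NA_real_
  }
  list(counts = c(upstream = n_up, downstream = n_down,
                  within = sum(cls == "within"),
                  ambiguous = sum(cls == "ambiguous")),
       binomial_p = binom_p, spearman_rho = rho, spearman_p = spearman_p,
       classification = data.frame(qtls, class = cls, tss_distance = dist,
                                   stringsAsFactors = FALSE))
}
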