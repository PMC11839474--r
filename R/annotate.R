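#' Classify miRNA precursors as intragenic or intergenic
#'
#' A precursor is intragenic iff it overlaps (>= 1 bp) a same-strand gene of
#' an eligible biotype (protein-coding, lncRNA, or short non-coding RNA other
#' than miRNA); otherwise intergenic. With multiple hosts, all are recorded
#' and the primary host is the one with the longest overlap.
#'
#' @param annotation miRNA coordinate table (one row per precursor entry).
#' @param genes data.frame (gene_id, biotype, chrom, start, end, strand).
#' @param eligible_biotypes biotypes that can host a miRNA.
#' @return data.frame per precursor: precursor_id, class
#'   ("intragenic"/"intergenic"), host (primary host gene id or NA),
#'   all_hosts (comma-separated).
#' @export
classify_intragenic <- function(annotation, genes,
                                eligible_biotypes = c("protein_coding",
                                                      "lncRNA", "snoRNA",
                                                      "snRNA", "scRNA",
                                                      "misc_RNA")) {
  g <- genes[genes$biotype %in% eligible_biotypes, , drop = FALSE]
  prec <- unique(annotation[, c("precursor_id", "chrom", "start", "end",
                                "strand")])
  out <- data.frame(precursor_id = prec$precursor_id,
                    class = "intergenic", host = NA_character_,
                    all_hosts = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(prec))) {
    hit <- g$chrom == prec$chrom[i] & g$strand == prec$strand[i] &
      g$start <= prec$end[i] & g$end >= prec$start[i]
    if (!any(hit)) next
    ov <- pmin(g$end[hit], prec$end[i]) - pmax(g$start[hit], prec$start[i]) + 1
    hosts <- g$gene_id[hit][order(-ov)]
    out$class[i] <- "intragenic"
    out$host[i] <- hosts[1]
    out$all_hosts[i] <- paste(hosts, collapse = ",")
  }
  out
}

#' Assign miRNA precursors to genomic clusters
#'
#' Single-linkage chaining: adjacent precursors (sorted by position within a
#' chromosome) whose inter-gene gap is below \code{gap_max} share a cluster
#' label; everything else is its own cluster.
#'
#' @param precursors data.frame (precursor_id, chrom, start, end).
#' @param gap_max maximum inter-miRNA distance in bp (default 10,000,
#'   exclusive).
#' @return character vector of cluster labels aligned with \code{precursors}.
#' @export
assign_clusters <- function(precursors, gap_max = 10000) {
  lab <- character(nrow(precursors))
  cl <- 0L
  for (ch in unique(precursors$chrom)) {
    rows <- which(precursors$chrom == ch)
    rows <- rows[order(precursors$start[rows])]
    for (k in seq_along(rows)) {
      gap <- if (k == 1) Inf else
        precursors$start[rows[k]] - precursors$end[rows[k - 1]]
      if (gap >= gap_max) cl <- cl + 1L
      lab[rows[k]] <- sprintf("cluster%03d", cl)
    }
  }
  lab
}

#' Host-gene correlation of intragenic miRNAs with a resampling background
#'
#' Spearman correlation per (miRNA, host transcript) pair on residualized
#' abundances, compared set-level against correlations of randomly re-paired
#' miRNA-gene combinations by a two-sided Wilcoxon rank-sum test.
#'
#' @param mirna_resid features x samples residual matrix (miRNA).
#' @param transcript_resid features x samples residual matrix (transcripts).
#' @param pairs data.frame (mirna, gene) of intragenic miRNA-host pairs.
#' @param n_resample number of random background pairs (default 1000).
#' @param min_samples minimum overlapping samples per pair (default 10).
#' @param seed integer seed for the background resampling.
#' @return list with per-pair data.frame (mirna, gene, rho, p, n),
#'   \code{wilcoxon_p} and the background correlations.
#' @export
host_correlation <- function(mirna_resid, transcript_resid, pairs,
                             n_resample = 1000, min_samples = 10,
                             seed = 1L) {
  shared <- intersect(colnames(mirna_resid), colnames(transcript_resid))
  pair_rho <- function(m, g) {
    if (!(m %in% rownames(mirna_resid)) ||
        !(g %in% rownames(transcript_resid))) return(c(NA, NA, 0))
    x <- mirna_resid[m, shared]; y <- transcript_resid[g, shared]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_samples) return(c(NA, NA, sum(ok)))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                           method = "spearman"))
    c(ct$estimate, ct$p.value, sum(ok))
  }
  obs <- t(mapply(pair_rho, pairs$mirna, pairs$gene))
  res <- data.frame(pairs, rho = obs[, 1], p = obs[, 2], n = obs[, 3],
                    row.names = NULL, stringsAsFactors = FALSE)
  bg <- with_seed(seed, {
    ms <- sample(rownames(mirna_resid), n_resample, replace = TRUE)
    gs <- sample(rownames(transcript_resid), n_resample, replace = TRUE)
    vapply(seq_len(n_resample),
           function(i) pair_rho(ms[i], gs[i])[1], numeric(1))
  })
  wp <- if (sum(!is.na(res$rho)) >= 3)
    suppressWarnings(stats::wilcox.test(res$rho, bg)$p.value) else NA_real_
  list(pairs = res, wilcoxon_p = wp, background = bg)
}

#' miR-QTL sharing with predicted-target protein abundance
#'
#' Tests each (miR-QTL SNP, predicted-target protein) pair by OLS of protein
#' abundance on SNP dosage (plus optional covariates), corrects across all
#' tests run by Benjamini-Hochberg, and labels each FDR-significant shared
#' pair cis (protein within \code{cis_kb} of the miRNA precursor on the same
#' chromosome) or trans. Proteins missing in more than half the samples are
#' excluded.
#'
#' @param mir_qtls data.frame (mirna, snp) of index/conditional miR-QTLs.
#' @param protein_mat proteins x samples abundance matrix (residualized).
#' @param panel a \code{\link{variant_panel}}.
#' @param targets data.frame (mirna, gene) of predicted miRNA targets.
#' @param protein_coords data.frame (gene, chrom, start, end).
#' @param mirna_coords data.frame (mirna, chrom, start, end) of precursors.
#' @param covariates optional samples x k model matrix.
#' @param fdr_max FDR threshold for a shared pair (default 0.05).
#' @param cis_kb cis distance bound in kb (default 500).
#' @param max_missing maximum missing fraction per protein (default 0.5).
#' @return data.frame of all tests (mirna, snp, gene, beta, p, fdr, shared,
#'   location).
#' @export
target_pqtl_share <- function(mir_qtls, protein_mat, panel, targets,
                              protein_coords, mirna_coords,
                              covariates = NULL, fdr_max = 0.05,
                              cis_kb = 500, max_missing = 0.5) {
  keep_prot <- rowMeans(is.na(protein_mat)) <= max_missing
  protein_mat <- protein_mat[keep_prot, , drop = FALSE]
  samples <- intersect(colnames(protein_mat), rownames(panel$dosage))
  rows <- list()
  for (i in seq_len(nrow(mir_qtls))) {
    m <- mir_qtls$mirna[i]; s <- mir_qtls$snp[i]
    if (!(s %in% panel$snps$snp)) next
    genes <- intersect(targets$gene[targets$mirna == m],
                       rownames(protein_mat))
    for (g in genes) {
      y <- protein_mat[g, samples]
      ok <- !is.na(y)
      x <- panel$dosage[samples, s][ok]
      X <- cbind(rep(1, sum(ok)), if (!is.null(covariates))
        as.matrix(covariates)[samples, , drop = FALSE][ok, , drop = FALSE])
      pv <- cond_p(y[ok], x, X)
      fit_b <- sum(qr.resid(qr(X), x) * qr.resid(qr(X), y[ok])) /
        sum(qr.resid(qr(X), x)^2)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = m, snp = s, gene = g, beta = fit_b, p = pv,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$shared <- !is.na(out$fdr) & out$fdr < fdr_max
  out$location <- NA_character_
  pc <- protein_coords[match(out$gene, protein_coords$gene), ]
  mc <- mirna_coords[match(out$mirna, mirna_coords$mirna), ]
  same_chr <- !is.na(pc$chrom) & !is.na(mc$chrom) & pc$chrom == mc$chrom
  gap <- pmax(0, pmax(pc$start, mc$start) - pmin(pc$end, mc$end))
  out$location <- ifelse(same_chr & gap <= cis_kb * 1000, "cis", "trans")
  out
}
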