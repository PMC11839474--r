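test_that("intragenic classification needs overlap, strand match and biotype", {
  ann <- data.frame(mature_id = c("m1", "m2", "m3", "m4"),
                    precursor_id = c("p1", "p2", "p3", "p4"),
                    chrom = "1",
                    start = c(5000L, 6000L, 7000L, 20000L),
                    end = c(5080L, 6080L, 7080L, 20080L),
                    strand = c("+", "-", "+", "+"),
                    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("HOST", "MIRGENE", "FAR"),
                      biotype = c("protein_coding", "miRNA",
                                  "protein_coding"),
                      chrom = "1",
                      start = c(4000L, 6900L, 100000L),
                      end = c(9000L, 7200L, 110000L),
                      strand = "+", stringsAsFactors = FALSE)
  cl <- classify_intragenic(ann, genes)
  # intronic same-strand precursor: intragenic with the host recorded
  expect_equal(cl$class[cl$precursor_id == "p1"], "intragenic")
  expect_equal(cl$host[cl$precursor_id == "p1"], "HOST")
  # full overlap but opposite strand: intergenic
  expect_equal(cl$class[cl$precursor_id == "p2"], "intergenic")
  # overlap only with another miRNA gene: intergenic (ineligible biotype);
  # here p3 also sits inside HOST, so restrict the gene set to test the rule
  cl3 <- classify_intragenic(ann[3, ], genes[genes$gene_id == "MIRGENE", ])
  expect_equal(cl3$class, "intergenic")
  expect_equal(cl$class[cl$precursor_id == "p4"], "intergenic")
})

test_that("cluster assignment chains precursors transitively under 10 kb", {
  prec <- data.frame(precursor_id = c("a", "b", "c", "d", "e"),
                     chrom = c("1", "1", "1", "1", "2"),
                     start = c(10000L, 16000L, 22000L, 40000L, 10000L),
                     end = c(10100L, 16100L, 22100L, 40100L, 10100L),
                     stringsAsFactors = FALSE)
  lab <- assign_clusters(prec)
  # a-5.9kb-b-5.9kb-c chain into one cluster; d 17.9 kb away separate
  expect_equal(lab[1], lab[2])
  expect_equal(lab[2], lab[3])
  expect_false(lab[3] == lab[4])
  expect_false(lab[4] == lab[5])  # different chromosome
  # 15 kb gap splits
  prec2 <- prec[1:2, ]
  prec2$start[2] <- 25100L; prec2$end[2] <- 25200L
  lab2 <- assign_clusters(prec2)
  expect_false(lab2[1] == lab2[2])
  # permutation invariance
  perm <- c(3, 5, 1, 4, 2)
  expect_identical(assign_clusters(prec[perm, ])[order(perm)], lab)
})

test_that("host correlation detects planted coupling and stays null otherwise", {
  set.seed(101)
  n <- 200
  mk <- function(coupled_frac) {
    n_pairs <- 60
    mir <- matrix(rnorm(n_pairs * n), n_pairs, n,
                  dimnames = list(paste0("mir", 1:n_pairs),
                                  paste0("S", 1:n)))
    tx <- matrix(rnorm(n_pairs * n), n_pairs, n,
                 dimnames = list(paste0("g", 1:n_pairs), paste0("S", 1:n)))
    k <- round(coupled_frac * n_pairs)
    if (k > 0)
      for (i in seq_len(k)) tx[i, ] <- 0.7 * mir[i, ] + sqrt(0.51) * tx[i, ]
    list(mir = mir, tx = tx,
         pairs = data.frame(mirna = rownames(mir), gene = rownames(tx)))
  }
  # monotone transform: rho = 1
  one <- mk(0)
  one$tx[1, ] <- exp(one$mir[1, ])
  hc1 <- host_correlation(one$mir, one$tx, one$pairs[1, ], n_resample = 50)
  expect_equal(unname(hc1$pairs$rho[1]), 1)

  null_sig <- vapply(1:20, function(s) {
    set.seed(300 + s)
    d <- mk(0)
    host_correlation(d$mir, d$tx, d$pairs, n_resample = 200,
                     seed = s)$wilcoxon_p < 0.05
  }, logical(1))
  expect_gte(mean(!null_sig), 0.9)

  pow_sig <- vapply(1:20, function(s) {
    set.seed(400 + s)
    d <- mk(0.3)
    host_correlation(d$mir, d$tx, d$pairs, n_resample = 200,
                     seed = s)$wilcoxon_p < 0.05
  }, logical(1))
  expect_gte(mean(pow_sig), 0.8)
})

test_that("target-protein sharing finds a planted trans effect and labels cis/trans", {
  hits <- vapply(1:20, function(s) {
    p <- simulate_genotypes(500, 30, seed = 1500 + s)
    tr <- sim_truth(data.frame(feature = "mirX", snp = p$snps$snp[15],
                               var_frac = 0.1))
    sim <- simulate_mirna_counts(p, tr, n_features = 10, seed = 1600 + s)
    em <- normalize_log2(sim$expr)
    covars <- cbind(stats::model.matrix(~ batch, sim$covariates),
                    sim$factors)
    mir_resid <- residualize(em$values["mirX", ], covars)
    # distant target protein partially driven by the miRNA (trans effect)
    set.seed(1700 + s)
    prot <- -0.5 * scale(mir_resid)[, 1] + rnorm(500, 0, sqrt(0.75))
    pm <- matrix(c(prot, rnorm(500)), 2, 500, byrow = TRUE,
                 dimnames = list(c("TARG", "OTHER"),
                                 rownames(p$dosage)))
    res <- target_pqtl_share(
      mir_qtls = data.frame(mirna = "mirX", snp = p$snps$snp[15]),
      protein_mat = pm, panel = p,
      targets = data.frame(mirna = c("mirX", "mirX"),
                           gene = c("TARG", "OTHER")),
      protein_coords = data.frame(gene = c("TARG", "OTHER"),
                                  chrom = c("7", "1"),
                                  start = c(1e6, 180000),
                                  end = c(1e6 + 5e4, 230000)),
      mirna_coords = data.frame(mirna = "mirX", chrom = "1",
                                start = 137500, end = 137600))
    res$shared[res$gene == "TARG"]
  }, logical(1))
  expect_gte(mean(hits), 0.7)

  # cis/trans labels follow the 500 kb / different-chromosome rule
  p <- simulate_genotypes(100, 5, seed = 1900)
  pm <- matrix(rnorm(200), 2, 100,
               dimnames = list(c("NEAR", "FARGENE"), rownames(p$dosage)))
  res <- target_pqtl_share(
    mir_qtls = data.frame(mirna = "mirX", snp = p$snps$snp[3]),
    protein_mat = pm, panel = p,
    targets = data.frame(mirna = c("mirX", "mirX"),
                         gene = c("NEAR", "FARGENE")),
    protein_coords = data.frame(gene = c("NEAR", "FARGENE"), chrom = "1",
                                start = c(237600, 737601),
                                end = c(238000, 738000)),
    mirna_coords = data.frame(mirna = "mirX", chrom = "1",
                              start = 137500, end = 137600))
  expect_equal(res$location[res$gene == "NEAR"], "cis")     # 100 kb away
  expect_equal(res$location[res$gene == "FARGENE"], "trans") # 600 kb away

  # null couplings: essentially no FDR-significant pairs
  set.seed(2000)
  pm0 <- matrix(rnorm(50 * 100), 50, 100,
                dimnames = list(paste0("prt", 1:50), rownames(p$dosage)))
  res0 <- target_pqtl_share(
    mir_qtls = data.frame(mirna = rep("mirX", 5), snp = p$snps$snp),
    protein_mat = pm0, panel = p,
    targets = data.frame(mirna = "mirX", gene = rownames(pm0)),
    protein_coords = data.frame(gene = rownames(pm0), chrom = "9",
                                start = 1e6 + 1:50 * 1e4,
                                end = 1e6 + 1:50 * 1e4 + 5e3),
    mirna_coords = data.frame(mirna = "mirX", chrom = "1",
                              start = 137500, end = 137600))
  expect_lte(sum(res0$shared), 1)
})
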