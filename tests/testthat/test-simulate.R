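test_that("genotype simulation is seed-deterministic and respects MAF range", {
  a <- simulate_genotypes(200, 50, seed = 11)
  b <- simulate_genotypes(200, 50, seed = 11)
  expect_identical(a$dosage, b$dosage)
  expect_identical(a$snps, b$snps)
  c <- simulate_genotypes(200, 50, seed = 12)
  expect_false(identical(a$dosage, c$dosage))
  expect_true(all(a$snps$maf > 0 & a$snps$maf <= 0.5))
  # stored maf always equals the dosage-derived maf
  f <- colMeans(a$dosage) / 2
  expect_equal(a$snps$maf, unname(pmin(f, 1 - f)), tolerance = 1e-12)
  expect_error(simulate_genotypes(1, 10), "n_samples")
})

test_that("independent SNPs show near-zero LD and blocks carry planted LD", {
  p0 <- simulate_genotypes(2000, 100, within_block_r = 0, seed = 21)
  R2 <- cor(p0$dosage)^2
  off <- R2[upper.tri(R2)]
  # E[r^2] under independence is ~ 1/(n-1); allow 3 SE of the mean
  expect_lt(abs(mean(off) - 1 / 1999), 3 * sd(off) / sqrt(length(off)))

  # empirical within/between-block r^2 over replicate blocks as oracle
  wb <- c(); bb <- c()
  for (s in 1:20) {
    p <- simulate_genotypes(500, 20, block_size = 10, within_block_r = 0.9,
                            seed = 100 + s)
    R2 <- cor(p$dosage)^2
    blk <- rep(1:2, each = 10)
    wb <- c(wb, R2[outer(blk, blk, "==") & upper.tri(R2)])
    bb <- c(bb, R2[outer(blk, blk, "!=") & upper.tri(R2)])
  }
  expect_gte(median(wb), 0.6)
  expect_lte(median(wb), 0.9)
  expect_lt(median(bb), 0.05)
})

test_that("count simulation calibrates planted variance and nulls are null", {
  p <- simulate_genotypes(604, 40, seed = 31)
  tr <- sim_truth(data.frame(feature = c("m1", "m2"),
                             snp = p$snps$snp[c(5, 25)],
                             var_frac = c(0.04, 0.1)))
  sim <- simulate_mirna_counts(p, tr, n_features = 30, seed = 32)
  cm <- sim$truth$causal_map
  expect_lt(max(abs(cm$realized_var_frac - cm$var_frac)), 0.02)
  expect_true(all(is.finite(cm$beta)))

  # beta = 0 everywhere: per-pair regression p-values calibrated at 0.05
  p_ind <- simulate_genotypes(604, 40, within_block_r = 0, seed = 34)
  tr0 <- sim_truth(data.frame(feature = paste0("m", 1:20),
                              snp = p_ind$snps$snp[1:20], var_frac = 0))
  sim0 <- simulate_mirna_counts(p_ind, tr0, seed = 33)
  em <- normalize_log2(sim0$expr)
  pv <- c()
  for (f in rownames(em$values)) for (j in seq_len(40))
    pv <- c(pv, summary(lm(em$values[f, ] ~ p_ind$dosage[, j]))$coef[2, 4])
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.02)

  # requested fractions summing to >= 1 are rejected
  bad <- sim_truth(data.frame(feature = "m", snp = p$snps$snp[1:2],
                              var_frac = c(0.6, 0.5)))
  expect_error(simulate_mirna_counts(p, bad, seed = 1), "sum")
})

test_that("dispersion -> 0 approaches Poisson counts", {
  p <- simulate_genotypes(2000, 5, seed = 41)
  tr <- sim_truth(data.frame(feature = "m1", snp = p$snps$snp[1],
                             var_frac = 0))
  sim <- simulate_mirna_counts(p, tr, n_features = 3, dispersion = 0,
                               libsize_range = c(2e7, 2e7),
                               batch_sd = 0, factor_sd = 0, noise_sd = 0,
                               base_range = c(5, 5), seed = 42)
  vm <- apply(sim$expr$values, 1, function(x) var(x) / mean(x))
  expect_equal(unname(vm), rep(1, 3), tolerance = 0.1)
})

test_that("GWAS summary scenarios carry the intended signal structure", {
  p <- simulate_genotypes(604, 60, seed = 51)
  tr <- sim_truth(data.frame(feature = "m1", snp = p$snps$snp[25],
                             var_frac = 0.05),
                  mediation_map = data.frame(trait = "T", feature = "m1",
                                             effect = -0.3))
  # Monte-Carlo null distribution: max |z| rarely exceeds 4.9
  exceed <- vapply(1:1000, function(s)
    max(abs(simulate_gwas_summary(p, tr, "null", seed = s)$z)) > 4.9,
    logical(1))
  expect_lt(mean(exceed), 0.01)

  # sign propagation: negative mediation flips the GWAS z at the causal SNP
  sim <- simulate_mirna_counts(p, tr, n_features = 5, seed = 52)
  g <- simulate_gwas_summary(p, sim$truth, "mediated", n_gwas = 50000,
                             seed = 53)
  zc <- g$z[g$snp == p$snps$snp[25]]
  expect_true(sign(zc) == -sign(sim$truth$causal_map$beta[1]))

  # |z| at the causal SNP grows as sqrt(n_gwas)
  ns <- c(1e4, 4e4, 1.6e5, 6.4e5)
  zs <- vapply(ns, function(n) {
    mean(vapply(1:20, function(s)
      abs(simulate_gwas_summary(p, sim$truth, "mediated", n_gwas = n,
                                seed = 1000 + s)$z[25]), numeric(1)))
  }, numeric(1))
  slope_fit <- lm(zs ~ 0 + sqrt(ns))
  expect_gt(summary(slope_fit)$r.squared, 0.99)

  # linkage without an eligible partner SNP is rejected
  p_ind <- simulate_genotypes(604, 10, within_block_r = 0, seed = 54)
  tr2 <- sim_truth(data.frame(feature = "m1", snp = p_ind$snps$snp[1],
                              var_frac = 0.05))
  expect_error(
    simulate_gwas_summary(p_ind, tr2, "linkage",
                          linkage_r2 = c(0.8, 0.95), seed = 1),
    "no SNP")
})

test_that("annotation simulation plants a stratum-constant odds ratio", {
  set.seed(60)
  snps <- data.frame(snp = sprintf("rs%05d", 1:20000), chrom = "1",
                     pos = seq(1e5, by = 100, length.out = 20000),
                     maf = runif(20000, 0.01, 0.5))
  qtl <- sample(snps$snp, 4000)
  # null odds ratio
  ann0 <- simulate_annotations(snps, qtl, target_or = 1, seed = 61)
  flags0 <- overlap_flags(snps, ann0$intervals)
  t0 <- stratified_tables(snps$snp %in% qtl, flags0, snps$maf)
  r0 <- cmh_test(t0)
  expect_equal(r0$or, 1, tolerance = 0.12)
  expect_gt(r0$p, 0.001)
  # planted enrichment recovered through the interval representation
  ann <- simulate_annotations(snps, qtl, target_or = 1.3, seed = 62)
  flags <- overlap_flags(snps, ann$intervals)
  expect_identical(flags, ann$member)
  r <- cmh_test(stratified_tables(snps$snp %in% qtl, flags, snps$maf))
  expect_gt(r$or, 1.1)
  expect_lt(r$p, 0.05)
  expect_error(simulate_annotations(snps, character(0), 1.3), "non-empty")
})
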