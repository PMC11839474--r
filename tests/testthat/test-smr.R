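test_that("SMR statistic follows its closed form", {
  # z_zx = z_zy = 4: T = 16*16/32 = 8, p = P(chi2(1) > 8)
  r <- smr_test(b_zx = 0.4, se_zx = 0.1, b_zy = 0.08, se_zy = 0.02)
  expect_equal(r$T_smr, 8, tolerance = 1e-12)
  expect_equal(r$p, pchisq(8, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$b_xy, 0.2)
  # no outcome signal: T = 0, p = 1
  r0 <- smr_test(0.4, 0.1, 0, 0.02)
  expect_equal(r0$T_smr, 0)
  expect_equal(r0$p, 1)
  expect_error(smr_test(0, 0.1, 0.1, 0.1), "instrument")

  # symmetry in (z_zx, z_zy) and bound by min(z^2)
  set.seed(29)
  for (i in 1:50) {
    bzx <- rnorm(1); bzy <- rnorm(1)
    sx <- runif(1, 0.05, 0.3); sy <- runif(1, 0.05, 0.3)
    if (abs(bzx) < 1e-3 || abs(bzy) < 1e-3) next
    a <- smr_test(bzx, sx, bzy, sy)
    b <- smr_test(bzy, sy, bzx, sx)
    expect_equal(a$T_smr, b$T_smr, tolerance = 1e-10)
    expect_lte(a$T_smr, min((bzx / sx)^2, (bzy / sy)^2) + 1e-10)
    # flipping the SNP's effect allele flips both b's, leaves b_xy fixed
    f <- smr_test(-bzx, sx, -bzy, sy)
    expect_equal(f$b_xy, a$b_xy, tolerance = 1e-12)
  }
})

test_that("mediated simulations recover the causal effect b_xy", {
  est <- c()
  for (s in 1:60) {
    p <- simulate_genotypes(604, 60, seed = 5000 + s)
    tr <- sim_truth(data.frame(feature = "m", snp = p$snps$snp[25],
                               var_frac = 0.1),
                    mediation_map = data.frame(trait = "T", feature = "m",
                                               effect = -0.3))
    sim <- simulate_mirna_counts(p, tr, n_features = 20, seed = 5100 + s)
    em <- normalize_log2(sim$expr)
    covars <- cbind(stats::model.matrix(~ batch, sim$covariates),
                    sim$factors)
    y <- em$values["m", ]
    yr <- residualize(y, covars)
    yr <- yr / sd(yr)  # SD units to match the GWAS effect scale
    d <- p$dosage[, p$snps$snp[25]]
    fit <- summary(lm(yr ~ d))
    g <- simulate_gwas_summary(p, sim$truth, "mediated", n_gwas = 50000,
                               seed = 5200 + s)
    gi <- which(g$snp == p$snps$snp[25])
    r <- smr_test(fit$coef[2, 1], fit$coef[2, 2], g$beta[gi], g$se[gi])
    est <- c(est, r$b_xy)
  }
  expect_gte(mean(est), -0.35)
  expect_lte(mean(est), -0.25)
})

test_that("HEIDI is calibrated under one shared variant and powered under linkage", {
  shared <- vapply(1:100, function(s) heidi_replicate(s, "mediated"),
                   numeric(1))
  linked <- vapply(1:60, function(s) heidi_replicate(s, "linkage"),
                   numeric(1))
  expect_lt(abs(mean(shared < 0.05, na.rm = TRUE) - 0.05), 0.05)
  expect_gte(mean(linked < 0.05, na.rm = TRUE), 0.5)
})

test_that("HEIDI edge cases: too few SNPs and exact homogeneity", {
  m <- 10
  R <- diag(m); R[R == 0] <- 0.3
  colnames(R) <- rownames(R) <- paste0("rs", 1:m)
  ex <- data.frame(snp = paste0("rs", 1:m), beta = rep(0.5, m),
                   se = rep(0.05, m), p = rep(1e-20, m))
  # noise-free proportional outcome: all b_xy identical -> p ~ 1
  out <- data.frame(snp = paste0("rs", 1:m), beta = rep(0.25, m),
                    se = rep(0.05, m))
  h <- heidi_test(ex, out, R, "rs1", r2_range = c(0.05, 0.95))
  expect_gt(h$p_heidi, 0.99)
  # fewer than 3 eligible partners: missing with reason
  ex2 <- ex[1:3, ]
  h2 <- heidi_test(ex2, out[1:3, ], R[1:3, 1:3], "rs1",
                   r2_range = c(0.05, 0.95))
  expect_true(is.na(h2$p_heidi))
  expect_match(h2$reason, "eligible")
})

test_that("two-molecular-trait SMR attaches the mediation verdict", {
  # outcome = exposure: b_xy = 1 exactly
  m <- 12
  set.seed(31)
  R <- cov2cor(crossprod(matrix(rnorm(40 * m), 40)))
  colnames(R) <- rownames(R) <- paste0("rs", 1:m)
  ex <- data.frame(snp = paste0("rs", 1:m), beta = rnorm(m, 0, 0.4),
                   se = runif(m, 0.04, 0.08))
  ex$p <- 2 * pnorm(-abs(ex$beta / ex$se))
  r <- suppressWarnings(smr_two_molecular(ex, ex, R))
  expect_equal(r$b_xy, 1)

  # planted mediation with negative coupling is detected
  hit <- 0; null_ok <- 0
  for (s in 1:50) {
    p <- simulate_genotypes(604, 60, block_size = 10, within_block_r = 0.8,
                            seed = 9000 + s)
    tr <- sim_truth(data.frame(feature = "m", snp = p$snps$snp[25],
                               var_frac = 0.1),
                    mediation_map = data.frame(trait = "host", feature = "m",
                                               effect = -0.4))
    sim <- simulate_mirna_counts(p, tr, n_features = 15, seed = 9100 + s)
    em <- normalize_log2(sim$expr)
    covars <- cbind(stats::model.matrix(~ batch, sim$covariates),
                    sim$factors)
    win <- data.frame(mature_id = "m", chrom = "1", start = 1L, end = 1e6)
    suppressWarnings(qtl <- scan_cis(p, em, covars, win))
    exposure <- qtl[, c("snp", "beta", "se", "p")]
    # "eQTL of the host" under shared causal variant: mediated scenario
    g_sh <- simulate_gwas_summary(p, sim$truth, "mediated", n_gwas = 30000,
                                  seed = 9200 + s)
    r_sh <- suppressWarnings(
      smr_two_molecular(exposure, g_sh[, c("snp", "beta", "se")],
                        ld_matrix(p), instrument_p_max = 1e-4))
    if (isTRUE(r_sh$mediation)) hit <- hit + 1
    # independent regulation: distinct causal variants in low LD
    g_di <- simulate_gwas_summary(p, sim$truth, "linkage", n_gwas = 30000,
                                  linkage_r2 = c(0, 0.2),
                                  direct_effect = 0.04, seed = 9300 + s)
    r_di <- suppressWarnings(
      smr_two_molecular(exposure, g_di[, c("snp", "beta", "se")],
                        ld_matrix(p), instrument_p_max = 1e-4))
    if (!isTRUE(r_di$mediation)) null_ok <- null_ok + 1
  }
  expect_gte(hit / 50, 0.8)
  expect_gte(null_ok / 50, 0.9)
})
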