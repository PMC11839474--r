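#' Simulate one complete miR-QTL study and scan it
#'
#' Convenience harness tying the generator to the scan: simulates an
#' LD-structured panel, plants cis effects of the requested variance
#' fractions, normalizes counts, builds windows and runs the covariate-
#' adjusted scan (batch + the hidden-factor scores standing in for estimated
#' surrogate variables).
#'
#' @param seed integer master seed (stage seeds are derived from it).
#' @param n_samples,n_snps,block_size,within_block_r panel dimensions and LD
#'   structure.
#' @param n_features number of miRNAs; \code{n_causal} of them carry one
#'   planted cis-QTL each.
#' @param n_causal number of causal features.
#' @param var_frac planted variance fraction(s), recycled over causal
#'   features.
#' @param mediation optional mediation_map passed to \code{\link{sim_truth}}.
#' @return list: panel, truth, expr (log2-CPM), covars, windows, records
#'   (the scan output), factors.
#' @export
simulate_study <- function(seed, n_samples = 604, n_snps = 100,
                           block_size = 10, within_block_r = 0.8,
                           n_features = 250, n_causal = 100,
                           var_frac = 0.04, mediation = NULL) {
  panel <- simulate_genotypes(n_samples, n_snps, block_size = block_size,
                              within_block_r = within_block_r, seed = seed)
  causal <- with_seed(derive_seed(seed, 7), {
    data.frame(feature = sprintf("mir-%03d", seq_len(n_causal)),
               snp = panel$snps$snp[sample.int(n_snps, n_causal,
                                               replace = TRUE)],
               var_frac = rep_len(var_frac, n_causal),
               stringsAsFactors = FALSE)
  })
  truth <- sim_truth(causal, mediation_map = mediation, seed = seed)
  sim <- simulate_mirna_counts(panel, truth, n_features = n_features,
                               seed = derive_seed(seed, 11))
  em <- normalize_log2(sim$expr)
  covars <- cbind(stats::model.matrix(~ batch, sim$covariates),
                  sim$factors)
  colnames(covars)[ncol(covars) - 2:0] <- paste0("F", 1:3)
  rownames(covars) <- sim$covariates$sample
  windows <- build_cis_windows(
    data.frame(mature_id = rownames(em$values),
               precursor_id = rownames(em$values),
               chrom = panel$snps$chrom[1], start = 170000L, end = 170100L,
               strand = "+", stringsAsFactors = FALSE))
  records <- suppressWarnings(scan_cis(panel, em, covars, windows))
  list(panel = panel, truth = sim$truth, expr = em, covars = covars,
       windows = windows, records = records, factors = sim$factors)
}

#' One replicate of the synthetic four-criteria causal screen
#'
#' Simulates a single-miRNA locus with a planted cis-QTL, a GWAS trait under
#' the requested scenario, and runs the full screen: cis scan, heritability
#' gate, weight-model fit, TWAS association, colocalization, SMR and HEIDI,
#' then the four-criteria conjunction.
#'
#' @param seed integer replicate seed.
#' @param scenario "mediated", "linkage" or "null".
#' @param var_frac planted cis variance fraction (default 0.1, a strong
#'   QTL of the kind that survives all four criteria).
#' @param mediation_effect per-SD trait effect of the miRNA (mediated
#'   scenario).
#' @param direct_effect standardized trait effect at the decoy SNP
#'   (linkage scenario); the default models a genome-wide-significant locus.
#' @param n_gwas GWAS sample size.
#' @return list with the screen verdict (\code{causal}), its components, and
#'   \code{gated} (TRUE when the heritability/weight gates excluded the
#'   miRNA, in which case \code{causal} is FALSE).
#' @export
screen_replicate <- function(seed, scenario = c("mediated", "linkage",
                                                "null"),
                             var_frac = 0.1, mediation_effect = 0.35,
                             direct_effect = 0.08, n_gwas = 50000) {
  scenario <- match.arg(scenario)
  # within_block_r = 0.7 puts the linkage decoy at r^2 ~ 0.5 with the
  # exposure SNP, the canonical two-causal-SNP linkage configuration
  panel <- simulate_genotypes(604, 60, block_size = 10,
                              within_block_r = 0.7,
                              seed = derive_seed(seed, 1))
  truth <- sim_truth(
    data.frame(feature = "m", snp = panel$snps$snp[25],
               var_frac = var_frac),
    mediation_map = data.frame(trait = "T", feature = "m",
                               effect = mediation_effect))
  sim <- simulate_mirna_counts(panel, truth, n_features = 15,
                               seed = derive_seed(seed, 2))
  em <- normalize_log2(sim$expr)
  covars <- cbind(stats::model.matrix(~ batch, sim$covariates),
                  sim$factors)
  win <- data.frame(mature_id = "m", chrom = "1", start = 1L, end = 1e6)
  qtl <- suppressWarnings(scan_cis(panel, em, covars, win))
  yr <- residualize(em$values["m", ], covars)
  h2 <- estimate_cis_h2(panel$dosage, yr)
  if (h2$p >= 0.01)
    return(list(causal = FALSE, gated = TRUE, reason = "h2 gate"))
  model <- fit_weight_models(panel$dosage, yr,
                             seed = derive_seed(seed, 3),
                             h2 = h2$h2, h2_p = h2$p)
  if (model$model == "none")
    return(list(causal = FALSE, gated = TRUE, reason = "no model"))
  g <- simulate_gwas_summary(panel, sim$truth, scenario, n_gwas = n_gwas,
                             direct_effect = direct_effect,
                             linkage_r2 = c(0.3, 0.9),
                             seed = derive_seed(seed, 4))
  R <- ld_matrix(panel)
  tw <- twas_associate(model, g, R)
  cr <- coloc_abf(qtl[, c("snp", "beta", "se")],
                  g[, c("snp", "beta", "se")])
  smr <- suppressWarnings(
    smr_two_molecular(qtl[, c("snp", "beta", "se", "p")],
                      g[, c("snp", "beta", "se")], R,
                      instrument_p_max = 1e-4))
  out <- causal_screen(
    data.frame(mirna = "m", trait = "T", z = tw$z, p = tw$p, fdr = tw$p),
    data.frame(mirna = "m", trait = "T", pp4 = cr$pp4),
    data.frame(mirna = "m", trait = "T", p_smr = smr$p_smr,
               p_heidi = smr$p_heidi))
  list(causal = out$causal[1], gated = FALSE, z = tw$z, pp4 = cr$pp4,
       p_smr = smr$p_smr, p_heidi = smr$p_heidi, reason = out$reason[1])
}

#' One replicate of the HEIDI calibration/power simulation
#'
#' Simulates a strong single-miRNA cis locus and a GWAS trait that either
#' shares the causal variant (mediated; HEIDI's null of homogeneity) or is
#' driven by a distinct correlated SNP (linkage), and returns the HEIDI
#' p-value over the locus.
#'
#' @param seed integer replicate seed.
#' @param scenario "mediated" or "linkage".
#' @return HEIDI p-value (NA when fewer than 3 eligible SNPs).
#' @export
heidi_replicate <- function(seed, scenario = c("mediated", "linkage")) {
  scenario <- match.arg(scenario)
  panel <- simulate_genotypes(604, 60, block_size = 20,
                              within_block_r = 0.8,
                              seed = derive_seed(seed, 1))
  truth <- sim_truth(
    data.frame(feature = "m", snp = panel$snps$snp[30], var_frac = 0.15),
    mediation_map = data.frame(trait = "T", feature = "m", effect = 0.4))
  sim <- simulate_mirna_counts(panel, truth, n_features = 15,
                               seed = derive_seed(seed, 2))
  em <- normalize_log2(sim$expr)
  covars <- cbind(stats::model.matrix(~ batch, sim$covariates),
                  sim$factors)
  win <- data.frame(mature_id = "m", chrom = "1", start = 1L, end = 1e6)
  qtl <- suppressWarnings(scan_cis(panel, em, covars, win))
  exposure <- qtl[, c("snp", "beta", "se", "p")]
  g <- simulate_gwas_summary(panel, sim$truth, scenario, n_gwas = 50000,
                             direct_effect = 0.06,
                             linkage_r2 = c(0.3, 0.9),
                             seed = derive_seed(seed, 3))
  top <- exposure$snp[which.min(exposure$p)]
  heidi_test(exposure, g[, c("snp", "beta", "se")], ld_matrix(panel),
             top)$p_heidi
}
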