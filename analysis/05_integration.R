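#!/usr/bin/env Rscript

# Stage 5: colocalization and SMR/HEIDI against a simulated GWAS trait.
#
# For one strong planted miRNA locus, simulates GWAS summary statistics
# under the mediated (shared causal variant) and linkage (distinct causal
# variant) scenarios, then runs single-causal-variant colocalization and the
# SMR + HEIDI mediation test on each.

suppressMessages(library(mirqtl))

dat <- "results/data"; qtl <- "results/qtl"
out <- "results/integration"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- read_genotypes(file.path(dat, "genotypes.vcf"))
recs <- read_tsv(file.path(qtl, "cis_qtl_summary.tsv"))
truth <- read_tsv(file.path(dat, "truth_causal_map.tsv"))

# strongest planted miRNA locus
best <- truth$feature[which.max(truth$realized_var_frac)]
exposure <- recs[recs$mirna == best, c("snp", "beta", "se", "p")]
tr <- sim_truth(truth[truth$feature == best, c("feature", "snp", "var_frac")],
                mediation_map = data.frame(trait = "trait", feature = best,
                                           effect = 0.35))
R <- ld_matrix(panel, exposure$snp)

rows <- list()
for (scen in c("mediated", "linkage")) {
  g <- simulate_gwas_summary(panel, tr, scen, n_gwas = 50000,
                             direct_effect = 0.08, seed = 20240605L)
  g <- g[match(exposure$snp, g$snp), ]
  cc <- coloc_abf(exposure, g[, c("snp", "beta", "se")])
  sm <- smr_two_molecular(exposure, g[, c("snp", "beta", "se")], R,
                          instrument_p_max = 1e-4)
  rows[[scen]] <- data.frame(scenario = scen, mirna = best,
                             pp3 = cc$pp3, pp4 = cc$pp4,
                             b_xy = sm$b_xy, p_smr = sm$p_smr,
                             p_heidi = sm$p_heidi,
                             mediation = sm$mediation)
}
tab <- do.call(rbind, rows)
write_tsv(tab, file.path(out, "coloc_smr.tsv"))
print(tab, row.names = FALSE)
cat("\nUnder the shared-causal-variant scenario the locus colocalizes",
    "(high PP4) and the SMR/HEIDI verdict is mediation. A linkage decoy",
    "in strong LD with the miR-QTL can still fool a single locus (PP4 and",
    "HEIDI are then borderline); the replicate suites of stage 6 quantify",
    "how often.\n")
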