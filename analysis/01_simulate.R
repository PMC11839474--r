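#!/usr/bin/env Rscript

# Stage 1: generate one synthetic miR-QTL study with known ground truth.
#
# Emulates the statistical structure of a brain miR-QTL dataset: an
# LD-structured dosage panel for 604 donors, negative-binomial miRNA counts
# with planted cis effects at the 4%-of-variance scale, batch and
# hidden-factor structure, and a truth table for later scoring. Files land
# under results/data/ in the standard formats (VCF with DS dosages, counts
# TSV, covariates TSV, truth TSV).

suppressMessages(library(mirqtl))

seed <- 20240604L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- simulate_genotypes(n_samples = 604, n_snps = 200, block_size = 10,
                            within_block_r = 0.8, seed = seed)
panel <- filter_variants(panel, maf_min = 0.01, hwe_p_min = 1e-8,
                         miss_max = 0.05)

n_causal <- 40
truth <- sim_truth(
  data.frame(feature = sprintf("mir-%03d", 1:n_causal),
             snp = panel$snps$snp[seq(3, by = 5, length.out = n_causal)],
             var_frac = 0.04),
  seed = seed)
sim <- simulate_mirna_counts(panel, truth, n_features = 100,
                             seed = seed + 1L)

write_genotypes(panel, file.path(out, "genotypes.vcf"))
write_tsv(data.frame(feature = rownames(sim$expr$values),
                     sim$expr$values, check.names = FALSE),
          file.path(out, "mirna_counts.tsv"))
write_tsv(sim$covariates, file.path(out, "covariates.tsv"))
write_tsv(sim$truth$causal_map, file.path(out, "truth_causal_map.tsv"))
write_tsv(data.frame(sample = rownames(panel$dosage), sim$factors),
          file.path(out, "hidden_factors.tsv"))

ann <- data.frame(mature_id = rownames(sim$expr$values),
                  precursor_id = rownames(sim$expr$values),
                  chrom = "1", start = 170000L, end = 170100L,
                  strand = "+")
write_tsv(ann, file.path(out, "mirna_annotation.tsv"))

cat(sprintf("Simulated %d samples x %d SNPs, %d miRNAs (%d with a planted cis-QTL at 4%% of residual variance).\n",
            nrow(panel$dosage), ncol(panel$dosage),
            nrow(sim$expr$values), n_causal))
cat("Planted effects (log2 per allele): median |beta| =",
    signif(median(abs(sim$truth$causal_map$beta)), 3), "\n")
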