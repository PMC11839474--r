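#!/usr/bin/env Rscript

# Stage 3: cis-QTL scan.
#
# Tests every SNP within 500 kb of each miRNA precursor for an additive
# effect of allele dosage on normalized abundance, adjusting for batch and
# the surrogate variables, and attaches Storey q-values computed from all
# tests.

suppressMessages(library(mirqtl))

dat <- "results/data"; qc <- "results/qc"
out <- "results/qtl"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- read_genotypes(file.path(dat, "genotypes.vcf"))
lg_df <- read_tsv(file.path(qc, "log2cpm.tsv"))
lg <- as.matrix(lg_df[, -1]); rownames(lg) <- lg_df$feature
em <- expression_matrix(lg, tag = "log2cpm")
covars <- read_tsv(file.path(dat, "covariates.tsv"))
sv <- read_tsv(file.path(qc, "svs.tsv"))

X <- cbind(stats::model.matrix(~ batch, covars), as.matrix(sv[, -1]))
rownames(X) <- covars$sample

ann <- read_mirna_annotation(file.path(dat, "mirna_annotation.tsv"))
windows <- build_cis_windows(ann[ann$mature_id %in% rownames(lg), ],
                             pad = 500000L)
recs <- scan_cis(panel, em, X, windows)
write_tsv(recs, file.path(out, "cis_qtl_summary.tsv"))

sig <- recs[recs$q < 0.01, ]
emirs <- unique(sig$mirna)
cat(sprintf("Tested %d SNP-miRNA pairs; %d significant at q < 0.01 (pi0 = %.3f).\n",
            nrow(recs), nrow(sig), attr(recs, "pi0")))
cat(sprintf("eMiRs (miRNAs with at least one miR-QTL): %d of %d tested (%.0f%%).\n",
            length(emirs), length(unique(recs$mirna)),
            100 * length(emirs) / length(unique(recs$mirna))))
truth <- read_tsv(file.path(dat, "truth_causal_map.tsv"))
hit <- paste(truth$feature, truth$snp) %in% paste(sig$mirna, sig$snp)
cat(sprintf("Planted truth pairs recovered at q < 0.01: %d of %d.\n",
            sum(hit), nrow(truth)))
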