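#!/usr/bin/env Rscript

# Stage 2: expression quality control.
#
# Reads the raw counts from stage 1, applies the abundance filter (>= 1 RPM
# in >= 50% of samples), deduplicates multi-precursor entries, normalizes by
# TMM/log2-CPM, removes PCA outlier samples, and estimates surrogate
# variables from the residual expression.

suppressMessages(library(mirqtl))

dat <- "results/data"
out <- "results/qc"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

counts_df <- read_tsv(file.path(dat, "mirna_counts.tsv"))
counts <- as.matrix(counts_df[, -1])
rownames(counts) <- counts_df$feature
ann <- read_mirna_annotation(file.path(dat, "mirna_annotation.tsv"))
covars <- read_tsv(file.path(dat, "covariates.tsv"))

em <- expression_matrix(counts, tag = "counts",
                        features = data.frame(
                          mature_id = rownames(counts),
                          precursor_id = rownames(counts)))
em <- filter_low_expression(em)
em <- dedup_multi_precursor(em)
cat(sprintf("Abundance filter retained %d miRNAs.\n", nrow(em$values)))

lg <- normalize_log2(em)
keep <- remove_outlier_samples(lg, "pca")
cat(sprintf("PCA outlier pass removed %d of %d samples.\n",
            length(keep$removed), ncol(lg$values)))
lg$values <- lg$values[, keep$retained, drop = FALSE]
covars <- covars[match(keep$retained, covars$sample), ]

X <- stats::model.matrix(~ batch, covars)
sv <- estimate_surrogate_variables(lg, X, n_sv = 5)
write_tsv(data.frame(sample = rownames(sv), sv), file.path(out, "svs.tsv"))
write_tsv(data.frame(feature = rownames(lg$values), lg$values,
                     check.names = FALSE),
          file.path(out, "log2cpm.tsv"))
writeLines(keep$retained, file.path(out, "retained_samples.txt"))
cat(sprintf("Estimated %d surrogate variables; normalized matrix written.\n",
            ncol(sv)))
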