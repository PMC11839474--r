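#!/usr/bin/env Rscript

# Stage 6: the four-criteria causal-miRNA screen, evaluated over replicate
# synthetic trait suites.
#
# Each replicate simulates a miRNA locus with a strong planted cis-QTL and a
# GWAS trait that is either mediated by the miRNA, driven by a distinct SNP
# in LD (linkage decoy), or null, then applies the full screen: miRWAS
# FDR < 0.05, coloc PP.H4 > 0.5, SMR p < 0.05, HEIDI p >= 0.05.

suppressMessages(library(mirqtl))

out <- "results/screen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
reps <- 50  # per scenario; a reduced-size rendering of the evaluation suite

rates <- vapply(c("mediated", "linkage", "null"), function(scen) {
  mean(vapply(seq_len(reps), function(s)
    isTRUE(screen_replicate(10 * s + 3, scen)$causal), logical(1)))
}, numeric(1))

tab <- data.frame(scenario = names(rates), flagged_causal = rates,
                  n = reps)
write_tsv(tab, file.path(out, "screen_rates.tsv"))
print(tab, row.names = FALSE)
cat("\nPlanted mediators should be flagged causal in >= 80% of replicates;",
    "linkage decoys in <= 10%; null traits essentially never.\n")
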