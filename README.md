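# mirqtl

Mapping microRNA expression quantitative trait loci (miR-QTLs) and
integrating them with GWAS and multi-omic data.

## The problem

MicroRNAs repress gene expression post-transcriptionally, and common genetic
variants that shift a miRNA's abundance (miR-QTLs) are a mechanistic bridge
between GWAS risk loci and the genes the miRNA regulates. A brain miR-QTL
study asks, in order: which miRNAs have cis genetic regulation; how many
independent signals each has and how large they are; whether intragenic
miRNAs are co-regulated with their host genes; whether miR-QTLs are enriched
in promoters and enhancers and shared across tissues; and — by combining
miR-QTLs with GWAS summary statistics — which miRNAs are consistent with a
*causal* role in a disorder. `mirqtl` implements that full pipeline for
people who work with QTL and TWAS-style analyses, together with a seeded
synthetic-data generator that reproduces the statistical structure the
pipeline assumes, so every stage can be calibrated and scored against known
ground truth without access-controlled genotypes.

## The statistics at the core

- **cis scan**: for each SNP within 500 kb of a precursor, OLS of normalized
  abundance on allele dosage plus covariates (batch, clinical covariates,
  genetic PCs, surrogate variables); two-sided t test on the dosage
  coefficient; Storey q-values (pi0 by df = 3 spline on the lambda grid)
  with miR-QTLs declared at q < 0.01.
- **independent signals**: greedy LD clumping (absorb r² ≥ 0.5 within
  250 kb) to index SNPs, then stepwise conditional analysis re-testing index
  SNPs with the selected set as covariates.
- **colocalization**: single-causal-variant Bayes factors,
  lABF = ½log(1−r) + z²r/2 with r = W/(se²+W), priors p1 = p2 = 1e-4,
  p12 = 1e-5; shared causal variant declared at PP.H4 > 0.5.
- **SMR / HEIDI**: b_xy = b_zy/b_zx at the top instrument,
  T = z_zx²z_zy²/(z_zx²+z_zy²) ~ χ²(1); HEIDI tests homogeneity of per-SNP
  b_xy across the locus against the LD-implied covariance (Satterthwaite
  two-moment reference); mediation = SMR p < 0.05 and HEIDI p ≥ 0.05.
- **miRWAS**: cis-h² by single-component REML with a boundary-mixture LRT
  gate (p < 0.01); expression weights from {top1, lasso, elastic net} by
  cross-validated R²; association z = w'z_gwas/√(w'Rw); a miRNA is flagged
  causal for a trait when miRWAS FDR < 0.05, PP.H4 > 0.5, SMR p < 0.05 and
  HEIDI p ≥ 0.05 all hold.
- **enrichment & sharing**: Cochran–Mantel–Haenszel common OR over three MAF
  strata with RBG confidence intervals; cross-study eMiR sharing by Yates-
  corrected chi-squared on the reconstructed 2×2 table; Storey pi1 for
  replication; strand-aware positional statistics with an exact two-sided
  binomial test.

## Worked example

The `analysis/` directory is a numbered workflow over the package functions;
each stage reads the previous stage's outputs from `results/`. Stages 1–3
simulate a study (604 samples, 200 SNPs, 100 miRNAs of which 40 carry one
planted cis-QTL at 4% of residual variance), run expression QC, and scan:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc.R
Rscript analysis/03_scan_cis.R
```

```
Simulated 604 samples x 200 SNPs, 100 miRNAs (40 with a planted cis-QTL at 4% of residual variance).
Abundance filter retained 100 miRNAs.
Estimated 5 surrogate variables; normalized matrix written.
Tested 20000 SNP-miRNA pairs; 248 significant at q < 0.01 (pi0 = 0.965).
eMiRs (miRNAs with at least one miR-QTL): 39 of 100 tested (39%).
Planted truth pairs recovered at q < 0.01: 38 of 40.
```

38 of the 40 planted SNP–miRNA pairs reach q < 0.01 and one null miRNA is
called (a 4%-variance effect at n = 604 is comfortably detectable; the
two misses are planted pairs whose count noise fell unfavorably). Stage 4
reduces the significant set to index and conditionally independent QTLs:

```
39 index miR-QTLs across 39 eMiRs.
Median variance explained per conditionally independent miR-QTL: 3.9%.
```

The recovered median effect (3.9% of residual variance) matches the planted
4%. Stages 5–7 run colocalization + SMR/HEIDI on a simulated GWAS trait,
replicate the four-criteria causal screen, and compute enrichment/sharing
statistics:

```
 scenario flagged_causal  n
 mediated           1.00 50
  linkage           0.02 50
     null           0.00 50
Blood: X2(1, n = 173) = 4.3, p = 0.038; 41% of our eMiRs shared.
Fetal neocortex: X2(1, n = 394) = 9.1, p = 0.0026; 74% of fetal eMiRs shared.
CMH common OR = 1.32 (95% CI 1.29-1.36), p = 5.4e-109 over 350000 SNPs in 3 MAF strata.
```

Planted mediator miRNAs are flagged causal in every replicate while linkage
decoys (a distinct causal SNP at r² ≈ 0.5) pass in 2% and null traits never;
the sharing chi-squared values are computed from the published counts of the
whole-blood and fetal-neocortex comparisons; the CMH odds ratio recovers the
planted stratum-constant enrichment of 1.3.

See `vignettes/mirqtl-methods.Rmd` for the models, parameter choices,
generator assumptions and known limitations.

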