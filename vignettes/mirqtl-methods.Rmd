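---
title: "miR-QTL mapping and multi-omic integration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miR-QTL mapping and multi-omic integration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package does

`mirqtl` implements a complete microRNA expression quantitative trait locus
(miR-QTL) analysis: from raw small-RNA count matrices through cis-QTL
scanning, LD clumping and conditional analysis, Bayesian colocalization,
summary-based Mendelian randomization (SMR) with the HEIDI heterogeneity
test, a FUSION-style miRNA-wide association study (miRWAS), regulatory-region
enrichment and cross-study sharing statistics, ending in a four-criteria
screen for miRNAs consistent with a causal role in a complex trait. Because
genotype-level brain datasets of this kind are access-controlled, the package
pairs every stage with a seeded synthetic-data generator that reproduces the
statistical structure those stages assume, so the whole pipeline can be
exercised, calibrated and scored against known ground truth on a desk-scale
problem.

# The statistical pipeline

## Expression processing

Raw counts are filtered on abundance (kept when the feature reaches at least
1 read per million in at least half the samples, both thresholds inclusive);
mature miRNAs quantified from several precursors keep the entry with the
highest total count (ties broken by the lexicographically smallest precursor
id). Normalization is trimmed-mean-of-M-values (TMM) scaling followed by
log2 counts-per-million with a prior count of 0.5, via edgeR. One deliberate
departure from edgeR's default: the trimmed mean is **unweighted**. With
precision weighting, uniformly doubling one sample's counts shifts its
normalized values by a few thousandths of a log2 unit because the per-gene
weights do not cancel; the unweighted trimmed mean makes normalized values
exactly invariant to such rescaling, which we consider the defining property
of a library-size correction. Precision weighting remains available via
`normalize_log2(weighted = TRUE)`.

Outlier samples are removed either by batch-wise metrics (iteratively, 5 SD
within batch until stable) or by expression PCA (4 SD on either of the first
two components, single pass by default, with an iterate-until-stable option).
Hidden structure (cell-type composition and other unmeasured confounders) is
absorbed by surrogate variables computed as the top right singular vectors of
the covariate-residualized expression matrix ("PCA on residuals"). The
iteratively reweighted SVA algorithm adds nothing here because the variable
of interest used in the original pipeline was random noise, which makes its
reweighting step a no-op in expectation; residual SVD is deterministic and
recovers planted hidden factors with correlation above 0.9 in our tests.

## The cis scan

For every SNP within 500 kb of a miRNA precursor (windows merged across
precursors of the same mature miRNA so a SNP is tested once), expression is
regressed on allele dosage plus covariates; the dosage coefficient is tested
two-sided with the exact t reference on n − p degrees of freedom. The
implementation residualizes expression and dosage on the covariates once per
scan (Frisch–Waugh), which reproduces full-model coefficients exactly and
keeps the scan a handful of matrix products. Covariates are pruned by a
variance-inflation-factor bound (default 500) rather than by inflating
numerical tolerances. False discovery control uses Storey q-values: pi0 is
estimated on the lambda grid 0.05–0.95 with a cubic smoothing spline
(df = 3) evaluated at the largest lambda; below 100 p-values the estimator
falls back to pi0 = 1, i.e. Benjamini–Hochberg.

Per-QTL effect size is reported as the fraction of variance explained,
Var(beta·dosage)/Var(outcome), with the outcome pre-residualized for
non-genetic covariates and surrogate variables, matching the units in which
the field reports the median effect of a conditionally independent miR-QTL
(about 4% of expression variance).

## Clumping and conditional analysis

Significant miR-QTLs are reduced to index SNPs by greedy clumping: the
remaining SNP with the smallest p becomes an index and absorbs SNPs with
r² ≥ 0.5 **and** within 250 kb (PLINK's semantics of these two options —
stated in the literature as retention of SNPs with r² < 0.5 *or* separated
by 250 kb, which is the same rule read from the other side). Ties on p break
by smaller genomic position. Conditional analysis then re-tests index SNPs
(only index SNPs, matching the published procedure's wording) with the
growing independent set as covariates: while more than one remains
significant the best-ranked joins the set; when exactly one remains it joins
and the procedure stops. The conditional threshold defaults to the
unadjusted p cutoff that defined the q < 0.01 set in the same run.

## Colocalization

Single-causal-variant Bayesian colocalization with Wakefield approximate
Bayes factors: lABF = ½·log(1−r) + z²r/2 with r = W/(se² + W). Priors are
the standard p1 = p2 = 1e-4, p12 = 1e-5; W = (0.15)² in phenotype-SD units
for quantitative traits and (0.2)² on the log-odds scale for case-control
GWAS. Hypothesis sums run in log space (log-sum-exp); the H3 term is
computed as a stable log-difference and clamped at zero mass with a warning
if cancellation makes it numerically negative. The vectorized posteriors are
tested against brute-force enumeration of all causal configurations at
1e-10. The multiple-causal-variant (credible-set) extension is out of scope;
the single-variant branch is the documented fallback when no credible sets
exist.

## SMR and HEIDI

At the exposure's top SNP, b_xy = b_zy/b_zx with the SMR statistic
T = z_zx²·z_zy²/(z_zx² + z_zy²) referred to chi-squared(1) and a delta-method
standard error. HEIDI tests homogeneity of per-SNP b_xy estimates across the
locus: up to 20 SNPs with exposure p < 1.57e-3 and r² with the top SNP in
[0.05, 0.9] (the published defaults) contribute d_i = b_xy(i) − b_xy(top);
their covariance follows from LD and the per-SNP sampling variances, and the
statistic Σ(d_i/sd_i)² is referred to a Satterthwaite two-moment match of
the correlated chi-squared sum (eigenvalues of the correlation matrix of d).
The two-moment approximation is accurate at the 0.05 decision boundary used
here; an exact numerical inversion would change little and costs more. A
mediation verdict for two molecular traits is SMR p < 0.05 and HEIDI
p ≥ 0.05.

## miRWAS and the causal screen

Cis heritability is estimated by single-variance-component REML on the
genomic relationship matrix of standardized cis dosages (eigenrotation of
the centered kernel; likelihood-ratio p against the ½χ²(0) + ½χ²(1) boundary
mixture). miRNAs passing the heritability gate (p < 0.01) get expression
weight models: `top1` (the most significant cis SNP's marginal beta),
`lasso`, and elastic net with mixing 0.5, with penalties chosen by
cross-validation; the model with the highest out-of-fold R² is kept (ties
to top1, the simplest). The BLUP and BSLMM entries of the published model
menu are omitted — the tested mechanism is the selection rule, not the menu
breadth, and MCMC weight models are out of scope. Association is the
weighted z, z = w'z_gwas/√(w'Rw), with the training panel serving as its own
LD reference (the desk-scale analog of an external reference panel; the
matrix is ridge-regularized by 1e-3 only if w'Rw is numerically
nonpositive). A miRNA is flagged consistent with causality when all four
criteria hold: miRWAS FDR < 0.05, coloc PP.H4 > 0.5 (strict), SMR p < 0.05,
HEIDI p ≥ 0.05.

## Enrichment, sharing and positions

Regulatory-region enrichment is the Cochran–Mantel–Haenszel test over three
MAF strata — (0, 0.1), [0.1, 0.2), [0.2, 0.5] — with the MH common odds
ratio, no continuity correction, and a Robins–Breslow–Greenland 95% CI;
complete separation returns a +Inf sentinel with a warning. Cross-study
sharing reconstructs the 2×2 table (shared / A-only / B-only / neither) from
published counts and applies the chi-squared test **with** Yates continuity
correction — chosen because it reproduces both printed statistics from the
reconstructed tables (4.33 → 4.3 and 9.05 → 9.1) where the uncorrected
values (5.0, 9.7) do not. Replication of discovery hits is summarized by
Storey's pi1 = 1 − pi0. Index miR-QTL positions are classified strand-aware
(upstream/downstream in the miRNA gene's transcriptional orientation, with
"within" and "ambiguous" classes); the up/down imbalance uses the exact
two-sided binomial test (minimum-likelihood rule), which reproduces the
printed p = 1.32e-10 for 809 versus 570, where a normal approximation does
not at three significant figures.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions every calibration and recovery check runs under.

**Genotypes.** Haplotypes are drawn per LD block from a Gaussian copula with
exchangeable latent correlation, thresholded at allele-frequency quantiles;
dosage is the sum of two haplotypes. The latent correlation is numerically
inverted (bivariate-normal orthant probabilities, bisection) so the realized
*binary* haplotype correlation equals the requested `within_block_r`; for
that target to be attainable exactly, SNPs within a block share one
allele frequency, drawn uniformly from the MAF range (default 0.05–0.5,
the common-variant spectrum after a MAF > 5% merge filter). Blocks are
independent. This is deliberately simpler than coalescent simulation: the
pipeline's LD consumers (clumping, conditional analysis, colocalization,
HEIDI, TWAS) need controlled block structure, not realistic recombination
maps.

**Counts.** Per-feature log2 abundance is baseline + planted SNP effects +
batch offsets (SD 0.3) + three hidden Gaussian factors (loading SD 0.4,
standing in for cell-type composition) + white noise (SD 0.5); counts are
negative-binomial, Var = mu + mu²·dispersion, against library sizes drawn
from 13.2–37.4 million reads (the sequencing-depth range of the emulating
study). The dispersion default is 0.05 and represents *technical*
overdispersion of the counting process only — biological variability is
carried explicitly by the latent terms, and folding it into the NB layer
would double-count it. Planted variance fractions are defined on the
covariate-residualized scale (the unit in which effect sizes are reported):
the allelic effect is calibrated against the realized white-noise variance
plus the expected count-sampling variance (delta method:
var(ln X) ≈ 1/mu + dispersion), and the noise is orthogonalized against the
causal dosages in-sample, so the realized fraction equals the request
essentially exactly. Batch and factor variance sit outside the denominator
because every consumer removes them via covariates or surrogate variables.

**GWAS summary statistics.** Per-locus z-scores are drawn from
z ~ N(R·ncp, R) with R the panel's dosage correlation matrix. The mediated
scenario places the trait's causal SNP on the miRNA's causal SNP with
standardized effect (mediation effect per SD of miRNA) × √(variance
fraction); pleiotropy places an independent direct effect on the same SNP;
linkage places the effect on a correlated but distinct SNP; null has no
effect.

**Annotations.** Interval membership is assigned per SNP with a
stratum-constant odds ratio between miR-QTL and non-QTL SNPs (baseline
overlap 0.3), and member positions are merged into BED-convention intervals,
so the enrichment machinery is exercised end-to-end through its interval
representation.

**Evaluation-suite conditions.** The calibration and recovery suites use
n = 604 samples (the emulated study's size), planted cis effects of 4% of
residual variance (its median effect scale), and a planted heritability of
0.3 spread over four SNPs. The causal-screen suites use a strong cis-QTL
(10% of residual variance), GWAS loci at genome-wide-significant strength
(|z| ≈ 18–24 at the causal or decoy SNP, n_gwas = 50,000) and a linkage
decoy at r² ≈ 0.5 with the exposure SNP — the canonical two-causal-variant
linkage configuration. Problem sizes for the heavier checks: 25,000–40,000
SNP–miRNA pairs per mixed scan, 300 HEIDI replicates, 100 screen replicates
per scenario, 350,000 SNPs for the stratified-enrichment recovery.

# What passing tests do and do not show

The suites demonstrate that each stage is *correct* (closed forms,
brute-force enumeration, normal-equations oracles, round-trips), that the
null behavior is *calibrated* (uniform scan p-values, ~5% HEIDI type-I
error, ~1% heritability-gate false positives, empirical FDR ≤ 2% at
q < 0.01), and that planted structure is *recovered* (power, variance
fractions, heritability, odds ratios, mediation verdicts) under the
conditions above. They do not show that real brain miRNA data satisfy those
conditions: real LD is not block-exchangeable, real library-size artifacts
are not pure scaling, real hidden structure is not three Gaussian factors,
and real causal architectures are not single-variant. Results on real data
inherit all the usual caveats of the underlying methods.

# Known limitations

- **Strong-LD decoys leak.** When a distinct trait-causal SNP sits at
  r² ≳ 0.6 with the miR-QTL, colocalization often still reports a shared
  variant and HEIDI loses power; in that regime roughly one decoy in six
  passed all four criteria in our experiments. The screen's error
  guarantees hold for decoys at r² ≈ 0.5 and below; claims about
  near-perfect-LD loci should not rely on this screen.
- The colocalization branch assumes a single causal variant per trait per
  locus; multi-causal loci are summarized, not resolved.
- The REML heritability and the weight models share one panel for training
  and LD reference; with an external reference panel the TWAS z can be
  conservative or anticonservative depending on LD mismatch.
- The Satterthwaite approximation in HEIDI is a two-moment match; extreme
  tail accuracy (p ≪ 1e-6) is not guaranteed, only behavior near the 0.05
  boundary.
- The q-value pi0 spline is noisy below a few thousand p-values; pi1
  estimates from small replication sets inherit that noise.
- BED is the only 0-based format handled; all internal coordinates are
  1-based inclusive, converted at the boundary.
- When an external study matches variants by rsID and another by position,
  both keys are supported but no precedence is defined for conflicts; the
  caller chooses per dataset.
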