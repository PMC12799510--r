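---
title: "Validating eGFR-trained polygenic scores against measured GFR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating eGFR-trained polygenic scores against measured GFR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalpgs)
```

## The problem

Genome-wide association studies of kidney function almost universally use
creatinine-based estimated GFR (eGFRcr) as the phenotype, because measuring
GFR directly (e.g. by plasma clearance of iohexol) is impractical at GWAS
scale. But serum creatinine is shaped by more than filtration: muscle mass,
creatine metabolism, tubular secretion and assay behaviour all move the
biomarker without moving GFR. Any variant acting on these *non-GFR
determinants* will look like a GFR locus in an eGFRcr GWAS, and any polygenic
score (PGS) built from such a GWAS inherits the confounding. Cystatin C has
the same problem with a different set of determinants.

`renalpgs` implements the full analysis stack for quantifying this bias in a
longitudinal cohort that has both measured GFR (mGFR) and the biomarkers:

1. **Phenotype extraction.** Seven phenotypes per person — standardized
   mGFR, eGFRcr, eGFRcys, eGFRcr-cys, and the three *bias phenotypes*
   (standardized mGFR minus each standardized eGFR) — each estimated as the
   person's random-intercept BLUP from a longitudinal mixed model.
2. **PGS validation.** Scores are parsed from PGS Catalog files (or derived
   from a simulated discovery GWAS), harmonized to cohort alleles, computed
   with score-tool semantics, and regressed on each phenotype with
   covariates; phenotype differences in the PGS coefficient are tested by
   BCa bootstrap.
3. **Per-variant comparison.** Effects of the score's variants are estimated
   per phenotype and compared between mGFR and each eGFR by Deming
   (orthogonal) regression; a slope above 1 means the variants act more
   strongly on mGFR than on the eGFR.
4. **SNP heritability.** V(G), V(e) and h² = V(G)/V(p) by average-information
   REML on the genomic relationship matrix (GRM), with a boundary-corrected
   likelihood-ratio test. Heritable bias phenotypes are direct evidence of
   genetic non-GFR determinants.

Because cohorts with measured GFR are rare and typically not shareable, the
package is organized around a synthetic-cohort generator that encodes the
hypothesized causal structure, so the entire pipeline is exercisable and
testable end to end without any clinical data.

## The generative model

`simConfig()` fixes the study conditions. Defaults emulate a middle-aged
population cohort: 1617 adults (51% women) aged 50–62, visits at 0, 5 and 11
years with retention 1.0/0.81/0.72, and 125 injected first/second-degree
related pairs. Sex-specific baseline GFR means are 89.9 (women) and 98.0
(men) ml/min per 1.73 m² with person-intercept SD 13.7, so the cohort mean
baseline mGFR is ~94 with SD ~14.3 once measurement noise (SD 4, the
day-to-day error of single-sample iohexol clearance) is added.

Latent GFR for person $j$ at time $t$ is

$$T_j(t) = \mu_{\text{sex}} + g_j + e_j + \beta_{\text{sex}}\,t + \gamma t^2,$$

with $g_j$ the genetic value over the GFR-pathway variants (variance
`h2Gfr` = 0.5 of the intercept variance, consistent with the heritability of
measured GFR), $e_j$ environmental, and sex-specific mean decline
$\beta_f = -0.9$, $\beta_m = -1.1$ ml/min per 1.73 m² per year with a mild
acceleration $\gamma = -0.01$.

Biomarkers are generated by *structural inversion* of the CKD-EPI equations:

$$\log \mathrm{Scr}_j(t) = \mathrm{inv}_{2009}\!\big(\tilde T_j(t),
  \text{age}, \text{sex}\big) + g^{cr}_j + u^{cr}_j + \varepsilon^{cr}_{jt},$$

where $\mathrm{inv}_{2009}$ returns the creatinine that makes the 2009
equation reproduce a given GFR, $g^{cr}_j$ is the marker-specific genetic
value (non-GFR creatinine genetics), $u^{cr}_j$ a persistent non-genetic
person effect (muscle mass and other stable determinants), and
$\varepsilon$ visit-level noise. Cystatin C is analogous through the 2012
equation. Two structural features matter:

* **Attenuated GFR sensitivity.** The biomarker responds to GFR deviations
  through $\tilde T = \mu (T/\mu)^{s}$ with elasticity $s < 1$
  (`crGfrSensitivity` = 0.65, `cysGfrSensitivity` = 0.85). Within a healthy
  population creatinine varies less than proportionally with GFR (tubular
  secretion, extrarenal elimination), which is why eGFRcr has a smaller
  population SD than mGFR; the elasticities are calibrated to that SD
  ordering. Attenuation compresses true GFR signal in the estimated GFRs,
  which is what makes per-variant effects *larger* on standardized mGFR than
  on standardized eGFR.
* **Persistent non-GFR terms.** $g^{cr}$ and $u^{cr}$ survive BLUP averaging
  over visits, unlike visit noise. Their variance fractions
  (`h2CrNonGfr` = 0.20, `h2CysNonGfr` = 0.30 of total log-marker variance;
  person SDs 0.05 and 0.06) are free parameters of the generator: no
  published estimates exist, so they are set once to values that reproduce
  the qualitative orderings of interest — a discovery-derived PGS predicting
  eGFRcr better than mGFR, Deming slopes above 1, and heritable bias
  phenotypes — not any particular magnitude. Conclusions from this package's
  synthetic runs are therefore directional, never quantitative.

In the noiseless limit with all non-GFR terms zero and elasticity 1, the
estimating equations recover latent GFR exactly (the inversion is exact on
both sides of each equation's knot), a property the tests exploit.

Genotypes are independent autosomal SNVs (no LD) drawn as two Bernoulli
draws per variant — Hardy-Weinberg by construction — with allele frequencies
uniform on [0.05, 0.5]. The analysis operates on index/lead variants, where
independence is a reasonable idealization; there is no LD mode. Causal sets
for the three pathways are disjoint by default (200 GFR, 100 creatinine, 100
cystatin variants of 2000). Effects are rescaled analytically so each
pathway's expected genetic variance $\sum_i \beta_i^2\, 2p_i(1-p_i)$ hits
its target exactly. Related pairs are injected by gene-drop: one allele per
variant copied from the partner (first degree) or copied with probability
one half (second degree), giving expected GRM relatedness 0.5 or 0.25.

All randomness flows from one master seed through named substreams
(`streamSeed()`), so a cohort, its discovery GWAS, and every bootstrap are
jointly reproducible yet separately replayable.

### What the generator does not emulate

Linkage disequilibrium and imputation artifacts; ancestry structure (PCs in
synthetic runs capture noise, and the PC adjustment is exercised rather than
stressed); assay drift and laboratory recalibration; comorbidity-driven
non-GFR variation (the emulated cohort is healthy by design); X-chromosome
and mitochondrial variation. Passing tests therefore demonstrate that the
*machinery* is correct and that the bias mechanism behaves as hypothesized
under the encoded structure — not that real cohorts will show any particular
effect size.

## Statistical choices

**Phenotype models.** The penalized additive mixed model often used for
longitudinal GFR is implemented as a linear mixed model with an unpenalized
cubic B-spline basis in time (default `splineDf` 3, reduced automatically to
the number of distinct visit times minus one) interacted with sex, plus
baseline age, the leading `k` = 10 genotype PCs and PC-by-time interactions;
the random structure is a person intercept with independent residuals. The
deliverable is the random-intercept BLUP, which is insensitive to modest
differences in the smoother and to replacing an unstructured covariance with
intercept-plus-residual; both simplifications are deliberate. BLUPs are
age-comparable because baseline age is a fixed effect evaluated on the
common design; the package fixes this convention rather than predicting at
a reference age. Bias phenotypes are fitted as their own response series
(per-visit differences of standardized measures) with the same design,
including the PC-by-time terms. Responses are analysed untransformed;
`residualSkewness()` reproduces the diagnostic showing that log
transformation worsens residual skewness for GFR-scale phenotypes.

**Genotype QC.** Hardy-Weinberg uses the exact conditional test (two-sided
by summing configuration probabilities not exceeding the observed one),
which is well-defined at low counts; dosages are rounded to hard calls for
count-based tests. The filter order — samples, then variant call rate, then
HWE, then imputation quality — is fixed for reproducibility; heterozygosity
outliers (|F| > 5 SD) are flagged, never removed. The GRM is the standard
frequency-standardized cross-product with mean imputation of missing
dosages; one estimator serves both the cohort relatedness exclusion
(threshold 0.177, the first/second-degree scale) and the GREML exclusion
(0.025 by convention). `excludeRelated()` removes greedily: highest-degree
persons first, uniform random tie-break under a seed — for disjoint pairs
this removes exactly one random member per pair. With a simulated panel of
$m$ variants the GRM off-diagonal sampling noise is $\approx 1/\sqrt{m}$,
so `runPipeline()` widens the GREML threshold to
$\max(0.025,\, 4/\sqrt{m})$; the genome-wide convention is recovered as $m$
grows.

**Scoring.** Harmonization matches by id with a chrom:pos fallback; effect
allele equal to the alternate uses the dosage, equal to the reference uses
its complement, anything else is dropped and logged; strand-ambiguous (A/T,
C/G) pairs are kept but counted. Missing dosages are mean-imputed to twice
the effect-allele frequency (the common score-tool default). Coverage is
reported as an integer percentage. Disease-risk scores are handled by an
orientation flag that negates weights, with no recalibration.

**Inference.** The PGS contrast between phenotypes resamples *persons* with
replacement, refits both regressions per resample, and forms the
bias-corrected accelerated interval (median-bias z0 from the bootstrap
distribution, acceleration from a person-level jackknife); degenerate
resamples with a constant score are redrawn and counted. Case resampling
(not residual resampling) is the natural choice for a paired cohort
contrast. Per-variant effects use untransformed 0–2 dosages and are computed
by residualizing on covariates (Frisch–Waugh), which is algebraically the
full per-variant regression. Deming regression uses the closed-form slope
with error-variance ratio fixed at 1 and leave-one-point-out jackknife
intervals with a t reference — the common method-comparison practice;
effect vectors enter unweighted.

**GREML.** The variance model $y \sim N(X\beta,\ \sigma_g^2 A +
\sigma_e^2 I)$ is maximized in restricted likelihood after a one-time
eigendecomposition of the GRM, which diagonalizes every iteration. Updates
are average-information with three initial EM steps, step-halving on
overshoot, a monotone-EM rescue, and — when the iteration stalls crawling a
ridge — a profile rescue that optimizes the exact 1-D profile likelihood in
the variance ratio. Components are floored at $10^{-8}\,\mathrm{var}(y)$ and
boundary solutions flagged; a GRM numerically proportional to the identity
is rejected as non-identifiable. Standard errors come from the inverse
average-information matrix (delta method for h²). The h² > 0 test uses the
50:50 chi-square boundary mixture; a Wald p-value is reported as a secondary
column since the test construction behind published GREML tables is usually
unstated. Covariates are handled inside the restricted likelihood (the
rotated design enters every solve), not by pre-residualizing.

## Problem sizes

The test suite and the acceptance script run everything at sizes chosen to
make Monte Carlo conclusions stable on a single core: oracle equivalences on
toys up to n = 50; parameter recovery at n = 800 and m = 2000 over 20
replicates (GREML) and n = 500 (mixed model); bootstrap calibration over 200
null replicates at B = 500; and the qualitative bias-mechanism suite on 20
replicate cohorts of 1500 individuals with a discovery GWAS of 20,000 —
matching the scale of the motivating study design, where the validation
cohort has ~1500 members. The end-to-end acceptance run uses the full
default configuration (1617 individuals, 125 related pairs).

## Known limitations

* Magnitudes of the non-GFR variance fractions are conventions, so
  synthetic h² and variance-explained values are not comparable to
  published cohort estimates; only orderings and directions are.
* The random-slope extension of the phenotype model is not implemented; the
  decline is a fixed sex-specific trend, so person-level slope variation is
  absorbed into residuals.
* Deming intervals are jackknife-based; an analytic alternative is not
  provided.
* GREML is single-component; MAF-stratified and bivariate extensions are out
  of scope.
* `runPipeline()` is the orchestration surface; there is no shell
  executable, by design — the package is meant to be driven from R like its
  Bioconductor peers.
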