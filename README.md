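# renalpgs

Validation of eGFR-trained polygenic scores against measured GFR.

## The problem

Polygenic scores (PGS) for kidney function are built from genome-wide
association studies of *estimated* GFR — almost always creatinine-based
eGFRcr — because directly measured GFR (mGFR, e.g. iohexol clearance) is
unavailable at GWAS scale. Serum creatinine, however, has well-known
**non-GFR determinants** (muscle mass, creatine metabolism, tubular
secretion), and so does cystatin C. Variants acting on those determinants
masquerade as GFR loci, biasing both the GWAS and every score derived from
it. `renalpgs` is for statistical geneticists and nephrology researchers who
want to quantify that bias in a cohort with measured GFR, or to study the
mechanism itself on fully synthetic cohorts.

## What it computes

For each person, seven longitudinal phenotypes are extracted as
random-intercept BLUPs from mixed models with sex-specific spline time
trends, baseline age, and principal-component adjustment: the four GFR
measures (standardized mGFR, eGFRcr, eGFRcys, eGFRcr-cys via the 2009/2012
CKD-EPI equations) and three **bias phenotypes**

    bias_cr  = standardized mGFR − standardized eGFRcr   (etc.)

Scores are harmonized and computed as the weighted effect-allele dosage sum

    PGS_j = Σ_i w_i · d_ij,

and compared across phenotypes three ways:

* **Regression:** β per 1 SD of PGS, with variance explained
  `100 · β² · var(PGS) / var(phenotype)`, and BCa bootstrap tests of
  β differences between mGFR and each eGFR;
* **Deming regression** (error ratio λ = 1) of per-variant effect vectors —
  a slope above 1 means the score's variants act more strongly on mGFR than
  on the eGFR;
* **GREML heritability:** `h² = V(G)/V(p)` from
  `y ~ N(Xβ, V(G)·A + V(e)·I)` by average-information REML on the genomic
  relationship matrix A, with a boundary-corrected likelihood-ratio test.
  A heritable bias phenotype is direct evidence of genetic non-GFR
  determinants.

A synthetic-cohort generator (`simConfig()`, `simulateGenotypes()`,
`simulateCohort()`, `runDiscoveryGwas()`) encodes GFR-pathway versus
marker-specific genetic effects so the entire pipeline runs with no external
data; genotype QC (exact Hardy-Weinberg test, call-rate filters, GRM,
relatedness exclusion, PCs) and PGS Catalog scoring-file I/O round out the
stack. See the vignette in `vignettes/` for the generative model and all
statistical choices.

## Worked example

A small end-to-end run (600 simulated persons, 1500 variants, 20 injected
related pairs, a discovery GWAS of 10,000 on eGFRcr):

```r
library(renalpgs)

cfg    <- simConfig(nIndividuals = 600, nVariants = 1500,
                    nRelatedPairs = 20, seed = 1)
arch   <- simulateArchitecture(cfg)
geno   <- injectRelatives(simulateGenotypes(cfg, arch), nPairs = 20, seed = 2)
visits <- addEgfr(simulateCohort(geno, arch, cfg))

keep   <- excludeRelated(computeGRM(geno), threshold = 0.177, seed = 3)
geno   <- geno[, keep]
visits <- visits[visits$person_id %in% keep, ]
pcs    <- computePCs(geno, k = 10)
phen   <- estimatePhenotypes(visits, pcs = pcs, k = 10)$phenotypes

score  <- runDiscoveryGwas(cfg, discoveryN = 10000, pThreshold = 1e-4,
                           arch = arch)
score  <- harmonizeScore(score, geno)
pgs    <- scaleScores(computeScores(score, geno))

base   <- visits[visits$visit == 1, ]
covar  <- merge(data.frame(person_id = base$person_id, age0 = base$age0,
                           sex = base$sex), pcs, by = "person_id")
for (nm in c("mGFR", "eGFRcr")) {
  est <- fitPgsRegression(phen[c("person_id", nm)], pgs, covar)
  cat(sprintf("%-7s beta %.3f (%.3f-%.3f)  variance explained %.1f%%\n", nm,
              est$beta, est$ci_lo, est$ci_hi,
              varianceExplained(est$beta, 1, var(phen[[nm]]))))
}

ids  <- scoreVariants(score)$rsID
effM <- perSnvEffects(geno, phen[c("person_id", "mGFR")], covar,
                      variantIds = ids)
effC <- perSnvEffects(geno, phen[c("person_id", "eGFRcr")], covar,
                      variantIds = ids)
demingFit(effC$beta, effM$beta)

X <- model.matrix(~ . , covar[match(phen$person_id, covar$person_id), -1])[, -1]
remlFit(phen$bias_cr, X, computeGRM(geno))
```

Output:

```
mGFR    beta 0.418 (0.355-0.481)  variance explained 24.0%
eGFRcr  beta 0.462 (0.404-0.520)  variance explained 31.6%
Deming regression (lambda = 1, n = 89)
  slope 1.052 (0.927-1.177)  intercept -0.0037 (-0.0147-0.0073)
VarianceComponents (n = 580)
  V(G) 0.0597 (0.0170)   V(e) 0.0925 (0.0151)   V(p) 0.1522 (0.0094)
  h2   0.392 (0.103)   LRT p = 0.000173
```

Reading it: 20 of the 600 persons (one per related pair) were excluded
before analysis (580 remain). The eGFRcr-derived score explains more
variance of the eGFRcr phenotype (31.6%) than of measured GFR (24.0%) —
the score is partly predicting creatinine biology, not filtration. Yet the
per-variant Deming slope is above 1: individual variants act more strongly
on mGFR once each phenotype is standardized, because non-GFR variance
dilutes the eGFR phenotypes. And the creatinine bias phenotype is itself
heritable (h² = 0.39, p < 0.001) — the genetic signature of non-GFR
determinants. `runPipeline(cfg, outdir)` runs the same stages end to end
and writes every report table.

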