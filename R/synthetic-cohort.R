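## Synthetic cohort generator.
##
## Emulates a middle-aged population cohort with longitudinal iohexol-measured
## GFR, serum creatinine and cystatin C, genotyped at independent autosomal
## SNVs. The genetic architecture separates three pathways: variants acting on
## latent (true) GFR, variants acting on log-creatinine independent of GFR
## ("non-GFR determinants", e.g. creatinine metabolism), and variants acting on
## log-cystatin-C independent of GFR. Marker concentrations are generated by
## structurally inverting the CKD-EPI estimating equations at the person's
## true GFR and then perturbing on the log scale with genetic, persistent
## person-level (non-genetic, e.g. muscle mass) and visit-level terms; thus
## with all perturbations at zero the estimating equations recover true GFR
## exactly, and non-zero marker genetics biases eGFR-based analyses downstream.

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a population-based cohort of 1617 unrelated adults aged
#' 50-62 (51\% women) with visits at 0, 5 and 11 years (retention 1.0 / 0.81 /
#' 0.72), baseline BSA-standardized measured GFR averaging ~94 ml/min per
#' 1.73 m^2 (SD ~14), and 125 injected first/second-degree related pairs.
#'
#' @slot nIndividuals,nVariants cohort and panel sizes.
#' @slot mafLow,mafHigh allele-frequency bounds in (0, 0.5].
#' @slot nGfrSnvs,nCrSnvs,nCysSnvs causal variant counts per pathway.
#' @slot h2Gfr fraction of person-intercept GFR variance that is genetic.
#' @slot h2CrNonGfr,h2CysNonGfr fraction of log-marker variance attributable
#'   to marker-specific (non-GFR) genetics.
#' @slot visitTimes years since baseline, strictly increasing from 0.
#' @slot retention per-visit retention probabilities.
#' @slot mgfrNoiseSd measurement error of mGFR, ml/min per 1.73 m^2.
#' @slot crNoiseSd,cysNoiseSd visit-level log-marker noise SD.
#' @slot crPersonSd,cysPersonSd persistent non-genetic non-GFR log-marker SD.
#' @slot crGfrSensitivity,cysGfrSensitivity elasticity of the marker with
#'   respect to true GFR, relative to the cross-sectional slope the
#'   estimating equations assume. Values below 1 compress the GFR signal in
#'   the marker (tubular secretion and extrarenal elimination for
#'   creatinine), so the derived eGFR varies less than mGFR -- matching the
#'   smaller population SD of eGFRcr vs mGFR -- and genetic GFR effects are
#'   attenuated in eGFR relative to mGFR.
#' @slot declineRateF,declineRateM mean GFR slope per year by sex.
#' @slot declineQuad quadratic (accelerating) decline term per year^2.
#' @slot gfrMeanF,gfrMeanM,gfrSd baseline person-intercept distribution.
#' @slot nRelatedPairs related pairs injected by [injectRelatives()].
#' @slot relatedDegree 1 (parent-offspring/sibling-like) or 2.
#' @slot seed master seed; all operations draw named substreams from it.
#' @export
setClass("SimConfig", representation(
  nIndividuals = "integer", nVariants = "integer",
  mafLow = "numeric", mafHigh = "numeric",
  nGfrSnvs = "integer", nCrSnvs = "integer", nCysSnvs = "integer",
  h2Gfr = "numeric", h2CrNonGfr = "numeric", h2CysNonGfr = "numeric",
  visitTimes = "numeric", retention = "numeric",
  mgfrNoiseSd = "numeric", crNoiseSd = "numeric", cysNoiseSd = "numeric",
  crPersonSd = "numeric", cysPersonSd = "numeric",
  crGfrSensitivity = "numeric", cysGfrSensitivity = "numeric",
  declineRateF = "numeric", declineRateM = "numeric", declineQuad = "numeric",
  gfrMeanF = "numeric", gfrMeanM = "numeric", gfrSd = "numeric",
  nRelatedPairs = "integer", relatedDegree = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- NULL
  if (object@mafLow <= 0 || object@mafHigh > 0.5 ||
      object@mafLow > object@mafHigh)
    msg <- c(msg, "require 0 < mafLow <= mafHigh <= 0.5")
  for (h in c(object@h2Gfr, object@h2CrNonGfr, object@h2CysNonGfr))
    if (h < 0 || h >= 1) msg <- c(msg, "variance fractions must lie in [0, 1)")
  vt <- object@visitTimes
  if (vt[1] != 0 || any(diff(vt) <= 0))
    msg <- c(msg, "visitTimes must be strictly increasing and start at 0")
  if (length(object@retention) != length(vt))
    msg <- c(msg, "retention must have one entry per visit")
  if (max(object@nGfrSnvs, object@nCrSnvs, object@nCysSnvs) > object@nVariants)
    msg <- c(msg, "causal counts must not exceed nVariants")
  if (2L * object@nRelatedPairs > object@nIndividuals)
    msg <- c(msg, "2 * nRelatedPairs must not exceed nIndividuals")
  if (is.null(msg)) TRUE else msg
})

#' Create a simulation configuration
#'
#' See [SimConfig-class] for the meaning and rationale of each default.
#'
#' @param nIndividuals,nVariants,mafLow,mafHigh,nGfrSnvs,nCrSnvs,nCysSnvs
#'   see [SimConfig-class].
#' @param h2Gfr,h2CrNonGfr,h2CysNonGfr,visitTimes,retention see
#'   [SimConfig-class].
#' @param mgfrNoiseSd,crNoiseSd,cysNoiseSd,crPersonSd,cysPersonSd see
#'   [SimConfig-class].
#' @param declineRateF,declineRateM,declineQuad,gfrMeanF,gfrMeanM,gfrSd see
#'   [SimConfig-class].
#' @param nRelatedPairs,relatedDegree,seed see [SimConfig-class].
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nIndividuals = 1617, nVariants = 2000,
                      mafLow = 0.05, mafHigh = 0.5,
                      nGfrSnvs = min(200, nVariants %/% 4),
                      nCrSnvs = min(100, nVariants %/% 8),
                      nCysSnvs = min(100, nVariants %/% 8),
                      h2Gfr = 0.5, h2CrNonGfr = 0.2, h2CysNonGfr = 0.3,
                      visitTimes = c(0, 5, 11),
                      retention = c(1, 0.81, 0.72),
                      mgfrNoiseSd = 4, crNoiseSd = 0.04, cysNoiseSd = 0.04,
                      crPersonSd = 0.05, cysPersonSd = 0.06,
                      crGfrSensitivity = 0.65, cysGfrSensitivity = 0.85,
                      declineRateF = -0.9, declineRateM = -1.1,
                      declineQuad = -0.01,
                      gfrMeanF = 89.9, gfrMeanM = 98.0, gfrSd = 13.7,
                      nRelatedPairs = 125, relatedDegree = 1, seed = 1) {
  new("SimConfig",
      nIndividuals = as.integer(nIndividuals),
      nVariants = as.integer(nVariants),
      mafLow = mafLow, mafHigh = mafHigh,
      nGfrSnvs = as.integer(nGfrSnvs), nCrSnvs = as.integer(nCrSnvs),
      nCysSnvs = as.integer(nCysSnvs),
      h2Gfr = h2Gfr, h2CrNonGfr = h2CrNonGfr, h2CysNonGfr = h2CysNonGfr,
      visitTimes = visitTimes, retention = retention,
      mgfrNoiseSd = mgfrNoiseSd, crNoiseSd = crNoiseSd,
      cysNoiseSd = cysNoiseSd, crPersonSd = crPersonSd,
      cysPersonSd = cysPersonSd,
      crGfrSensitivity = crGfrSensitivity,
      cysGfrSensitivity = cysGfrSensitivity,
      declineRateF = declineRateF, declineRateM = declineRateM,
      declineQuad = declineQuad,
      gfrMeanF = gfrMeanF, gfrMeanM = gfrMeanM, gfrSd = gfrSd,
      nRelatedPairs = as.integer(nRelatedPairs),
      relatedDegree = as.integer(relatedDegree), seed = as.integer(seed))
}

#' Draw the shared genetic architecture
#'
#' Allele frequencies, causal variant sets and per-variant effects are drawn
#' once per configuration (substream "architecture") and shared between
#' discovery and validation cohorts, so the same variant has the same causal
#' role in both. Effects are N(0,1) draws rescaled analytically so that the
#' expected genetic variance of each pathway, `sum(beta_i^2 * 2 p_i (1-p_i))`,
#' equals its target exactly: `h2Gfr * gfrSd^2` for the GFR pathway (in
#' ml/min per 1.73 m^2 units) and, for each marker, the log-scale variance
#' making the marker-specific genetic share of total log-marker variance equal
#' `h2CrNonGfr` (resp. `h2CysNonGfr`).
#'
#' @param config a [SimConfig-class].
#' @return a list with `variants` (metadata data.frame including `af`),
#'   `gfrEffects`, `crEffects`, `cysEffects` (per-variant vectors, 0 at
#'   non-causal variants) and the causal index sets.
#' @export
simulateArchitecture <- function(config) {
  validObject(config)
  set.seed(streamSeed(config@seed, "architecture"))
  m <- config@nVariants
  af <- stats::runif(m, config@mafLow, config@mafHigh)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  variants <- data.frame(
    variant_id = sprintf("snv%05d", seq_len(m)),
    chrom = as.character(sort(sample(1:22, m, replace = TRUE))),
    pos = sort(sample.int(2.5e8, m)),
    ref = ref, alt = unname(alt), af = af)

  perm <- sample.int(m)
  idxGfr <- perm[seq_len(config@nGfrSnvs)]
  idxCr <- perm[config@nGfrSnvs + seq_len(config@nCrSnvs)]
  remaining <- config@nGfrSnvs + config@nCrSnvs
  idxCys <- perm[((remaining + seq_len(config@nCysSnvs) - 1L) %% m) + 1L]

  scaleTo <- function(idx, targetVar) {
    beta <- numeric(m)
    if (targetVar <= 0 || !length(idx)) return(beta)
    raw <- stats::rnorm(length(idx))
    v <- sum(raw^2 * 2 * af[idx] * (1 - af[idx]))
    beta[idx] <- raw * sqrt(targetVar / v)
    beta
  }

  ## log-scale variance bookkeeping for the markers: the GFR-driven share of
  ## log-marker variance is b^2 * var(log trueGFR) with b the CKD-EPI
  ## power-law slope; targets are set so the marker-genetic share of the
  ## total equals the configured fraction.
  gfrMean <- 0.51 * config@gfrMeanF + 0.49 * config@gfrMeanM
  varLogT <- (config@gfrSd / gfrMean)^2
  crBase <- (config@crGfrSensitivity / 1.209)^2 * varLogT +
    config@crPersonSd^2 + config@crNoiseSd^2
  cysBase <- (config@cysGfrSensitivity / 1.328)^2 * varLogT +
    config@cysPersonSd^2 + config@cysNoiseSd^2
  crVar <- config@h2CrNonGfr / (1 - config@h2CrNonGfr) * crBase
  cysVar <- config@h2CysNonGfr / (1 - config@h2CysNonGfr) * cysBase

  list(variants = variants,
       gfrEffects = scaleTo(idxGfr, config@h2Gfr * config@gfrSd^2),
       crEffects = scaleTo(idxCr, crVar),
       cysEffects = scaleTo(idxCys, cysVar),
       idxGfr = idxGfr, idxCr = idxCr, idxCys = idxCys)
}

#' Simulate genotype dosages
#'
#' Hard-call dosages drawn as two Bernoulli(p) draws per person per variant
#' (Hardy-Weinberg proportions by construction), variants independent (no LD).
#'
#' @param config a [SimConfig-class].
#' @param arch architecture from [simulateArchitecture()]; drawn from `config`
#'   when `NULL`.
#' @param n number of individuals (default `config@nIndividuals`).
#' @param stream substream name; use distinct names for distinct cohorts.
#' @return a [GenotypeMatrix-class] (variants x persons).
#' @export
simulateGenotypes <- function(config, arch = NULL, n = config@nIndividuals,
                              stream = "genotypes") {
  validObject(config)
  if (is.null(arch)) arch <- simulateArchitecture(config)
  set.seed(streamSeed(config@seed, stream))
  m <- config@nVariants
  d <- matrix(stats::rbinom(m * n, 2L, rep(arch$variants$af, n)), nrow = m)
  persons <- data.frame(person_id = sprintf("%s%05d",
                                            if (stream == "genotypes") "P" else "D",
                                            seq_len(n)))
  GenotypeMatrix(d, arch$variants, persons)
}

#' Simulate a longitudinal visit table
#'
#' True GFR follows `T_j(t) = T0_j + slope_sex * t + declineQuad * t^2` with
#' person intercept `T0_j = mean_sex + g_j + e_j` (genetic value plus
#' environmental intercept). Measured GFR adds visit-level noise; log serum
#' creatinine is the structural CKD-EPI inversion at true GFR plus the
#' person's marker-genetic value, a persistent non-genetic person term, and
#' visit noise (cystatin C analogous). Height and weight are drawn by sex for
#' BSA computation; per-visit dropout follows the retention probabilities.
#'
#' @param genotypes a [GenotypeMatrix-class] for the cohort.
#' @param arch matching architecture from [simulateArchitecture()].
#' @param config a [SimConfig-class].
#' @param stream substream name.
#' @return a long-format data.frame (one row per person-visit) with columns
#'   `person_id, sex, age0, age, height, weight, visit, time, true_gfr, mgfr,
#'   scr, scys`, and an attribute `"truth"`: a per-person data.frame of the
#'   latent intercepts and genetic values.
#' @export
simulateCohort <- function(genotypes, arch, config, stream = "cohort") {
  validObject(config)
  d <- dosages(genotypes)
  if (nrow(d) != length(arch$gfrEffects))
    stop("architecture dimensions do not match genotypes")
  set.seed(streamSeed(config@seed, stream))
  n <- ncol(d)
  ids <- personIds(genotypes)

  sex <- ifelse(stats::runif(n) < 0.51, "female", "male")
  f <- sex == "female"
  age0 <- pmin(pmax(stats::rnorm(n, 58, 3.8), 50), 62)
  height <- ifelse(f, stats::rnorm(n, 164.5, 6.0), stats::rnorm(n, 177.0, 6.2))
  weight <- ifelse(f, stats::rnorm(n, 72.6, 12.4), stats::rnorm(n, 87.4, 12.4))

  gGfr <- drop(crossprod(d, arch$gfrEffects))
  gCr <- drop(crossprod(d, arch$crEffects))
  gCys <- drop(crossprod(d, arch$cysEffects))
  gGfr <- gGfr - mean(gGfr); gCr <- gCr - mean(gCr); gCys <- gCys - mean(gCys)

  envSd <- sqrt(max(0, (1 - config@h2Gfr))) * config@gfrSd
  envInt <- stats::rnorm(n, 0, envSd)
  t0 <- ifelse(f, config@gfrMeanF, config@gfrMeanM) + gGfr + envInt
  uCr <- stats::rnorm(n, 0, config@crPersonSd)
  uCys <- stats::rnorm(n, 0, config@cysPersonSd)

  vt <- config@visitTimes
  K <- length(vt)
  keep <- matrix(stats::runif(n * K) < rep(config@retention, each = n),
                 nrow = n)
  keep[, 1] <- keep[, 1] | config@retention[1] >= 1

  rows <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(keep[, k])
    t <- vt[k]
    slope <- ifelse(f[idx], config@declineRateF, config@declineRateM)
    trueGfr <- pmax(t0[idx] + slope * t + config@declineQuad * t^2, 5)
    age <- age0[idx] + t
    mgfr <- trueGfr + stats::rnorm(length(idx), 0, config@mgfrNoiseSd)
    ## the markers respond to GFR deviations (on the log scale, around the
    ## sex-specific cohort mean) with a configurable elasticity < 1
    ref <- ifelse(f[idx], config@gfrMeanF, config@gfrMeanM)
    gfrCr <- ref * (trueGfr / ref)^config@crGfrSensitivity
    gfrCys <- ref * (trueGfr / ref)^config@cysGfrSensitivity
    logScr <- log(invertScr(gfrCr, age, sex[idx])) + gCr[idx] + uCr[idx] +
      stats::rnorm(length(idx), 0, config@crNoiseSd)
    logScys <- log(invertScys(gfrCys, age, sex[idx])) + gCys[idx] +
      uCys[idx] + stats::rnorm(length(idx), 0, config@cysNoiseSd)
    rows[[k]] <- data.frame(
      person_id = ids[idx], sex = sex[idx], age0 = age0[idx], age = age,
      height = height[idx], weight = weight[idx], visit = k, time = t,
      true_gfr = trueGfr, mgfr = mgfr, scr = exp(logScr), scys = exp(logScys))
  }
  visits <- do.call(rbind, rows)
  visits <- visits[order(visits$person_id, visits$visit), ]
  rownames(visits) <- NULL
  attr(visits, "truth") <- data.frame(
    person_id = ids, sex = sex, intercept = t0, genetic_gfr = gGfr,
    env_gfr = envInt, genetic_cr = gCr, genetic_cys = gCys,
    person_cr = uCr, person_cys = uCys)
  visits
}

#' Inject related pairs by gene-drop
#'
#' For each of `nPairs` disjoint pairs, the second member's genotype is
#' re-drawn so that at every variant one allele is copied from the partner
#' (first degree) or copied with probability 1/2 and drawn from the population
#' otherwise (second degree); the remaining allele is a fresh Bernoulli(p)
#' draw. Expected genomic relatedness is 0.5 (first degree) or 0.25 (second).
#'
#' @param genotypes a [GenotypeMatrix-class] with an `af` rowData column.
#' @param nPairs number of pairs; 0 returns the input unchanged.
#' @param degree 1 or 2.
#' @param seed integer seed.
#' @param pairs optional 2-column matrix of person indices; random disjoint
#'   pairs are drawn when `NULL`. Overlapping pairs are an error.
#' @return the modified [GenotypeMatrix-class]; the chosen pairs are stored in
#'   `metadata()$relatedPairs`.
#' @export
injectRelatives <- function(genotypes, nPairs, degree = 1, seed = 1,
                            pairs = NULL) {
  if (nPairs == 0) return(genotypes)
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2")
  d <- dosages(genotypes)
  n <- ncol(d)
  if (2 * nPairs > n) stop("2 * nPairs exceeds the number of individuals")
  set.seed(seed)
  if (is.null(pairs)) {
    chosen <- sample.int(n, 2 * nPairs)
    pairs <- matrix(chosen, ncol = 2)
  } else {
    pairs <- as.matrix(pairs)
    if (anyDuplicated(as.vector(pairs))) stop("pairs must be disjoint")
  }
  af <- variantInfo(genotypes)$af
  if (is.null(af)) af <- rowMeans(d, na.rm = TRUE) / 2
  m <- nrow(d)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    transmitted <- stats::rbinom(m, 1L, d[, a] / 2)
    if (degree == 2) {
      fresh <- stats::rbinom(m, 1L, af)
      fromPartner <- stats::runif(m) < 0.5
      transmitted <- ifelse(fromPartner, transmitted, fresh)
    }
    d[, b] <- transmitted + stats::rbinom(m, 1L, af)
  }
  out <- GenotypeMatrix(d, variantInfo(genotypes),
                        as.data.frame(colData(genotypes)))
  metadata(out)$relatedPairs <- pairs
  out
}

#' Derive a polygenic score from a simulated discovery GWAS
#'
#' Simulates an independent discovery cohort (substreams
#' "discovery-genotypes" / "discovery-cohort") under the same architecture,
#' computes the baseline eGFRcr phenotype, regresses it marginally on each
#' variant's dosage, and turns variants passing `pThreshold` into a scoring
#' set with effect allele = alternate allele and weight = estimated beta.
#'
#' @param config a [SimConfig-class].
#' @param discoveryN discovery sample size (>= 100).
#' @param phenotype currently `"eGFRcr"` (standardized baseline value).
#' @param pThreshold marginal p-value threshold for inclusion.
#' @param arch optional pre-drawn architecture.
#' @return a [ScoreSet-class]; the full per-variant GWAS table is attached as
#'   attribute `"gwas"`.
#' @export
runDiscoveryGwas <- function(config, discoveryN = 20000,
                             phenotype = "eGFRcr", pThreshold = 5e-4,
                             arch = NULL) {
  if (discoveryN < 100)
    stop("discoveryN < 100: weights would be meaningless")
  phenotype <- match.arg(phenotype, "eGFRcr")
  if (is.null(arch)) arch <- simulateArchitecture(config)
  g <- simulateGenotypes(config, arch, n = discoveryN,
                         stream = "discovery-genotypes")
  ## the discovery GWAS is cross-sectional: only the baseline visit is drawn
  cfg1 <- config
  cfg1@visitTimes <- 0
  cfg1@retention <- 1
  visits <- simulateCohort(g, arch, cfg1, stream = "discovery-cohort")
  base <- visits[visits$visit == 1, ]
  base <- base[match(personIds(g), base$person_id), ]
  y <- egfrCr2009(base$scr, base$age, base$sex)
  y <- (y - mean(y)) / stats::sd(y)

  d <- dosages(g)
  dc <- d - rowMeans(d)
  sxx <- rowSums(dc^2)
  sxy <- drop(dc %*% (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  ok <- sxx > 0
  beta <- se <- p <- rep(NA_real_, nrow(d))
  beta[ok] <- sxy[ok] / sxx[ok]
  df <- discoveryN - 2
  s2 <- pmax((syy - beta[ok] * sxy[ok]) / df, 0)
  se[ok] <- sqrt(s2 / sxx[ok])
  p[ok] <- 2 * stats::pt(-abs(beta[ok] / se[ok]), df)

  vi <- arch$variants
  gwas <- data.frame(vi[c("variant_id", "chrom", "pos", "ref", "alt")],
                     beta = beta, se = se, p = p)
  sel <- which(!is.na(p) & p < pThreshold)
  if (!length(sel)) stop("no variant passed the discovery p-threshold")
  sv <- data.frame(rsID = vi$variant_id[sel], chr_name = vi$chrom[sel],
                   chr_position = vi$pos[sel], effect_allele = vi$alt[sel],
                   other_allele = vi$ref[sel], effect_weight = beta[sel])
  out <- ScoreSet(sv, name = sprintf("PGS_discovery_%s", phenotype),
                  orientation = 1)
  attr(out, "gwas") <- gwas
  out
}
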