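## End-to-end orchestration: simulate -> QC -> phenotypes -> scores ->
## association -> heritability, writing tab-delimited report tables and a
## run log with every seed used.

#' Run the full synthetic validation pipeline
#'
#' Simulates a cohort under `config` (with related pairs injected), applies
#' the QC cascade, excludes close relatives (cohort threshold), computes
#' principal components and the seven BLUP phenotypes, derives a polygenic
#' score from an independent discovery cohort, scores and scales it,
#' estimates PGS effects on the four GFR phenotypes with variance explained
#' and BCa contrasts against mGFR, compares per-variant effect vectors by
#' Deming regression, and estimates GREML heritability for all seven
#' phenotypes on the relatedness-pruned subset.
#'
#' @param config a [SimConfig-class].
#' @param outdir output directory (created if needed).
#' @param discoveryN discovery-cohort size for the derived score.
#' @param pThreshold discovery p-value threshold.
#' @param bootB bootstrap resamples for the effect contrasts.
#' @param relatedThreshold GRM threshold for the cohort relatedness
#'   exclusion (first/second-degree scale).
#' @param gremlThreshold GRM threshold for the GREML exclusion. The
#'   conventional 0.025 presumes genome-wide panels where GRM sampling noise
#'   is negligible; with m simulated variants the off-diagonal noise SD is
#'   ~1/sqrt(m), so the default `NULL` uses `max(0.025, 4/sqrt(m))` to keep
#'   the exclusion aimed at genuine relatedness.
#' @param k number of principal components used as covariates.
#' @return invisibly, a list with the report tables (`qc`, `phenotypes`,
#'   `scores`, `harmonization`, `associations`, `deming`, `heritability`)
#'   and the paths written.
#' @export
runPipeline <- function(config = simConfig(), outdir,
                        discoveryN = 6000, pThreshold = 1e-4, bootB = 500,
                        relatedThreshold = 0.177, gremlThreshold = NULL,
                        k = 10) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logLines <- c(sprintf("master seed: %d", config@seed),
                sprintf("stage seeds: architecture=%d genotypes=%d cohort=%d",
                        streamSeed(config@seed, "architecture"),
                        streamSeed(config@seed, "genotypes"),
                        streamSeed(config@seed, "cohort")))
  note <- function(...) logLines <<- c(logLines, sprintf(...))

  ## --- simulate -----------------------------------------------------------
  arch <- simulateArchitecture(config)
  g <- simulateGenotypes(config, arch)
  g <- injectRelatives(g, config@nRelatedPairs, degree = config@relatedDegree,
                       seed = streamSeed(config@seed, "relatives"))
  note("simulated %d persons x %d variants, %d related pairs injected",
       ncol(g), nrow(g), config@nRelatedPairs)
  ## visit table is generated against the full variant panel, before QC
  visits <- simulateCohort(g, arch, config)

  ## --- QC -----------------------------------------------------------------
  qc <- applyQCFilters(g)
  g <- qc$genotypes
  note("QC: %d variants, %d samples retained", nrow(g), ncol(g))
  grm <- computeGRM(g)
  retained <- excludeRelated(grm, threshold = relatedThreshold,
                             seed = streamSeed(config@seed, "exclusion"))
  note("relatedness exclusion (> %.3f): %d -> %d retained",
       relatedThreshold, ncol(g), length(retained))
  g <- g[, retained]
  grm <- computeGRM(g)
  pcs <- computePCs(g, k = k)

  ## --- phenotypes ---------------------------------------------------------
  visits <- visits[visits$person_id %in% retained, ]
  visits <- addEgfr(visits)
  ph <- estimatePhenotypes(visits, pcs = pcs, k = k)
  phen <- ph$phenotypes
  note("phenotypes: %d persons, %d visits", nrow(phen), nrow(visits))

  ## --- polygenic score ----------------------------------------------------
  score <- runDiscoveryGwas(config, discoveryN = discoveryN,
                            pThreshold = pThreshold, arch = arch)
  score <- harmonizeScore(score, g)
  lg <- harmonizationLog(score)
  note("score '%s': %d/%d variants matched (%d%%)", score@name, lg$matched,
       lg$total, lg$coverage_pct)
  scores <- scaleScores(computeScores(score, g))
  harm <- data.frame(score = score@name, matched = lg$matched,
                     flipped = lg$flipped, ambiguous = lg$ambiguous,
                     missing = lg$missing, total = lg$total,
                     coverage_pct = lg$coverage_pct)

  ## --- association --------------------------------------------------------
  base <- visits[visits$visit == 1, ]
  covar <- data.frame(person_id = base$person_id, age0 = base$age0,
                      sex = base$sex)
  covar <- merge(covar, pcs, by = "person_id")
  gfrPhen <- c("mGFR", "eGFRcr", "eGFRcys", "eGFRcrcys")
  assoc <- do.call(rbind, lapply(gfrPhen, function(nm) {
    est <- fitPgsRegression(phen[c("person_id", nm)], scores, covar)
    est$variance_explained_pct <- varianceExplained(
      est$beta, 1, stats::var(phen[[nm]], na.rm = TRUE))
    est$pgs <- score@name
    est
  }))

  ids <- phen$person_id
  Xcov <- alignCovariates(ids, covar)
  pgsVec <- scores$weighted[match(ids, scores$person_id)]
  contrasts <- do.call(rbind, lapply(setdiff(gfrPhen, "mGFR"), function(nm) {
    b <- bootstrapBetaDifference(phen$mGFR, phen[[nm]], pgsVec, Xcov,
                                 B = bootB,
                                 seed = streamSeed(config@seed,
                                                   paste0("boot-", nm)))
    data.frame(phenotype_a = "mGFR", phenotype_b = nm, diff = b@observed,
               ci_lo = b@ci[1], ci_hi = b@ci[2], B = b@B, reject = b@reject)
  }))

  snvIds <- scoreVariants(score)$rsID
  effects <- lapply(gfrPhen, function(nm)
    perSnvEffects(g, phen[c("person_id", nm)], covar, variantIds = snvIds))
  names(effects) <- gfrPhen
  deming <- do.call(rbind, lapply(setdiff(gfrPhen, "mGFR"), function(nm) {
    dm <- demingFit(effects[[nm]]$beta, effects$mGFR$beta)
    data.frame(x_phenotype = nm, y_phenotype = "mGFR", pgs = score@name,
               slope = dm@slope, slope_lo = dm@slopeCI[1],
               slope_hi = dm@slopeCI[2], intercept = dm@intercept,
               n = dm@n)
  }))

  ## --- heritability -------------------------------------------------------
  if (is.null(gremlThreshold))
    gremlThreshold <- max(0.025, 4 / sqrt(grm@nVariants))
  keepH <- excludeRelated(grm, threshold = gremlThreshold,
                          seed = streamSeed(config@seed, "greml-exclusion"))
  note("GREML exclusion (> %.3f): %d retained", gremlThreshold, length(keepH))
  hIdx <- match(keepH, phen$person_id)
  Xh <- alignCovariates(keepH, covar)
  grmH <- new("RelationshipMatrix",
              as(grm, "matrix")[match(keepH, rownames(grm)),
                                match(keepH, rownames(grm))],
              nVariants = grm@nVariants)
  allPhen <- c(gfrPhen, "bias_cr", "bias_cys", "bias_crcys")
  herit <- do.call(rbind, lapply(allPhen, function(nm) {
    vc <- remlFit(phen[[nm]][hIdx], Xh, grmH)
    data.frame(phenotype = nm, vg = vc@vg, vg_se = vc@se["vg"],
               vp = vc@vp, vp_se = vc@se["vp"],
               h2 = vc@h2, h2_se = vc@se["h2"],
               ve = vc@ve, ve_se = vc@se["ve"], lrt_p = vc@lrtP,
               row.names = NULL)
  }))

  ## --- reports ------------------------------------------------------------
  tables <- list(qc = qc$report, phenotypes = phen, scores = scores,
                 harmonization = harm, associations = assoc,
                 contrasts = contrasts, deming = deming,
                 heritability = herit)
  paths <- vapply(names(tables), function(nm) {
    writeTsv(tables[[nm]], file.path(outdir, paste0(nm, ".tsv")))
  }, "")
  writeLines(logLines, file.path(outdir, "run_log.txt"))
  invisible(c(tables, list(paths = paths, log = logLines)))
}
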