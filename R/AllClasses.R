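#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' GenotypeMatrix: per-person per-variant allele dosages
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"dosage"` assay (variants in rows, persons in columns; values in
#' \[0, 2\] or `NA` for missing), variant metadata in `rowData()` (`variant_id`,
#' `chrom`, `pos`, `ref`, `alt`, and optionally the generating allele frequency
#' `af` and an imputation quality `info` in \[0, 1\]) and person metadata in
#' `colData()`.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- NULL
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    if (any(d < 0 | d > 2, na.rm = TRUE))
      msg <- c(msg, "dosages must lie in [0, 2] or be NA")
  }
  rd <- rowData(object)
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ", paste(miss, collapse = ", ")))
  if ("variant_id" %in% colnames(rd) && anyDuplicated(rd$variant_id))
    msg <- c(msg, "variant ids must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix, variants x persons, values in \[0,2\] or `NA`.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt` (optionally `af`, `info`), one row per dosage row.
#' @param persons optional data.frame of person metadata (must contain
#'   `person_id`), one row per dosage column.
#' @return a [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosage, variants, persons = NULL) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(variants))
    stop("nrow(dosage) != nrow(variants)")
  if (is.null(persons)) {
    ids <- colnames(dosage)
    if (is.null(ids)) ids <- sprintf("P%05d", seq_len(ncol(dosage)))
    persons <- data.frame(person_id = ids)
  }
  rownames(dosage) <- variants$variant_id
  colnames(dosage) <- persons$person_id
  new("GenotypeMatrix", SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = DataFrame(variants),
    colData = DataFrame(persons, row.names = persons$person_id)))
}

#' @describeIn GenotypeMatrix extract the dosage matrix (variants x persons).
#' @param x a `GenotypeMatrix`.
#' @export
dosages <- function(x) assay(x, "dosage")

#' @describeIn GenotypeMatrix variant metadata as a base data.frame.
#' @export
variantInfo <- function(x) as.data.frame(rowData(x))

#' @describeIn GenotypeMatrix person identifiers.
#' @export
personIds <- function(x) colnames(x)

#' ScoreSet: a parsed polygenic score
#'
#' Holds the scoring variants of one polygenic score (PGS Catalog layout:
#' `rsID`, `chr_name`, `chr_position`, `effect_allele`, `other_allele`,
#' `effect_weight`), an orientation flag (+1 when an increasing score means
#' higher GFR, -1 for disease-risk scores whose weights must be negated), and,
#' after [harmonizeScore()], the per-variant genotype row index, an
#' allele-flip indicator, and the harmonization log.
#'
#' @slot name score name.
#' @slot variants data.frame of scoring variants (plus `g_index`, `flip`,
#'   `ambiguous` columns once harmonized).
#' @slot orientation +1 or -1; applied to weights when scoring.
#' @slot harmonized logical flag.
#' @slot log list with counts `matched`, `flipped`, `ambiguous`,
#'   `mismatched`, `missing`, `total` and `coverage_pct`.
#' @export
setClass("ScoreSet", representation(
  name = "character", variants = "data.frame", orientation = "numeric",
  harmonized = "logical", log = "list"))

setValidity("ScoreSet", function(object) {
  msg <- NULL
  v <- object@variants
  need <- c("rsID", "chr_name", "chr_position", "effect_allele",
            "other_allele", "effect_weight")
  miss <- setdiff(need, colnames(v))
  if (length(miss))
    msg <- c(msg, paste0("variants lack column(s): ", paste(miss, collapse = ", ")))
  if (!length(msg) && any(v$effect_allele == v$other_allele))
    msg <- c(msg, "effect allele must differ from other allele")
  if (!object@orientation %in% c(-1, 1))
    msg <- c(msg, "orientation must be +1 or -1")
  if (object@harmonized && length(object@log)) {
    lg <- object@log
    if (lg$matched + lg$missing != lg$total)
      msg <- c(msg, "harmonization counts must satisfy matched + missing = total")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a ScoreSet
#' @param variants data.frame in PGS Catalog column layout.
#' @param name score name.
#' @param orientation +1 (higher score = higher GFR) or -1 (disease risk).
#' @return a [ScoreSet-class].
#' @export
ScoreSet <- function(variants, name = "PGS", orientation = 1) {
  new("ScoreSet", name = name, variants = as.data.frame(variants),
      orientation = orientation, harmonized = FALSE, log = list())
}

#' @describeIn ScoreSet scoring variants as a data.frame.
#' @param x a `ScoreSet`.
#' @export
scoreVariants <- function(x) x@variants

#' @describeIn ScoreSet harmonization log (empty list before harmonization).
#' @export
harmonizationLog <- function(x) x@log

setMethod("show", "ScoreSet", function(object) {
  cat("ScoreSet '", object@name, "': ", nrow(object@variants),
      " variants, orientation ", sprintf("%+d", as.integer(object@orientation)),
      "\n", sep = "")
  if (object@harmonized) {
    lg <- object@log
    cat(sprintf("  harmonized: %d matched (%d flipped, %d ambiguous), %d missing, coverage %d%%\n",
                lg$matched, lg$flipped, lg$ambiguous, lg$missing, lg$coverage_pct))
  }
})

#' RelationshipMatrix: genomic relatedness between persons
#'
#' A symmetric person x person matrix of genomic relationships (diagonal
#' near 1 for outbred samples) carrying the number of variants it was
#' computed from.
#'
#' @slot nVariants number of variants entering the estimate.
#' @export
setClass("RelationshipMatrix", contains = "matrix",
         representation(nVariants = "integer"))

setValidity("RelationshipMatrix", function(object) {
  m <- object@.Data
  if (nrow(m) != ncol(m)) return("must be square")
  if (max(abs(m - t(m))) > 1e-8) return("must be symmetric")
  TRUE
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix: ", nrow(object), " persons, ",
      object@nVariants, " variants\n", sep = "")
  cat("  mean diagonal ", round(mean(diag(object@.Data)), 3),
      ", max off-diagonal ",
      round(max(object@.Data[upper.tri(object@.Data)]), 3), "\n", sep = "")
})

#' VarianceComponents: GREML variance decomposition of one phenotype
#'
#' @slot vg genetic variance V(G).
#' @slot ve residual variance V(e).
#' @slot vp phenotypic variance V(p) = V(G) + V(e).
#' @slot h2 narrow-sense SNP heritability V(G)/V(p).
#' @slot se named numeric: standard errors of vg, ve, vp, h2.
#' @slot loglik restricted log-likelihood at the optimum.
#' @slot loglikNull restricted log-likelihood with V(G) = 0.
#' @slot lrtP boundary-corrected likelihood-ratio p-value for h2 > 0.
#' @slot waldP one-sided Wald p-value (secondary).
#' @slot iterations iterations used.
#' @slot converged logical.
#' @slot boundary TRUE if a component was clamped at the variance floor.
#' @slot degenerate TRUE when V(G) and V(e) are not separable (e.g. identity GRM).
#' @slot n number of persons.
#' @export
setClass("VarianceComponents", representation(
  vg = "numeric", ve = "numeric", vp = "numeric", h2 = "numeric",
  se = "numeric", loglik = "numeric", loglikNull = "numeric",
  lrtP = "numeric", waldP = "numeric", iterations = "integer",
  converged = "logical", boundary = "logical", degenerate = "logical",
  n = "integer"))

setValidity("VarianceComponents", function(object) {
  msg <- NULL
  if (object@vg < 0 || object@ve < 0) msg <- c(msg, "variances must be >= 0")
  if (abs(object@vp - (object@vg + object@ve)) > 1e-8 * max(1, object@vp))
    msg <- c(msg, "vp must equal vg + ve")
  if (object@h2 < 0 || object@h2 > 1) msg <- c(msg, "h2 must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (n = ", object@n, ")\n", sep = "")
  cat(sprintf("  V(G) %.4f (%.4f)   V(e) %.4f (%.4f)   V(p) %.4f (%.4f)\n",
              object@vg, object@se["vg"], object@ve, object@se["ve"],
              object@vp, object@se["vp"]))
  cat(sprintf("  h2   %.3f (%.3f)   LRT p = %.3g\n",
              object@h2, object@se["h2"], object@lrtP))
  if (object@degenerate) cat("  [degenerate: components not identifiable]\n")
  if (object@boundary) cat("  [boundary solution]\n")
})

#' DemingResult: orthogonal-regression comparison of two effect vectors
#'
#' @slot slope Deming slope.
#' @slot intercept Deming intercept.
#' @slot slopeCI 95\% CI for the slope (jackknife).
#' @slot interceptCI 95\% CI for the intercept (jackknife).
#' @slot lambda assumed error-variance ratio.
#' @slot n number of paired points.
#' @export
setClass("DemingResult", representation(
  slope = "numeric", intercept = "numeric", slopeCI = "numeric",
  interceptCI = "numeric", lambda = "numeric", n = "integer"))

setValidity("DemingResult", function(object) {
  if (object@lambda <= 0) return("lambda must be > 0")
  if (object@n < 3) return("need at least 3 points")
  TRUE
})

setMethod("show", "DemingResult", function(object) {
  cat(sprintf("Deming regression (lambda = %g, n = %d)\n  slope %.3f (%.3f-%.3f)  intercept %.4f (%.4f-%.4f)\n",
              object@lambda, object@n, object@slope, object@slopeCI[1],
              object@slopeCI[2], object@intercept, object@interceptCI[1],
              object@interceptCI[2]))
})

#' BootstrapResult: BCa contrast of two regression coefficients
#'
#' @slot observed observed difference betaA - betaB.
#' @slot ci BCa 95\% confidence interval.
#' @slot B number of bootstrap resamples.
#' @slot seed seed used.
#' @slot reject TRUE when the CI excludes 0 at alpha = 0.05.
#' @slot betaA,betaB the two observed coefficients.
#' @slot redrawn number of degenerate resamples that were redrawn.
#' @export
setClass("BootstrapResult", representation(
  observed = "numeric", ci = "numeric", B = "integer", seed = "integer",
  reject = "logical", betaA = "numeric", betaB = "numeric",
  redrawn = "integer"))

setValidity("BootstrapResult", function(object) {
  inCI <- object@ci[1] <= 0 && 0 <= object@ci[2]
  if (object@reject == inCI)
    return("reject flag must correspond to CI excluding 0")
  TRUE
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("Bootstrap contrast: diff %.4f, BCa 95%% CI (%.4f, %.4f), B = %d%s\n",
              object@observed, object@ci[1], object@ci[2], object@B,
              if (object@reject) "  [rejects equality]" else ""))
})
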