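## Genotype quality control: per-variant statistics (call rate, MAF, exact
## Hardy-Weinberg test), sample/variant filtering, the genomic relationship
## matrix, greedy relatedness exclusion, and principal components.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on genotype counts: given the observed allele
#' count, the probability of every possible heterozygote count is computed
#' and the two-sided p-value is the sum of probabilities not exceeding that
#' of the observed configuration. Well-defined at low counts, unlike the
#' chi-square approximation.
#'
#' @param nAA,nAa,naa genotype counts (AA homozygote, heterozygote, aa
#'   homozygote).
#' @return p-value in (0, 1\].
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("genotype counts must be >= 0")
  n <- nAA + nAa + naa
  if (n == 0) stop("no genotypes")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)  # monomorphic
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- hs * log(2) +
    lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  pObs <- pr[match(nAa, hs)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-9)]))
}

#' Per-variant quality-control statistics
#'
#' Call rate (fraction non-missing), minor allele frequency computed from
#' non-missing dosages only, and the exact HWE p-value on dosages rounded to
#' hard genotype calls. Variants with all genotypes missing are flagged
#' (`all_missing`) with undefined statistics.
#'
#' @param g a [GenotypeMatrix-class].
#' @return data.frame with columns `variant_id`, `call_rate`, `maf`, `hwe_p`,
#'   `all_missing`.
#' @export
computeVariantStats <- function(g) {
  d <- dosages(g)
  nonmiss <- rowSums(!is.na(d))
  callRate <- nonmiss / ncol(d)
  p <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hard <- round(d)
  hweP <- vapply(seq_len(nrow(d)), function(i) {
    if (nonmiss[i] == 0) return(NA_real_)
    x <- hard[i, ]
    hweExactTest(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                 sum(x == 0, na.rm = TRUE))
  }, 0)
  data.frame(variant_id = variantInfo(g)$variant_id, call_rate = callRate,
             maf = ifelse(nonmiss == 0, NA_real_, maf), hwe_p = hweP,
             all_missing = nonmiss == 0)
}

#' Apply the standard QC filter cascade
#'
#' Samples below the sample call-rate threshold are removed first, then
#' variants below the variant call-rate threshold, then exact-HWE failures,
#' then imputation-quality failures (only when an `info` rowData column is
#' present). Heterozygosity outliers (|F| beyond `hetSdFlag` SDs of the
#' inbreeding-coefficient distribution) are flagged, not removed.
#'
#' @param g a [GenotypeMatrix-class].
#' @param sampleCallMin,variantCallMin call-rate thresholds in \[0, 1\].
#' @param hwePMin exact-HWE p-value threshold.
#' @param infoMin imputation-quality threshold.
#' @param hetSdFlag SD multiple for the heterozygosity flag.
#' @return list with `genotypes` (filtered [GenotypeMatrix-class]), `report`
#'   (data.frame of per-step removal counts) and `hetOutliers` (flagged
#'   person ids).
#' @export
applyQCFilters <- function(g, sampleCallMin = 0.975, variantCallMin = 0.975,
                           hwePMin = 1e-5, infoMin = 0.8, hetSdFlag = 5) {
  for (thr in c(sampleCallMin, variantCallMin, hwePMin, infoMin))
    if (thr < 0 || thr > 1) stop("thresholds must lie in [0, 1]")
  d <- dosages(g)
  steps <- list()

  sampleCall <- colSums(!is.na(d)) / nrow(d)
  keepS <- sampleCall >= sampleCallMin
  if (!any(keepS)) stop("all samples removed by the sample call-rate filter")
  steps$sample_call_rate <- sum(!keepS)
  g <- g[, keepS]

  vs <- computeVariantStats(g)
  keepV <- !vs$all_missing & vs$call_rate >= variantCallMin
  steps$variant_call_rate <- sum(!keepV)
  g <- g[keepV, ]
  vs <- vs[keepV, ]

  keepH <- is.na(vs$hwe_p) | vs$hwe_p >= hwePMin
  steps$hwe <- sum(!keepH)
  g <- g[keepH, ]

  info <- variantInfo(g)$info
  if (!is.null(info)) {
    keepI <- is.na(info) | info > infoMin
    steps$info_score <- sum(!keepI)
    g <- g[keepI, ]
  } else steps$info_score <- 0L

  ## method-of-moments inbreeding coefficient per sample
  d <- dosages(g)
  p <- rowMeans(d, na.rm = TRUE) / 2
  expHet <- 2 * p * (1 - p)
  obsHet <- colMeans(round(d) == 1, na.rm = TRUE)
  fhat <- 1 - obsHet / mean(expHet)
  out <- abs(fhat - mean(fhat)) > hetSdFlag * stats::sd(fhat)
  hetOutliers <- personIds(g)[which(out)]

  report <- data.frame(step = names(steps),
                       removed = unlist(steps, use.names = FALSE),
                       remaining_variants = NA_integer_,
                       remaining_samples = NA_integer_)
  report$remaining_variants[nrow(report)] <- nrow(g)
  report$remaining_samples[nrow(report)] <- ncol(g)
  list(genotypes = g, report = report, hetOutliers = hetOutliers)
}

#' Genomic relationship matrix
#'
#' `A_jk = (1/m) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over the m variants with MAF >= `mafMin`; missing dosages are mean-imputed
#' to `2 p_i`. Allele frequencies are computed from the data.
#'
#' @param g a [GenotypeMatrix-class] (post-QC).
#' @param mafMin minimum minor allele frequency.
#' @return a [RelationshipMatrix-class].
#' @export
computeGRM <- function(g, mafMin = 0.01) {
  d <- dosages(g)
  p <- rowMeans(d, na.rm = TRUE) / 2
  keep <- pmin(p, 1 - p) >= mafMin & p > 0 & p < 1
  if (!any(keep)) stop("no variant left after the MAF filter")
  d <- d[keep, , drop = FALSE]
  p <- p[keep]
  z <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  z[is.na(z)] <- 0
  a <- crossprod(z) / nrow(z)
  new("RelationshipMatrix", a, nVariants = as.integer(nrow(z)))
}

#' Greedy relatedness exclusion
#'
#' While any pair of persons exceeds the relatedness threshold, one person is
#' removed: among the persons involved in the largest number of
#' over-threshold pairs, one is chosen uniformly at random (seeded). For
#' disjoint pairs this removes exactly one random member per pair.
#'
#' @param grm a [RelationshipMatrix-class] with person ids as dimnames.
#' @param threshold relatedness threshold (> 0); 0.177 approximates a
#'   second-degree cutoff for cohort construction, 0.025 is the conventional
#'   GREML cutoff.
#' @param seed integer seed for the tie-break.
#' @return character vector of retained person ids.
#' @export
excludeRelated <- function(grm, threshold = 0.025, seed = 1) {
  if (threshold <= 0) stop("threshold must be > 0")
  a <- as(grm, "matrix")
  ids <- rownames(a)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(a)))
  adj <- a > threshold
  diag(adj) <- FALSE
  set.seed(seed)
  alive <- rep(TRUE, nrow(a))
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    cand <- which(deg == max(deg))
    drop <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
    alive[drop] <- FALSE
    adj[drop, ] <- FALSE
    adj[, drop] <- FALSE
  }
  ids[alive]
}

#' Principal components of the genotype matrix
#'
#' Top-k components of the column-standardized (per-variant) dosage matrix;
#' missing dosages are mean-imputed and zero-variance variants dropped.
#' Component vectors are orthogonal; the sign convention makes each
#' component's largest-magnitude variant loading positive.
#'
#' @param g a [GenotypeMatrix-class].
#' @param k number of components (k < number of persons).
#' @return data.frame with `person_id` and columns `PC1..PCk`.
#' @export
computePCs <- function(g, k = 10) {
  d <- dosages(g)
  n <- ncol(d)
  if (k >= n) stop("k must be smaller than the number of persons")
  p <- rowMeans(d, na.rm = TRUE) / 2
  sdv <- sqrt(2 * p * (1 - p))
  keep <- sdv > 0
  z <- (d[keep, , drop = FALSE] - 2 * p[keep]) / sdv[keep]
  z[is.na(z)] <- 0
  kk <- tcrossprod(t(z))          # n x n
  eg <- eigen(kk, symmetric = TRUE)
  lam <- pmax(eg$values[seq_len(k)], 0)
  scores <- eg$vectors[, seq_len(k), drop = FALSE]
  ## fix signs from variant loadings v_j = Z u_j / sqrt(lambda_j)
  for (j in seq_len(k)) {
    if (lam[j] == 0) next
    load <- drop(z %*% scores[, j]) / sqrt(lam[j])
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  out <- data.frame(person_id = personIds(g),
                    scores %*% diag(sqrt(lam), k, k))
  names(out)[-1] <- paste0("PC", seq_len(k))
  out
}
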