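## Inferential core: phenotype ~ PGS regressions with covariates, the
## variance-explained formula, BCa bootstrap contrasts of PGS effects between
## phenotypes, fast per-variant effect estimation, and Deming (orthogonal)
## regression comparing two per-variant effect vectors.

alignCovariates <- function(personIds, covariates) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.data.frame(covariates)
  if (!"person_id" %in% names(covariates))
    stop("covariates need a person_id column")
  hit <- match(personIds, covariates$person_id)
  if (anyNA(hit)) stop("covariates missing for some persons")
  C <- covariates[hit, setdiff(names(covariates), "person_id"), drop = FALSE]
  ## expand factors (sex) to numeric dummies
  M <- stats::model.matrix(~ ., data = C)[, -1, drop = FALSE]
  rownames(M) <- NULL
  M
}

#' Regression of a phenotype on a scaled polygenic score
#'
#' Ordinary least squares of the BLUP phenotype on the standardized weighted
#' PGS plus covariates (conventionally baseline age, sex and the leading
#' principal components).
#'
#' @param phenotype data.frame with `person_id` and a phenotype column
#'   (named by `phenotypeName`, default the second column).
#' @param pgs score table from [computeScores()]/[scaleScores()].
#' @param covariates data.frame with `person_id` and covariate columns.
#' @param phenotypeName column of `phenotype` to use.
#' @return one-row data.frame: `predictor`, `phenotype`, `beta`, `se`,
#'   `ci_lo`, `ci_hi`, `p`, `n` for the PGS term.
#' @export
fitPgsRegression <- function(phenotype, pgs, covariates = NULL,
                             phenotypeName = NULL) {
  if (is.null(phenotypeName)) phenotypeName <- names(phenotype)[2]
  ids <- intersect(phenotype$person_id, pgs$person_id)
  y <- phenotype[[phenotypeName]][match(ids, phenotype$person_id)]
  x <- pgs$weighted[match(ids, pgs$person_id)]
  M <- alignCovariates(ids, covariates)
  keep <- stats::complete.cases(y, x, M)
  y <- y[keep]; x <- x[keep]
  if (!is.null(M)) M <- M[keep, , drop = FALSE]
  p <- if (is.null(M)) 0 else ncol(M)
  if (length(y) < p + 3) stop("too few complete cases")
  X <- cbind(1, x, M)
  if (qr(X)$rank < ncol(X)) stop("collinear covariates in the PGS regression")
  fit <- stats::lm.fit(X, y)
  df <- length(y) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  beta <- fit$coefficients[2]
  tcrit <- stats::qt(0.975, df)
  data.frame(predictor = "PGS", phenotype = phenotypeName, beta = beta,
             se = se, ci_lo = beta - tcrit * se, ci_hi = beta + tcrit * se,
             p = 2 * stats::pt(-abs(beta / se), df), n = length(y),
             row.names = NULL)
}

#' Percentage of phenotype variance explained by a score
#'
#' `100 * beta^2 * var(PGS) / var(phenotype)`. With the PGS standardized to
#' unit variance this is the squared beta over the phenotype variance, in
#' percent.
#'
#' @param beta regression coefficient per 1 SD of the PGS.
#' @param varPgs variance of the (scaled) PGS, usually 1.
#' @param varPhenotype variance of the phenotype.
#' @return percent of variance explained.
#' @export
varianceExplained <- function(beta, varPgs, varPhenotype) {
  if (varPgs <= 0 || varPhenotype <= 0) stop("variances must be positive")
  100 * beta^2 * varPgs / varPhenotype
}

## fast OLS coefficient of the second column (the PGS) given a design matrix
olsBeta2 <- function(X, y) unname(stats::lm.fit(X, y)$coefficients[2])

#' BCa bootstrap contrast of a PGS effect between two phenotypes
#'
#' Persons are resampled with replacement; in each resample both phenotype
#' regressions are refitted on the same persons and the difference of the
#' PGS coefficients recorded. The adjusted (bias-corrected and accelerated)
#' percentile interval uses the median-bias correction z0 from the fraction
#' of replicates below the observed difference, and acceleration from a
#' jackknife over persons. Resamples with a degenerate (constant) PGS are
#' redrawn and counted.
#'
#' @param phenoA,phenoB aligned numeric vectors (same persons).
#' @param pgs numeric vector of scaled scores for the same persons.
#' @param covariates optional numeric matrix of covariates (no intercept).
#' @param B number of resamples (warning below 200).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return a [BootstrapResult-class].
#' @export
bootstrapBetaDifference <- function(phenoA, phenoB, pgs, covariates = NULL,
                                    B = 2000, seed = 1, conf = 0.95) {
  if (B < 200) warning("B < 200 resamples: BCa interval will be unstable")
  n <- length(pgs)
  stopifnot(length(phenoA) == n, length(phenoB) == n)
  X <- cbind(1, pgs, covariates)
  diffStat <- function(idx) {
    if (stats::sd(pgs[idx]) == 0) return(NA_real_)
    Xi <- X[idx, , drop = FALSE]
    olsBeta2(Xi, phenoA[idx]) - olsBeta2(Xi, phenoB[idx])
  }
  t0 <- diffStat(seq_len(n))
  set.seed(seed)
  tb <- numeric(B)
  redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      v <- diffStat(sample.int(n, n, replace = TRUE))
      if (is.finite(v)) break
      redrawn <- redrawn + 1L
    }
    tb[b] <- v
  }
  alpha <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  if (stats::sd(tb) == 0) {
    ## degenerate case (e.g. identical phenotypes): the difference is exact
    ci <- c(t0, t0)
  } else {
    ## jackknife over persons for the acceleration constant
    tj <- vapply(seq_len(n), function(i) diffStat(seq_len(n)[-i]), 0)
    u <- mean(tj) - tj
    a <- if (sum(u^2) > 0) sum(u^3) / (6 * sum(u^2)^1.5) else 0
    z0 <- stats::qnorm((sum(tb < t0) + 0.5 * sum(tb == t0)) / B)
    zA <- stats::qnorm(alpha)
    adj <- stats::pnorm(z0 + (z0 + zA) / (1 - a * (z0 + zA)))
    ci <- unname(stats::quantile(tb, adj, type = 6))
  }
  new("BootstrapResult", observed = t0, ci = ci, B = as.integer(B),
      seed = as.integer(seed), reject = !(ci[1] <= 0 && 0 <= ci[2]),
      betaA = olsBeta2(X, phenoA), betaB = olsBeta2(X, phenoB),
      redrawn = redrawn)
}

#' Per-variant effect estimates
#'
#' One OLS fit per variant of the phenotype on the raw dosage (0-2 scale)
#' plus the covariate set, computed by residualizing phenotype and dosages on
#' the covariates (Frisch-Waugh), which is algebraically identical to the
#' full per-variant regression. Missing dosages are mean-imputed;
#' monomorphic variants are flagged and excluded.
#'
#' @param g a [GenotypeMatrix-class].
#' @param phenotype data.frame with `person_id` and one phenotype column.
#' @param covariates data.frame with `person_id` and covariate columns.
#' @param variantIds optional subset of variant ids (e.g. one score's SNVs).
#' @param phenotypeName phenotype column name (default second column).
#' @return data.frame with `variant_id`, `beta`, `se`, `p`, `excluded`.
#' @export
perSnvEffects <- function(g, phenotype, covariates = NULL,
                          variantIds = NULL, phenotypeName = NULL) {
  if (is.null(phenotypeName)) phenotypeName <- names(phenotype)[2]
  ids <- intersect(personIds(g), phenotype$person_id)
  y <- phenotype[[phenotypeName]][match(ids, phenotype$person_id)]
  d <- dosages(g)[, match(ids, personIds(g)), drop = FALSE]
  if (!is.null(variantIds))
    d <- d[match(variantIds, variantInfo(g)$variant_id), , drop = FALSE]
  if (anyNA(d)) {
    mu <- rowMeans(d, na.rm = TRUE)
    fill <- which(is.na(d), arr.ind = TRUE)
    d[fill] <- mu[fill[, 1]]
  }
  M <- alignCovariates(ids, covariates)
  C <- cbind(1, M)
  qrC <- qr(C)
  ry <- stats::lm.fit(C, y)$residuals
  rd <- t(d) - C %*% qr.coef(qrC, t(d))          # n x m residual dosages
  sxx <- colSums(rd^2)
  sxy <- drop(crossprod(rd, ry))
  ok <- sxx > 1e-10
  beta <- se <- p <- rep(NA_real_, ncol(rd))
  beta[ok] <- sxy[ok] / sxx[ok]
  df <- length(y) - ncol(C) - 1
  rss <- pmax(sum(ry^2) - beta[ok] * sxy[ok], 0)
  se[ok] <- sqrt(rss / df / sxx[ok])
  p[ok] <- 2 * stats::pt(-abs(beta[ok] / se[ok]), df)
  data.frame(variant_id = rownames(d), beta = beta, se = se, p = p,
             excluded = !ok, row.names = NULL)
}

#' Deming (errors-in-both-variables) regression of two effect vectors
#'
#' Closed-form fit with error-variance ratio `lambda` (lambda = 1 is
#' orthogonal regression): on centered data the slope is
#' `((Syy - lambda Sxx) + sqrt((Syy - lambda Sxx)^2 + 4 lambda Sxy^2)) /
#' (2 Sxy)` and the intercept `ybar - slope * xbar`. Confidence intervals are
#' by leave-one-point-out jackknife with a t reference. A slope CI excluding
#' 1 indicates systematically different effect magnitudes between the two
#' phenotypes.
#'
#' @param x,y paired effect estimates (>= 3 points).
#' @param lambda ratio of the y- to x- error variances (> 0).
#' @param conf confidence level.
#' @return a [DemingResult-class].
#' @export
demingFit <- function(x, y, lambda = 1, conf = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired points")
  if (lambda <= 0) stop("lambda must be > 0")
  core <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
    if (abs(sxy) < .Machine$double.eps * sqrt(sxx * syy + 1))
      stop("Sxy = 0: Deming slope undefined")
    slope <- ((syy - lambda * sxx) +
                sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
      (2 * sxy)
    c(slope = slope, intercept = mean(y) - slope * mean(x))
  }
  est <- core(x, y)
  jack <- vapply(seq_len(n), function(i) core(x[-i], y[-i]), c(0, 0))
  seJack <- sqrt((n - 1) / n * rowSums((jack - rowMeans(jack))^2))
  tcrit <- stats::qt(1 - (1 - conf) / 2, n - 2)
  new("DemingResult", slope = unname(est[1]), intercept = unname(est[2]),
      slopeCI = unname(est[1] + c(-1, 1) * tcrit * seJack[1]),
      interceptCI = unname(est[2] + c(-1, 1) * tcrit * seJack[2]),
      lambda = lambda, n = as.integer(n))
}
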