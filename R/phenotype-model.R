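## Longitudinal phenotype extraction.
##
## Each of the seven phenotypes (standardized mGFR, eGFRcr, eGFRcys,
## eGFRcr-cys, and the three bias series mGFR - eGFR) is modelled as a linear
## mixed model with a per-person random intercept, sex-specific nonlinear time
## trends (cubic B-spline basis in time interacted with sex), baseline age,
## the leading genotype principal components and their interactions with
## time. The per-person best linear unbiased predictor (BLUP) of the random
## intercept is the phenotype taken forward to the genetic analyses: it pools
## all of a person's visits and shrinks noisy person means toward zero, and
## because baseline age and the time trend are fixed effects the BLUPs are
## age-comparable across persons.

#' Standardize a pooled measurement series to zero mean and unit variance
#'
#' @param visits long-format visit data.frame.
#' @param measure column name to standardize.
#' @return numeric vector, `(x - mean) / sd` over all person-visits pooled.
#' @export
standardizeMeasure <- function(visits, measure) {
  x <- visits[[measure]]
  if (is.null(x)) stop("no column '", measure, "' in the visit table")
  if (length(unique(x[!is.na(x)])) < 2 || stats::sd(x, na.rm = TRUE) == 0)
    stop("'", measure, "' has (near-)zero variance; cannot standardize")
  (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
}

## Fixed-effect design: sex, sex-specific spline in time, baseline age,
## optional PCs and PC x time interactions. Returns the matrix without
## intercept column (added by the model formula).
buildFixedDesign <- function(visits, splineDf = 3, pcs = NULL, k = 10,
                             pcTime = TRUE) {
  if (splineDf < 1) stop("spline degrees of freedom must be >= 1")
  sexM <- as.numeric(visits$sex == "male")
  anyTrend <- length(unique(visits$time)) > 1
  X <- cbind(sex = sexM, age0 = visits$age0 - mean(visits$age0))
  if (anyTrend) {
    dfUse <- min(splineDf, length(unique(visits$time)) - 1)
    B <- splines::bs(visits$time, df = dfUse,
                     degree = min(3, dfUse))
    colnames(B) <- paste0("t", seq_len(ncol(B)))
    X <- cbind(X, B, B * sexM)
    colnames(X)[(ncol(X) - ncol(B) + 1):ncol(X)] <-
      paste0(colnames(B), ":male")
  }
  if (!is.null(pcs)) {
    k <- min(k, ncol(pcs) - 1)
    P <- as.matrix(pcs[match(visits$person_id, pcs$person_id),
                       paste0("PC", seq_len(k)), drop = FALSE])
    X <- cbind(X, P)
    if (pcTime && anyTrend) {
      PT <- P * visits$time
      colnames(PT) <- paste0("PC", seq_len(k), ":time")
      X <- cbind(X, PT)
    }
  }
  X
}

#' Fit a random-intercept mixed model for one measurement series
#'
#' REML fit of `y ~ fixed effects + (1 | person)` via [lme4::lmer()], with
#' the fixed-effect structure described in [buildFixedDesign()] (sex-specific
#' B-spline time trend, baseline age, PCs, PC x time).
#'
#' @param visits long-format visit data.frame (needs `person_id`, `sex`,
#'   `age0`, `time`).
#' @param response numeric vector aligned with `visits` rows (e.g. from
#'   [standardizeMeasure()]), or a column name.
#' @param splineDf spline degrees of freedom for the time trend.
#' @param pcs optional principal-component table from [computePCs()].
#' @param k number of PCs to adjust for.
#' @param pcTime include PC x time interactions.
#' @return an object of class `riModel`: list with the `lme4` fit, the
#'   variance components `tau2` (person intercept) and `sigma2` (residual),
#'   the REML log-likelihood and AIC.
#' @export
fitRandomInterceptModel <- function(visits, response, splineDf = 3,
                                    pcs = NULL, k = 10, pcTime = TRUE) {
  y <- if (is.character(response)) visits[[response]] else response
  if (length(y) != nrow(visits)) stop("response length must match visits")
  X <- buildFixedDesign(visits, splineDf, pcs, k, pcTime)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X) + 1), qrX$pivot[seq_len(qrX$rank)]) - 1]
    stop("rank-deficient fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  dat <- data.frame(y = y, person = visits$person_id, X, check.names = FALSE)
  form <- stats::reformulate(c(sprintf("`%s`", colnames(X)), "(1 | person)"),
                             response = "y")
  fit <- lme4::lmer(form, data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "person"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  structure(list(fit = fit, tau2 = tau2, sigma2 = sigma2,
                 loglik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit), nPersons = length(unique(dat$person)),
                 visits = visits),
            class = "riModel")
}

#' @export
print.riModel <- function(x, ...) {
  cat(sprintf("Random-intercept model: %d persons, tau2 = %.4f, sigma2 = %.4f, AIC = %.1f\n",
              x$nPersons, x$tau2, x$sigma2, x$aic))
  invisible(x)
}

#' Random-intercept shrinkage formula
#'
#' `BLUP_j = tau2 * S_j / (sigma2 + n_j * tau2)` where `S_j` is the sum of a
#' person's residuals from the fixed-effect fit and `n_j` their visit count.
#' Exposed for transparency; [extractBlups()] applies it through the fitted
#' model.
#'
#' @param residSum per-person sum of marginal residuals.
#' @param nVisits per-person visit counts.
#' @param tau2,sigma2 random-intercept and residual variances.
#' @return per-person BLUPs.
#' @export
blupShrinkage <- function(residSum, nVisits, tau2, sigma2) {
  tau2 * residSum / (sigma2 + nVisits * tau2)
}

#' Extract per-person BLUP phenotypes from a fitted model
#'
#' @param model an object from [fitRandomInterceptModel()].
#' @return data.frame with `person_id`, `blup`, `n_visits`; BLUPs average to
#'   ~0 across persons by construction.
#' @export
extractBlups <- function(model) {
  re <- lme4::ranef(model$fit)$person
  nv <- table(model$visits$person_id)
  data.frame(person_id = rownames(re), blup = re[["(Intercept)"]],
             n_visits = as.integer(nv[rownames(re)]), row.names = NULL)
}

#' Compare AIC with and without the person random intercept
#'
#' Both models are fitted by maximum likelihood so their AICs are comparable.
#' A large improvement (`deltaAic` well above ~4) indicates the series
#' carries a persistent per-person component rather than visit-level noise
#' only -- the justification for treating the mGFR - eGFR biases as
#' phenotypes in their own right.
#'
#' @inheritParams fitRandomInterceptModel
#' @return list with `aicRandom`, `aicFixed` and `deltaAic = aicFixed -
#'   aicRandom` (positive favours the random intercept).
#' @export
compareAicRandomEffects <- function(visits, response, splineDf = 3,
                                    pcs = NULL, k = 10, pcTime = TRUE) {
  y <- if (is.character(response)) visits[[response]] else response
  X <- buildFixedDesign(visits, splineDf, pcs, k, pcTime)
  dat <- data.frame(y = y, person = visits$person_id, X, check.names = FALSE)
  form <- stats::reformulate(c(sprintf("`%s`", colnames(X)), "(1 | person)"),
                             response = "y")
  fitR <- lme4::lmer(form, data = dat, REML = FALSE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
  fitF <- stats::lm(stats::reformulate(sprintf("`%s`", colnames(X)), "y"),
                    data = dat)
  aicR <- stats::AIC(fitR); aicF <- stats::AIC(fitF)
  list(aicRandom = aicR, aicFixed = aicF, deltaAic = aicF - aicR)
}

#' Residual skewness under identity and log transforms
#'
#' Fits the random-intercept model to the (optionally log-transformed)
#' series and reports the sample skewness of the marginal residuals --
#' the diagnostic behind analysing GFR phenotypes untransformed when the log
#' transform skews residuals further.
#'
#' @inheritParams fitRandomInterceptModel
#' @param transform `"none"` or `"log"` (values must be positive for log).
#' @return sample skewness of the model residuals.
#' @export
residualSkewness <- function(visits, response, transform = c("none", "log"),
                             splineDf = 3, pcs = NULL, k = 10,
                             pcTime = TRUE) {
  transform <- match.arg(transform)
  y <- if (is.character(response)) visits[[response]] else response
  if (transform == "log") {
    if (any(y <= 0, na.rm = TRUE))
      stop("log transform requires positive values")
    y <- log(y)
  }
  m <- fitRandomInterceptModel(visits, y, splineDf, pcs, k, pcTime)
  sampleSkewness(stats::residuals(m$fit))
}

#' Estimate all seven GFR phenotypes
#'
#' Standardizes mGFR and the three eGFRs over pooled person-visits, forms the
#' three per-visit bias series (standardized mGFR minus standardized eGFR),
#' fits the seven random-intercept models, and returns the per-person BLUPs.
#'
#' @param visits long-format visit data.frame including `mgfr` and the eGFR
#'   columns from [addEgfr()].
#' @inheritParams fitRandomInterceptModel
#' @return list with `phenotypes` (wide data.frame: `person_id`, `n_visits`
#'   and columns `mGFR`, `eGFRcr`, `eGFRcys`, `eGFRcrcys`, `bias_cr`,
#'   `bias_cys`, `bias_crcys`) and `models` (the seven `riModel` fits).
#' @export
estimatePhenotypes <- function(visits, splineDf = 3, pcs = NULL, k = 10,
                               pcTime = TRUE) {
  std <- list(mGFR = standardizeMeasure(visits, "mgfr"),
              eGFRcr = standardizeMeasure(visits, "egfrcr"),
              eGFRcys = standardizeMeasure(visits, "egfrcys"),
              eGFRcrcys = standardizeMeasure(visits, "egfrcrcys"))
  series <- c(std, list(bias_cr = std$mGFR - std$eGFRcr,
                        bias_cys = std$mGFR - std$eGFRcys,
                        bias_crcys = std$mGFR - std$eGFRcrcys))
  models <- lapply(series, function(y)
    fitRandomInterceptModel(visits, y, splineDf, pcs, k, pcTime))
  blups <- lapply(models, extractBlups)
  wide <- blups[[1]][c("person_id", "n_visits")]
  for (nm in names(blups))
    wide[[nm]] <- blups[[nm]]$blup[match(wide$person_id,
                                         blups[[nm]]$person_id)]
  list(phenotypes = wide, models = models)
}
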