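## Deterministic renal formulas: DuBois body surface area, BSA
## standardization, and the 2009 (creatinine) and 2012 (cystatin C,
## creatinine + cystatin C) CKD-EPI estimating equations.
##
## The race coefficient of the original publications is omitted entirely
## (constant 1): the package targets North European cohorts where it is inert.
## Creatinine is mg/dl and cystatin C mg/l throughout; a converter from
## micromol/l is provided for SI-reporting assays.

#' DuBois body surface area
#'
#' `0.007184 * weight^0.425 * height^0.725`.
#'
#' @param weight body weight in kg.
#' @param height height in cm.
#' @return body surface area in m^2.
#' @export
bsaDuBois <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive")
  0.007184 * weight^0.425 * height^0.725
}

#' Standardize an absolute GFR to 1.73 m^2 of body surface area
#'
#' @param gfr absolute GFR in ml/min.
#' @param bsa body surface area in m^2.
#' @return GFR in ml/min per 1.73 m^2.
#' @export
standardizeToBSA <- function(gfr, bsa) {
  if (any(bsa <= 0)) stop("bsa must be positive")
  gfr * 1.73 / bsa
}

#' Convert serum creatinine from micromol/l to mg/dl
#' @param scr_umol creatinine in micromol/l.
#' @return creatinine in mg/dl.
#' @export
scrFromUmol <- function(scr_umol) scr_umol / 88.4

checkAnalyte <- function(x, name) {
  if (is.null(x) || all(is.na(x)))
    stop("missing required analyte: ", name)
  if (any(x <= 0, na.rm = TRUE)) stop(name, " must be positive")
  invisible(x)
}

checkSex <- function(sex) {
  if (!all(sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  sex == "female"
}

#' CKD-EPI 2009 creatinine-based eGFR
#'
#' Piecewise power law with the published sex-stratified constants:
#' `144 * min(Scr/0.7, 1)^-0.329 * max(Scr/0.7, 1)^-1.209 * 0.993^age` for
#' women (144 being the tabulated 141 x 1.018) and
#' `141 * min(Scr/0.9, 1)^-0.411 * max(Scr/0.9, 1)^-1.209 * 0.993^age` for
#' men. No race term.
#'
#' @param scr serum creatinine, mg/dl.
#' @param age age in years.
#' @param sex "female" or "male" (vectorized).
#' @return eGFRcr in ml/min per 1.73 m^2.
#' @export
egfrCr2009 <- function(scr, age, sex) {
  checkAnalyte(scr, "serum creatinine")
  female <- checkSex(sex)
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- scr / kappa
  ifelse(female, 144, 141) * pmin(r, 1)^alpha * pmax(r, 1)^-1.209 * 0.993^age
}

#' CKD-EPI 2012 cystatin-C-based eGFR
#'
#' `133 * min(Scys/0.8, 1)^-0.499 * max(Scys/0.8, 1)^-1.328 * 0.996^age *
#' 0.932[female]`.
#'
#' @param scys serum cystatin C, mg/l.
#' @inheritParams egfrCr2009
#' @return eGFRcys in ml/min per 1.73 m^2.
#' @export
egfrCys2012 <- function(scys, age, sex) {
  checkAnalyte(scys, "cystatin C")
  female <- checkSex(sex)
  r <- scys / 0.8
  133 * pmin(r, 1)^-0.499 * pmax(r, 1)^-1.328 * 0.996^age *
    ifelse(female, 0.932, 1)
}

#' CKD-EPI 2012 combined creatinine-cystatin eGFR
#'
#' `135 * min(Scr/k, 1)^a * max(Scr/k, 1)^-0.601 * min(Scys/0.8, 1)^-0.375 *
#' max(Scys/0.8, 1)^-0.711 * 0.995^age * 0.969[female]` with k and a as in
#' the creatinine equation (a = -0.248 women / -0.207 men).
#'
#' @inheritParams egfrCr2009
#' @inheritParams egfrCys2012
#' @return eGFRcr-cys in ml/min per 1.73 m^2.
#' @export
egfrCrCys2012 <- function(scr, scys, age, sex) {
  checkAnalyte(scr, "serum creatinine")
  checkAnalyte(scys, "cystatin C")
  female <- checkSex(sex)
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.248, -0.207)
  rcr <- scr / kappa
  rcys <- scys / 0.8
  135 * pmin(rcr, 1)^alpha * pmax(rcr, 1)^-0.601 *
    pmin(rcys, 1)^-0.375 * pmax(rcys, 1)^-0.711 *
    0.995^age * ifelse(female, 0.969, 1)
}

#' Add the three eGFR columns to a visit table
#'
#' @param visits long-format visit data.frame with columns `scr`, `scys`,
#'   `age`, `sex`.
#' @return `visits` with `egfrcr`, `egfrcys`, `egfrcrcys` columns appended.
#' @export
addEgfr <- function(visits) {
  visits$egfrcr <- egfrCr2009(visits$scr, visits$age, visits$sex)
  visits$egfrcys <- egfrCys2012(visits$scys, visits$age, visits$sex)
  visits$egfrcrcys <- egfrCrCys2012(visits$scr, visits$scys, visits$age,
                                    visits$sex)
  visits
}

## Structural inversions of the above equations: the creatinine (cystatin)
## concentration that makes the estimating equation return exactly `gfr`
## for a given age and sex. Used by the cohort generator so that, in the
## noiseless zero-genetics limit, the estimating equations recover true GFR.
invertScr <- function(gfr, age, sex) {
  female <- checkSex(sex)
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  c0 <- ifelse(female, 144, 141) * 0.993^age
  ifelse(gfr <= c0, kappa * (gfr / c0)^(-1 / 1.209),
         kappa * (gfr / c0)^(1 / alpha))
}

invertScys <- function(gfr, age, sex) {
  female <- checkSex(sex)
  c0 <- 133 * 0.996^age * ifelse(female, 0.932, 1)
  ifelse(gfr <= c0, 0.8 * (gfr / c0)^(-1 / 1.328),
         0.8 * (gfr / c0)^(-1 / 0.499))
}
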