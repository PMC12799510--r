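## SNP heritability by restricted maximum likelihood on the genomic
## relationship matrix: y ~ N(X beta, vg * A + ve * I), maximized by
## average-information (AI) updates with EM fallback, after a one-time
## eigendecomposition of A that makes every iteration O(n p^2).
##
## The restricted log-likelihood used throughout is
##   lR = -1/2 [ log|V| + log|X' V^-1 X| + y' P y ]
## (additive constants omitted; they cancel in all likelihood-ratio
## comparisons with the same fixed-effect design).

#' Restricted maximum likelihood fit of the GRM variance-component model
#'
#' Estimates the genetic variance V(G), residual variance V(e) and
#' h2 = V(G)/V(p) for one phenotype given fixed covariates and a genomic
#' relationship matrix. Persons should be pre-filtered with
#' [excludeRelated()] (conventional threshold 0.025). Standard errors come
#' from the inverse average-information matrix (delta method for h2); the
#' h2 > 0 test is a boundary-corrected likelihood ratio against V(G) = 0.
#'
#' @param y numeric phenotype vector.
#' @param X covariate matrix (an intercept column is prepended); `NULL` for
#'   intercept only.
#' @param grm a [RelationshipMatrix-class] (or square matrix) aligned with
#'   `y`.
#' @param tol relative convergence tolerance.
#' @param maxIter iteration cap; non-convergence is an error of class
#'   `remlNonConvergence` carrying the iteration trajectory.
#' @param nEm number of initial EM iterations before AI updates.
#' @return a [VarianceComponents-class].
#' @export
remlFit <- function(y, X = NULL, grm, tol = 1e-6, maxIter = 100, nEm = 3) {
  a <- as(grm, "matrix")
  n <- length(y)
  if (nrow(a) != n) stop("GRM dimension does not match phenotype length")
  X <- if (is.null(X)) matrix(1, n, 1) else cbind(1, as.matrix(X))
  p <- ncol(X)
  if (n <= p + 2) stop("too few persons for the covariate set")

  eg <- eigen(a, symmetric = TRUE)
  d <- eg$values
  if (diff(range(d)) < 1e-8 * max(1, max(abs(d)))) {
    stop("degenerate GRM (proportional to identity): V(G) and V(e) are not identifiable")
  }
  yt <- drop(crossprod(eg$vectors, y))
  Xt <- crossprod(eg$vectors, X)

  floorV <- 1e-8 * stats::var(y)
  restricted <- function(vg, ve) {
    V <- vg * d + ve
    if (any(V <= 0)) return(list(ll = -Inf))
    W <- 1 / V
    XtW <- Xt * W
    XtVX <- crossprod(Xt, XtW)
    R <- chol(XtVX)
    XtWy <- drop(crossprod(XtW, yt))
    beta <- backsolve(R, backsolve(R, XtWy, transpose = TRUE))
    Py <- W * yt - XtW %*% beta
    ll <- -0.5 * (sum(log(V)) + 2 * sum(log(diag(R))) + sum(yt * Py))
    list(ll = ll, W = W, XtW = XtW, XtVX = XtVX, R = R, Py = drop(Py))
  }
  applyP <- function(st, v) {
    drop(st$W * v - st$XtW %*% backsolve(st$R, backsolve(
      st$R, drop(crossprod(st$XtW, v)), transpose = TRUE)))
  }
  trPM <- function(st, m) {  # tr(P diag(m))
    T1 <- crossprod(Xt * (st$W^2 * m), Xt)
    sum(st$W * m) - sum(diag(backsolve(st$R, backsolve(
      st$R, T1, transpose = TRUE))))
  }

  vy <- stats::var(y)
  theta <- c(vg = vy / 2, ve = vy / 2)
  traj <- data.frame(iter = integer(), vg = numeric(), ve = numeric(),
                     loglik = numeric(), step = character())
  st <- restricted(theta[1], theta[2])
  converged <- FALSE
  it <- 0
  emStep <- function(st, theta) {
    Py <- st$Py
    pmax(c(theta[1] + theta[1]^2 * (sum(Py * (d * Py)) - trPM(st, d)) / n,
           theta[2] + theta[2]^2 * (sum(Py * Py) - trPM(st, rep(1, n))) / n),
         floorV)
  }
  while (it < maxIter) {
    it <- it + 1
    Py <- st$Py
    dPy <- d * Py
    yPAPy <- sum(Py * dPy)
    yPIPy <- sum(Py * Py)
    grad <- -0.5 * c(trPM(st, d) - yPAPy, trPM(st, rep(1, n)) - yPIPy)
    if (it <= nEm) {
      step <- "EM"
      new <- emStep(st, theta)
    } else {
      step <- "AI"
      PdPy <- applyP(st, dPy)
      PPy <- applyP(st, Py)
      AI <- 0.5 * matrix(c(sum(dPy * PdPy), sum(dPy * PPy),
                           sum(dPy * PPy), sum(Py * PPy)), 2)
      new <- tryCatch(pmax(theta + solve(AI, grad), floorV),
                      error = function(e) NULL)
      if (is.null(new) || any(!is.finite(new))) {
        step <- "EM(fallback)"
        new <- emStep(st, theta)
      }
    }
    stNew <- restricted(new[1], new[2])
    if (!is.finite(stNew$ll) || (it > nEm && stNew$ll < st$ll - 1e-10)) {
      ## AI overshoot: halve toward the current point
      improved <- FALSE
      for (h in 1:8) {
        new <- (new + theta) / 2
        stNew <- restricted(new[1], new[2])
        if (is.finite(stNew$ll) && stNew$ll >= st$ll - 1e-10) {
          improved <- TRUE; break
        }
      }
      step <- paste0(step, "+halving")
      if (!improved) {
        ## EM rescue; EM is monotone, so failure to improve means we are at
        ## the (possibly boundary) optimum
        new <- emStep(st, theta)
        stNew <- restricted(new[1], new[2])
        if (!is.finite(stNew$ll) || stNew$ll < st$ll + 1e-10) {
          converged <- TRUE
          break
        }
        step <- "EM(rescue)"
      }
    }
    traj <- rbind(traj, data.frame(iter = it, vg = new[1], ve = new[2],
                                   loglik = stNew$ll, step = step))
    delta <- max(abs(new - theta) / (abs(theta) + 1e-8))
    dll <- stNew$ll - st$ll
    theta <- unname(new)
    st <- stNew
    if (it > nEm && (delta < tol || abs(dll) < 1e-9)) {
      converged <- TRUE; break
    }
  }
  if (!converged) {
    ## profile rescue: for a fixed ratio g = vg/ve the scale has a closed
    ## form, leaving a 1-D restricted likelihood in log(g); slow AI/EM
    ## crawls along the (vg, ve) ridge collapse onto this profile
    profLl <- function(lg) {
      k <- exp(lg) * d + 1
      W <- 1 / k
      XtVX <- crossprod(Xt, Xt * W)
      R <- chol(XtVX)
      beta <- backsolve(R, backsolve(R, drop(crossprod(Xt * W, yt)),
                                     transpose = TRUE))
      q <- sum(yt * (W * yt - (Xt * W) %*% beta))
      ve <- q / (n - p)
      -0.5 * (sum(log(k)) + n * log(ve) + 2 * sum(log(diag(R))) -
                p * log(ve) + (n - p))
    }
    opt <- stats::optimize(profLl, c(-16, 16), maximum = TRUE, tol = 1e-10)
    gam <- exp(opt$maximum)
    k <- gam * d + 1
    W <- 1 / k
    XtVX <- crossprod(Xt, Xt * W)
    R <- chol(XtVX)
    beta <- backsolve(R, backsolve(R, drop(crossprod(Xt * W, yt)),
                                   transpose = TRUE))
    veProf <- sum(yt * (W * yt - (Xt * W) %*% beta)) / (n - p)
    cand <- pmax(c(gam * veProf, veProf), floorV)
    stCand <- restricted(cand[1], cand[2])
    if (is.finite(stCand$ll) && stCand$ll >= st$ll - 1e-6) {
      theta <- cand
      st <- stCand
      converged <- TRUE
    } else {
      cond <- structure(class = c("remlNonConvergence", "error", "condition"),
                        list(message = sprintf(
                          "REML did not converge in %d iterations", maxIter),
                          call = sys.call(-1), trajectory = traj))
      stop(cond)
    }
  }

  vg <- theta[1]; ve <- theta[2]; vp <- vg + ve
  boundary <- vg <= floorV * 1.01 || ve <= floorV * 1.01
  ## SEs from the inverse AI matrix at the optimum
  Py <- st$Py; dPy <- d * Py
  PdPy <- applyP(st, dPy); PPy <- applyP(st, Py)
  AI <- 0.5 * matrix(c(sum(dPy * PdPy), sum(dPy * PPy),
                       sum(dPy * PPy), sum(Py * PPy)), 2)
  cv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  seVg <- sqrt(cv[1, 1]); seVe <- sqrt(cv[2, 2])
  seVp <- sqrt(cv[1, 1] + cv[2, 2] + 2 * cv[1, 2])
  gradH <- c(ve, -vg) / vp^2
  seH2 <- sqrt(drop(gradH %*% cv %*% gradH))

  ## null model: vg = 0, V = ve I; profiled REML
  rss <- sum(stats::lm.fit(Xt, yt)$residuals^2)
  veNull <- rss / (n - p)
  XtX <- crossprod(Xt)
  llNull <- -0.5 * ((n - p) * log(veNull) + determinant(XtX)$modulus[1] +
                      (n - p))
  llFull <- st$ll
  lrtP <- lrtPvalue(llFull, llNull)
  waldP <- if (is.finite(seVg)) stats::pnorm(vg / seVg, lower.tail = FALSE)
           else NA_real_

  new("VarianceComponents", vg = vg, ve = ve, vp = vp, h2 = vg / vp,
      se = c(vg = seVg, ve = seVe, vp = seVp, h2 = seH2),
      loglik = llFull, loglikNull = llNull, lrtP = lrtP, waldP = waldP,
      iterations = as.integer(it), converged = converged,
      boundary = boundary, degenerate = FALSE, n = as.integer(n))
}

#' Heritability ratio for reporting
#'
#' `V(G) / V(p)`, rounded to two decimals as conventionally reported.
#'
#' @param vg genetic variance (0 <= vg <= vp).
#' @param vp phenotypic variance (> 0).
#' @return h2 rounded to 2 decimals.
#' @export
heritabilityRatio <- function(vg, vp) {
  if (any(vp <= 0)) stop("vp must be > 0")
  if (any(vg < 0) || any(vg > vp)) stop("require 0 <= vg <= vp")
  round(vg / vp, 2)
}

#' Boundary-corrected likelihood-ratio p-value for h2 > 0
#'
#' The null V(G) = 0 lies on the parameter boundary, so the LRT statistic is
#' referred to a 50:50 mixture of a point mass at zero and chi-square with
#' 1 df: `p = 0.5 * P(chisq_1 >= 2 * delta) + 0.5 * 1[delta = 0]`.
#'
#' @param loglikFull restricted log-likelihood of the full model.
#' @param loglikNull restricted log-likelihood with V(G) = 0.
#' @return p-value.
#' @export
lrtPvalue <- function(loglikFull, loglikNull) {
  delta <- loglikFull - loglikNull
  if (delta < -1e-6) stop("full-model likelihood below the null likelihood")
  delta <- max(delta, 0)
  0.5 * stats::pchisq(2 * delta, 1, lower.tail = FALSE) +
    0.5 * (delta == 0)
}
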