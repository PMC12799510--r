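makeAssocData <- function(n = 200, betaPgs = 0.2, noise = 0, seed = 1) {
  set.seed(seed)
  pgs <- data.frame(person_id = sprintf("P%04d", 1:n),
                    weighted = rnorm(n), unweighted = 0, n_variants = 10)
  covar <- data.frame(person_id = pgs$person_id, age0 = rnorm(n, 58, 4),
                      sex = sample(c("female", "male"), n, TRUE))
  y <- betaPgs * pgs$weighted + 0.02 * covar$age0 +
    0.3 * (covar$sex == "male") + rnorm(n, 0, noise)
  list(phen = data.frame(person_id = pgs$person_id, mGFR = y),
       pgs = pgs, covar = covar)
}

test_that("PGS regression recovers a noiseless coefficient exactly", {
  d <- makeAssocData(betaPgs = 0.2, noise = 0)
  est <- fitPgsRegression(d$phen, d$pgs, d$covar)
  expect_equal(est$beta, 0.2, tolerance = 1e-8)
  expect_true(est$ci_lo <= est$beta && est$beta <= est$ci_hi)
  bad <- d$covar
  bad$dup <- bad$age0
  expect_error(fitPgsRegression(d$phen, d$pgs, bad), "collinear")
})

test_that("PGS regression matches the normal-equations oracle", {
  d <- makeAssocData(betaPgs = 0.15, noise = 0.7, seed = 3)
  est <- fitPgsRegression(d$phen, d$pgs, d$covar)
  X <- cbind(1, d$pgs$weighted, d$covar$age0,
             as.numeric(d$covar$sex == "male"))
  betaHat <- solve(crossprod(X), crossprod(X, d$phen$mGFR))
  expect_equal(est$beta, betaHat[2], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("null PGS coefficients are calibrated against their SE", {
  hits <- 0L
  for (r in 1:60) {
    d <- makeAssocData(betaPgs = 0, noise = 1, seed = 100 + r)
    est <- fitPgsRegression(d$phen, d$pgs, d$covar)
    if (abs(est$beta) < 3 * est$se) hits <- hits + 1L
  }
  expect_gte(hits, 57)   # ~99.7% expected under the null
})

test_that("variance-explained formula reproduces printed-table arithmetic", {
  expect_equal(round(varianceExplained(0.20, 1, 0.41), 1), 9.8)
  expect_equal(varianceExplained(0, 1, 0.41), 0)
  expect_equal(varianceExplained(1, 0.3, 0.3), 100)
  expect_error(varianceExplained(0.2, 0, 1), "positive")
})

test_that("variance explained equals incremental R2 on residual variance", {
  d <- makeAssocData(betaPgs = 0.25, noise = 0.6, seed = 5)
  X0 <- cbind(1, d$covar$age0, as.numeric(d$covar$sex == "male"))
  r0 <- lm.fit(X0, d$phen$mGFR)$residuals
  r1 <- lm.fit(cbind(X0, d$pgs$weighted), d$phen$mGFR)$residuals
  incR2 <- 100 * (sum(r0^2) - sum(r1^2)) / sum(r0^2)
  est <- fitPgsRegression(d$phen, d$pgs, d$covar)
  rp <- lm.fit(X0, d$pgs$weighted)$residuals
  ve <- varianceExplained(est$beta, var(rp), var(r0))
  expect_equal(ve, incR2, tolerance = 1e-6)
})

test_that("bootstrap contrast: self-comparison, determinism, and power", {
  set.seed(6)
  n <- 250
  pgs <- rnorm(n)
  covm <- cbind(rnorm(n))
  yA <- 0.3 * pgs + rnorm(n)
  b <- bootstrapBetaDifference(yA, yA, pgs, covm, B = 300, seed = 2)
  expect_equal(b@observed, 0)
  expect_false(b@reject)

  b1 <- bootstrapBetaDifference(yA, 0.5 * yA, pgs, covm, B = 300, seed = 2)
  b2 <- bootstrapBetaDifference(yA, 0.5 * yA, pgs, covm, B = 300, seed = 2)
  expect_identical(b1@ci, b2@ci)

  # a real difference of 0.3 at n = 1500 is detected
  hits <- 0L
  for (r in 1:5) {
    set.seed(600 + r)
    nn <- 1500
    x <- rnorm(nn)
    e <- rnorm(nn)
    ya <- 0.4 * x + e
    yb <- 0.1 * x + e + rnorm(nn, 0, 0.3)
    bb <- bootstrapBetaDifference(ya, yb, x, NULL, B = 300, seed = r)
    if (bb@reject) hits <- hits + 1L
  }
  expect_gte(hits, 4)
  expect_warning(bootstrapBetaDifference(yA, yA, pgs, covm, B = 100,
                                         seed = 1), "unstable")
})

test_that("own BCa interval agrees with the boot-package oracle", {
  skip_if_not_installed("boot")
  set.seed(12)
  n <- 150
  x <- rnorm(n)
  yA <- 0.3 * x + rnorm(n)
  yB <- 0.25 * x + rnorm(n)
  ours <- bootstrapBetaDifference(yA, yB, x, NULL, B = 4000, seed = 7)
  X <- cbind(1, x)
  set.seed(7)
  bb <- boot::boot(seq_len(n), function(d, i) {
    Xi <- X[i, , drop = FALSE]
    lm.fit(Xi, yA[i])$coefficients[2] - lm.fit(Xi, yB[i])$coefficients[2]
  }, R = 4000)
  oracle <- boot::boot.ci(bb, type = "bca")$bca[4:5]
  width <- oracle[2] - oracle[1]
  expect_lt(abs(ours@ci[1] - oracle[1]), 0.15 * width)
  expect_lt(abs(ours@ci[2] - oracle[2]), 0.15 * width)
})

test_that("per-variant effects match the single-regression oracle", {
  set.seed(8)
  m <- 15; n <- 120
  d <- matrix(rbinom(m * n, 2, 0.35), nrow = m)
  d[1, ] <- 1   # monomorphic after centering -> flagged
  vi <- data.frame(variant_id = paste0("rs", 1:m),
                   chrom = as.character(rep(1, m)), pos = 1:m,
                   ref = "A", alt = "G")
  g <- GenotypeMatrix(d, vi)
  covar <- data.frame(person_id = personIds(g), age0 = rnorm(n, 58, 4),
                      sex = sample(c("female", "male"), n, TRUE))
  y <- 0.1 * d[3, ] + 0.02 * covar$age0 + rnorm(n, 0, 0.5)
  phen <- data.frame(person_id = personIds(g), mGFR = y)
  eff <- perSnvEffects(g, phen, covar)
  expect_true(eff$excluded[1])
  for (i in c(2, 3, 7)) {
    fit <- summary(lm(y ~ d[i, ] + covar$age0 + I(covar$sex == "male")))
    expect_equal(eff$beta[i], fit$coefficients[2, 1], tolerance = 1e-8)
    expect_equal(eff$se[i], fit$coefficients[2, 2], tolerance = 1e-8)
  }

  # noiseless injected effect is recovered exactly
  y0 <- 0.1 * d[3, ] + 0.5 * (covar$sex == "male")
  eff0 <- perSnvEffects(g, data.frame(person_id = personIds(g), mGFR = y0),
                        covar)
  expect_equal(eff0$beta[3], 0.1, tolerance = 1e-8)
})

test_that("Deming fit: exact line, swap symmetry, and the orthogonal oracle", {
  x <- c(-2, -1, 0, 1.5, 3)
  dm <- demingFit(x, 2 * x)
  expect_equal(dm@slope, 2, tolerance = 1e-12)
  expect_equal(dm@intercept, 0, tolerance = 1e-12)

  set.seed(9)
  xx <- rnorm(40); yy <- 1.3 * xx + 0.1 + rnorm(40, 0, 0.3)
  a <- demingFit(xx, yy)@slope
  b <- demingFit(yy, xx)@slope
  expect_equal(a, 1 / b, tolerance = 1e-10)

  # brute-force minimizer of summed orthogonal distances
  orth <- function(par) {
    s <- par[1]; i0 <- par[2]
    sum((yy - s * xx - i0)^2) / (1 + s^2)
  }
  opt <- optim(c(1, 0), orth, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(demingFit(xx, yy)@slope, opt$par[1], tolerance = 1e-4)

  # total least squares via the smallest singular direction
  M <- cbind(xx - mean(xx), yy - mean(yy))
  v <- svd(M)$v[, 2]
  expect_equal(demingFit(xx, yy)@slope, -v[1] / v[2], tolerance = 1e-10)

  expect_error(demingFit(c(1, 2), c(1, 2)), "3")
  expect_error(demingFit(c(-1, 0, 1), c(0, 0, 0)), "undefined")
})
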