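test_that("standardizeMeasure centers, scales, and is affine-invariant", {
  v <- data.frame(mgfr = c(80, 95, 110, 70, 100))
  s <- standardizeMeasure(v, "mgfr")
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(sd(s), 1, tolerance = 1e-12)
  v2 <- data.frame(mgfr = 3 * v$mgfr - 40)
  expect_equal(standardizeMeasure(v2, "mgfr"), s, tolerance = 1e-12)
  expect_equal(s - s, rep(0, 5))   # bias of a measure with itself
  expect_error(standardizeMeasure(data.frame(mgfr = rep(1, 5)), "mgfr"),
               "variance")
})

test_that("random-intercept variance is recovered on simulated data", {
  dat <- riToyData(500, visits = 3, tau2 = 0.5, sigma2 = 0.25, seed = 2)
  m <- fitRandomInterceptModel(dat, dat$y)
  expect_lt(abs(m$tau2 - 0.5), 0.1)
  expect_lt(abs(m$sigma2 - 0.25), 0.05)
})

test_that("the no-shrinkage limit returns per-person mean deviations", {
  dat <- riToyData(80, visits = 3, tau2 = 1, sigma2 = 1e-6, seed = 3)
  m <- fitRandomInterceptModel(dat, dat$y)
  b <- extractBlups(m)
  fe <- predict(m$fit, re.form = NA)
  dev <- tapply(dat$y - fe, dat$person_id, mean)
  expect_equal(b$blup, as.numeric(dev[b$person_id]), tolerance = 1e-4)
})

test_that("the shrinkage formula reproduces the hand-computed example", {
  # tau2 = 1, sigma2 = 1; residual sums {+2 over 2 visits} and {+2 over 1}
  expect_equal(blupShrinkage(c(2, 2), c(2, 1), 1, 1), c(2 / 3, 1))
  # fewer visits with the same mean residual means more shrinkage
  expect_lt(blupShrinkage(1, 1, 0.5, 0.5), blupShrinkage(3, 3, 0.5, 0.5))
})

test_that("BLUPs are centered and deterministic", {
  dat <- riToyData(120, visits = 3, seed = 4)
  m <- fitRandomInterceptModel(dat, dat$y)
  b1 <- extractBlups(m)
  expect_lt(abs(mean(b1$blup)), 1e-6 * sd(b1$blup))
  expect_lte(var(b1$blup),
             var(tapply(residuals(lm(dat$y ~ 1)), dat$person_id, mean)))
  b2 <- extractBlups(fitRandomInterceptModel(dat, dat$y))
  expect_identical(b1, b2)
})

test_that("phenotype extraction commutes with person relabeling", {
  dat <- riToyData(60, visits = 3, seed = 12)
  b1 <- extractBlups(fitRandomInterceptModel(dat, dat$y))
  relab <- dat
  map <- setNames(sprintf("Q%04d", seq_len(60)),
                  sprintf("P%04d", seq_len(60)))
  relab$person_id <- unname(map[dat$person_id])
  b2 <- extractBlups(fitRandomInterceptModel(relab, relab$y))
  expect_equal(b2$blup[match(map[b1$person_id], b2$person_id)], b1$blup,
               tolerance = 1e-8)
})

test_that("AIC improves strongly with a persistent person component and not under the null", {
  persistent <- riToyData(200, visits = 3, tau2 = 0.5, sigma2 = 0.5, seed = 5)
  cmp <- compareAicRandomEffects(persistent, persistent$y)
  expect_gt(cmp$deltaAic, 10)

  noise <- riToyData(200, visits = 3, tau2 = 0, sigma2 = 1, seed = 6)
  cmp0 <- compareAicRandomEffects(noise, noise$y)
  expect_lte(cmp0$deltaAic, 4)

  shifted <- compareAicRandomEffects(noise, noise$y + 100)
  expect_equal(shifted$deltaAic, cmp0$deltaAic, tolerance = 1e-6)
})

test_that("residual skewness diagnoses the log-transform decision", {
  dat <- riToyData(340, visits = 3, tau2 = 0, sigma2 = 1, seed = 7)
  expect_lt(abs(residualSkewness(dat, dat$y)), 0.15)

  # right-skewed lognormal response: log brings residual skewness toward 0
  dat$z <- exp(dat$y)
  skRaw <- residualSkewness(dat, "z", transform = "none")
  skLog <- residualSkewness(dat, "z", transform = "log")
  expect_lt(abs(skLog), abs(skRaw))
  dat$neg <- dat$y - 100
  expect_error(residualSkewness(dat, "neg", transform = "log"), "positive")
  dat$const <- 1
  suppressWarnings(expect_error(residualSkewness(dat, "const"),
                                "constant|rank"))
})

test_that("BLUP phenotypes track the latent person intercept better than baseline alone", {
  cfg <- simConfig(nIndividuals = 400, nVariants = 200, nRelatedPairs = 0,
                   seed = 23)
  arch <- simulateArchitecture(cfg)
  g <- simulateGenotypes(cfg, arch)
  v <- addEgfr(simulateCohort(g, arch, cfg))
  ph <- estimatePhenotypes(v)
  tr <- attr(v, "truth")
  ids <- ph$phenotypes$person_id
  truth <- tr$intercept[match(ids, tr$person_id)]
  base <- v[v$visit == 1, ]
  base <- base[match(ids, base$person_id), ]
  # compare on the same footing: the BLUP already has sex/age as fixed
  # effects, so residualize the single-visit measurement and the latent
  # intercept on them too
  sexAge <- model.matrix(~ sex + age0, base)
  truthAdj <- lm.fit(sexAge, truth)$residuals
  baselineAdj <- lm.fit(sexAge, base$mgfr)$residuals
  expect_gt(cor(ph$phenotypes$mGFR, truthAdj), cor(baselineAdj, truthAdj))
  # all 7 phenotype columns present and centered
  for (nm in c("mGFR", "eGFRcr", "eGFRcys", "eGFRcrcys", "bias_cr",
               "bias_cys", "bias_crcys"))
    expect_lt(abs(mean(ph$phenotypes[[nm]], na.rm = TRUE)), 0.05)
})
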