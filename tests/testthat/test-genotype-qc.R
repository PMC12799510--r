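test_that("exact HWE test matches hand cases and the paper-scale thresholds", {
  expect_gte(hweExactTest(25, 50, 25), 0.9)   # perfect HWE proportions
  expect_lt(hweExactTest(50, 0, 50), 1e-5)    # total heterozygote deficit
  expect_equal(hweExactTest(30, 0, 0), 1)     # monomorphic
  expect_error(hweExactTest(-1, 0, 1), ">= 0")
})

test_that("exact HWE test agrees with the enumeration oracle for n <= 50", {
  set.seed(8)
  for (rep in 1:60) {
    n <- sample(3:50, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hweExactTest(nAA, nAa, naa), hweEnumOracle(nAA, nAa, naa),
                 tolerance = 1e-10,
                 info = sprintf("counts (%d,%d,%d)", nAA, nAa, naa))
  }
})

test_that("variant statistics use non-missing dosages only", {
  d <- rbind(c(0, 1, 2, NA, 1), c(2, 2, 2, 2, 2), rep(NA_real_, 5))
  vs <- computeVariantStats(toyGenotypes(d))
  expect_equal(vs$call_rate, c(0.8, 1, 0))
  expect_equal(vs$maf[1], mean(c(0, 1, 2, 1)) / 2)
  expect_equal(vs$maf[2], 0)       # monomorphic: MAF 0
  expect_equal(vs$hwe_p[2], 1)
  expect_true(vs$all_missing[3])
})

test_that("the QC cascade removes samples, then variants, then HWE failures", {
  set.seed(3)
  d <- matrix(rbinom(10 * 12, 2, 0.4), nrow = 10)
  d[sample(10, 6), 3] <- NA             # person 3: 60% missing
  g <- toyGenotypes(d)
  qc <- applyQCFilters(g)
  expect_equal(ncol(qc$genotypes), 11)
  expect_false("P00003" %in% personIds(qc$genotypes))
  expect_equal(qc$report$removed[qc$report$step == "sample_call_rate"], 1)

  # HWE-failing variant (50/0/50 in n=100) is removed at the HWE step
  d2 <- rbind(matrix(rbinom(5 * 100, 2, 0.5), nrow = 5),
              c(rep(0, 50), rep(2, 50)))
  qc2 <- applyQCFilters(toyGenotypes(d2))
  expect_equal(nrow(qc2$genotypes), 5)
  expect_equal(qc2$report$removed[qc2$report$step == "hwe"], 1)

  # clean input passes through unchanged, and the filter is idempotent
  qc3 <- applyQCFilters(toyGenotypes(d2[1:5, ]))
  expect_identical(dosages(qc3$genotypes), dosages(toyGenotypes(d2[1:5, ])))
  qc4 <- applyQCFilters(qc2$genotypes)
  expect_identical(dosages(qc4$genotypes), dosages(qc2$genotypes))
})

test_that("GRM matches its formula and algebraic identities", {
  # hand case: one variant, p = 0.5, dosages (2, 0):
  # z = (x - 1)/sqrt(0.5) -> A = [[2,-2],[-2,2]]
  g <- toyGenotypes(matrix(c(2, 0), nrow = 1))
  a <- computeGRM(g, mafMin = 0)
  expect_equal(unname(as(a, "matrix")), matrix(c(2, -2, -2, 2), 2),
               tolerance = 1e-12)

  # duplicated individual: off-diagonal equals the shared diagonal
  set.seed(4)
  d <- matrix(rbinom(300 * 40, 2, runif(300, 0.1, 0.5)), nrow = 300)
  d <- cbind(d, d[, 1])
  a2 <- as(computeGRM(toyGenotypes(d)), "matrix")
  n <- ncol(d)
  expect_equal(a2[1, n], a2[1, 1], tolerance = 1e-12)
  expect_equal(a2[1, n], a2[n, n], tolerance = 1e-12)

  # unrelated cohort: mean diagonal ~ 1
  cfg <- simConfig(nIndividuals = 200, nVariants = 2000, nRelatedPairs = 0,
                   seed = 6)
  a3 <- computeGRM(simulateGenotypes(cfg))
  expect_gt(mean(diag(as(a3, "matrix"))), 0.95)
  expect_lt(mean(diag(as(a3, "matrix"))), 1.05)
})

test_that("GRM is equivariant to person order and invariant to variant order", {
  set.seed(5)
  d <- matrix(rbinom(100 * 30, 2, 0.3), nrow = 100)
  g <- toyGenotypes(d)
  a <- as(computeGRM(g), "matrix")
  pv <- sample(100); pp <- sample(30)
  aPerm <- as(computeGRM(toyGenotypes(d[pv, pp])), "matrix")
  expect_equal(unname(aPerm), unname(a[pp, pp]), tolerance = 1e-12)
})

test_that("greedy relatedness exclusion handles pairs, cliques and identity", {
  # 1617 persons with 125 disjoint over-threshold pairs -> 1492 retained
  n <- 1617
  a <- diag(n)
  for (i in seq_len(125)) {
    a[2 * i - 1, 2 * i] <- 0.5
    a[2 * i, 2 * i - 1] <- 0.5
  }
  rownames(a) <- colnames(a) <- sprintf("P%04d", seq_len(n))
  grm <- new("RelationshipMatrix", a, nVariants = 1000L)
  expect_length(excludeRelated(grm, threshold = 0.177, seed = 1), 1492)

  # nothing over threshold: everyone retained
  expect_length(excludeRelated(new("RelationshipMatrix", diag(10),
                                   nVariants = 10L), 0.177), 10)

  # 3-clique: one survivor
  tri <- matrix(0.5, 3, 3); diag(tri) <- 1
  expect_length(excludeRelated(new("RelationshipMatrix", tri,
                                   nVariants = 10L), 0.177), 1)
})

test_that("principal components separate structured subpopulations", {
  set.seed(7)
  m <- 400; n <- 120
  p1 <- runif(m, 0.1, 0.5)
  p2 <- pmin(pmax(p1 + rnorm(m, 0, 0.12), 0.02), 0.98)
  d <- cbind(matrix(rbinom(m * n / 2, 2, p1), nrow = m),
             matrix(rbinom(m * n / 2, 2, p2), nrow = m))
  g <- toyGenotypes(d)
  pcs <- computePCs(g, k = 4)
  pop <- rep(0:1, each = n / 2)
  expect_gt(abs(cor(pcs$PC1, pop)), 0.9)

  s <- as.matrix(pcs[, -1])
  cp <- crossprod(s)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)

  perm <- sample(n)
  pcsP <- computePCs(g[, perm], k = 4)
  expect_equal(as.matrix(pcsP[, -1]), s[perm, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(computePCs(g, k = n), "smaller")
})
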