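scoreFileLines <- function() {
  c("# pgs_id=PGS_TEST",
    "# trait=eGFR",
    paste("rsID", "chr_name", "chr_position", "effect_allele", "other_allele",
          "effect_weight", sep = "\t"),
    paste("rs1", "1", "100", "G", "A", "0.10", sep = "\t"),
    paste("rs2", "2", "200", "A", "G", "0.00", sep = "\t"),
    paste("rs3", "3", "300", "G", "A", "-0.20", sep = "\t"),
    paste("rs4", "MT", "400", "G", "A", "0.30", sep = "\t"),
    paste("rs5", "X", "500", "G", "A", "0.00", sep = "\t"),
    paste("rs6", "4", "600", "G", "A", "0.05", sep = "\t"))
}

test_that("scoring-file parsing drops zero weights and non-autosomal rows", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(scoreFileLines(), path)
  s <- readScoreFile(path)
  expect_s4_class(s, "ScoreSet")
  expect_equal(s@name, "PGS_TEST")
  expect_equal(nrow(scoreVariants(s)), 3)     # 6 rows - 2 zero - 1 MT
  expect_equal(harmonizationLog(s)$parse$zero_weight, 2)
  expect_equal(harmonizationLog(s)$parse$non_autosomal, 1)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("rsID\tchr_name", "rs1\t1"), bad)
  expect_error(readScoreFile(bad), "effect_weight|effect_allele")
})

test_that("write/parse round trip preserves weights to full precision", {
  v <- data.frame(rsID = c("rs1", "rs2"), chr_name = c("1", "2"),
                  chr_position = c(10L, 20L), effect_allele = c("G", "T"),
                  other_allele = c("A", "C"),
                  effect_weight = c(0.123456789012345, -1 / 3))
  s <- ScoreSet(v, name = "RT")
  path <- withr::local_tempfile(fileext = ".txt")
  writeScoreFile(s, path)
  s2 <- readScoreFile(path)
  expect_identical(scoreVariants(s2)$effect_weight, v$effect_weight)
})

test_that("harmonization matches, flips, and reports integer coverage", {
  d <- matrix(c(2, 1, 0,
                1, 0, 2,
                0, 2, 1), nrow = 3, byrow = TRUE)
  vi <- data.frame(variant_id = c("rs1", "rs3", "rs9"),
                   chrom = c("1", "3", "9"), pos = c(100L, 300L, 900L),
                   ref = c("A", "G", "A"), alt = c("G", "A", "C"))
  g <- GenotypeMatrix(d, vi)
  v <- data.frame(rsID = c("rs1", "rs3", "rsMissing"),
                  chr_name = c("1", "3", "7"),
                  chr_position = c(100L, 300L, 700L),
                  effect_allele = c("G", "G", "G"),
                  other_allele = c("A", "A", "A"),
                  effect_weight = c(0.5, 1, 2))
  s <- harmonizeScore(ScoreSet(v), g)
  lg <- harmonizationLog(s)
  expect_equal(lg$matched, 2)
  expect_equal(lg$flipped, 1)         # rs3: effect allele is the ref
  expect_equal(lg$missing, 1)
  expect_equal(lg$coverage_pct, 67)
  expect_equal(lg$matched + lg$missing, lg$total)

  # rs3 flipped: dosage (1,0,2) becomes (1,2,0)
  sc <- computeScores(s, g)
  expect_equal(sc$weighted, 0.5 * c(2, 1, 0) + 1 * c(1, 2, 0))
  expect_equal(sc$unweighted, c(2, 1, 0) + c(1, 2, 0))

  # published coverage arithmetic: 604 of 634 matched -> 95%
  expect_equal(as.integer(round(100 * 604 / 634)), 95L)
})

test_that("scores follow the hand sum, orientation and imputation rules", {
  d <- matrix(c(2, 1, 0), ncol = 1)            # one person, three variants
  vi <- data.frame(variant_id = paste0("rs", 1:3), chrom = c("1", "2", "3"),
                   pos = c(1L, 2L, 3L), ref = rep("A", 3), alt = rep("G", 3))
  g <- GenotypeMatrix(d, vi)
  v <- data.frame(rsID = paste0("rs", 1:3), chr_name = c("1", "2", "3"),
                  chr_position = 1:3, effect_allele = rep("G", 3),
                  other_allele = rep("A", 3),
                  effect_weight = c(0.1, -0.2, 0.05))
  s <- harmonizeScore(ScoreSet(v), g)
  sc <- computeScores(s, g)
  expect_equal(sc$weighted, 0.0)
  expect_equal(sc$unweighted, 3)

  sNeg <- harmonizeScore(ScoreSet(v, orientation = -1), g)
  expect_equal(computeScores(sNeg, g)$weighted, -sc$weighted)

  # missing dosage imputed to 2 * effect-allele frequency
  d2 <- rbind(c(2, 1, 0, 1, 2),
              c(1, 1, 0, 0, NA))               # 2 variants x 5 persons
  g2 <- GenotypeMatrix(d2, vi[1:2, ])
  s2 <- harmonizeScore(ScoreSet(v[1:2, ]), g2)
  sc2 <- computeScores(s2, g2)
  # variant 2: non-missing dosages (1,1,0,0) -> eaf 0.25, person 5 imputed
  # to 2 * 0.25 = 0.5
  expect_equal(sc2$weighted[5], 0.1 * 2 + (-0.2) * 0.5)
})

test_that("score agrees with a naive double loop and allele-coding flips", {
  set.seed(10)
  m <- 20; n <- 50
  d <- matrix(rbinom(m * n, 2, 0.4), nrow = m)
  vi <- data.frame(variant_id = paste0("rs", 1:m),
                   chrom = as.character(rep(1:10, 2)), pos = 1:m,
                   ref = rep("A", m), alt = rep("C", m))
  g <- GenotypeMatrix(d, vi)
  v <- data.frame(rsID = paste0("rs", 1:m), chr_name = vi$chrom,
                  chr_position = vi$pos, effect_allele = rep("C", m),
                  other_allele = rep("A", m),
                  effect_weight = rnorm(m))
  s <- harmonizeScore(ScoreSet(v), g)
  sc <- computeScores(s, g)
  oracle <- numeric(n)
  for (j in seq_len(n)) for (i in seq_len(m))
    oracle[j] <- oracle[j] + v$effect_weight[i] * d[i, j]
  expect_equal(sc$weighted, oracle, tolerance = 1e-12)

  # flipping every ref/alt label and every dosage leaves scores unchanged
  viFlip <- transform(vi, ref = alt, alt = ref)
  gFlip <- GenotypeMatrix(2 - d, viFlip)
  scFlip <- computeScores(harmonizeScore(ScoreSet(v), gFlip), gFlip)
  expect_equal(scFlip$weighted, sc$weighted, tolerance = 1e-12)

  # invariance to variant and person ordering
  pv <- sample(m); pp <- sample(n)
  gPerm <- GenotypeMatrix(d[pv, pp], vi[pv, ],
                          data.frame(person_id = personIds(g)[pp]))
  scPerm <- computeScores(harmonizeScore(ScoreSet(v), gPerm), gPerm)
  expect_equal(scPerm$weighted[match(sc$person_id, scPerm$person_id)],
               sc$weighted, tolerance = 1e-12)
})

test_that("scaleScores standardizes, preserves order, and is idempotent", {
  res <- data.frame(person_id = letters[1:5], weighted = c(3, 1, 4, 1, 5),
                    unweighted = 1:5, n_variants = 10)
  s1 <- scaleScores(res)
  expect_equal(mean(s1$weighted), 0, tolerance = 1e-12)
  expect_equal(sd(s1$weighted), 1, tolerance = 1e-12)
  expect_identical(order(s1$weighted), order(res$weighted))
  expect_equal(scaleScores(s1)$weighted, s1$weighted, tolerance = 1e-12)
  expect_error(scaleScores(transform(res, weighted = 1)), "variance")
})
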