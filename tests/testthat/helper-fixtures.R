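# Shared fixtures, built in code.

# a tiny GenotypeMatrix with explicit dosages
toyGenotypes <- function(d, af = NULL) {
  m <- nrow(d)
  vi <- data.frame(variant_id = sprintf("v%03d", seq_len(m)),
                   chrom = as.character(rep(1:22, length.out = m)),
                   pos = seq_len(m) * 1000L,
                   ref = rep("A", m), alt = rep("G", m))
  if (!is.null(af)) vi$af <- af
  GenotypeMatrix(d, vi)
}

# independent brute-force enumeration of the exact HWE conditional
# distribution, via the probability ratio recurrence (not the lgamma
# closed form used by the implementation)
hweEnumOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  pr <- numeric(length(hs))
  pr[1] <- 1
  if (length(hs) > 1) for (i in 2:length(hs)) {
    h <- hs[i]
    # P(h) / P(h-2) = 4 * nAA(h-2) * naa(h-2) / (h * (h-1))
    pr[i] <- pr[i - 1] * 4 * ((nA - (h - 2)) / 2) * ((na - (h - 2)) / 2) /
      (h * (h - 1))
  }
  pr <- pr / sum(pr)
  pObs <- pr[match(nAa, hs)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-9)]))
}

# simulated longitudinal series with known random-intercept structure
riToyData <- function(n, visits = 3, tau2 = 0.5, sigma2 = 0.25, seed = 1) {
  set.seed(seed)
  person <- rep(sprintf("P%04d", seq_len(n)), each = visits)
  u <- rep(rnorm(n, 0, sqrt(tau2)), each = visits)
  data.frame(person_id = person,
             sex = rep(sample(c("female", "male"), n, TRUE), each = visits),
             age0 = rep(rnorm(n, 58, 3), each = visits),
             time = rep(c(0, 5, 11)[seq_len(visits)], n),
             y = u + rnorm(n * visits, 0, sqrt(sigma2)))
}
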