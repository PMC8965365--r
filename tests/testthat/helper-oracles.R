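# Independent Weir & Cockerham (1984) oracle: explicit per-locus loops
# written directly from the published variance-component formulas (r = 2
# populations, no inbreeding decomposition beyond a, b, c).
wcOracle <- function(genoA, genoB) {
  r <- 2
  nA <- nrow(genoA); nB <- nrow(genoB)
  sumA <- 0; sumAbc <- 0
  for (l in seq_len(ncol(genoA))) {
    pA <- sum(genoA[, l]) / (2 * nA)
    pB <- sum(genoB[, l]) / (2 * nB)
    if ((pA + pB) == 0 || (pA + pB) == 2) next
    hA <- sum(genoA[, l] == 1) / nA
    hB <- sum(genoB[, l] == 1) / nB
    nbar <- (nA + nB) / 2
    nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
    pbar <- (nA * pA + nB * pB) / (r * nbar)
    s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
    hbar <- (nA * hA + nB * hB) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    sumA <- sumA + a
    sumAbc <- sumAbc + a + b + cc
  }
  if (sumAbc == 0) return(NA_real_)
  sumA / sumAbc
}

# genotype matrix with given allele frequency and heterozygote count
makeGeno <- function(n, nAlt, nHet) {
  nHom <- (nAlt - nHet) / 2
  stopifnot(nHom == round(nHom), nHom >= 0, nHom + nHet <= n)
  matrix(c(rep(2L, nHom), rep(1L, nHet), rep(0L, n - nHom - nHet)),
         ncol = 1)
}
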