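# Independent brute-force oracles. These deliberately use different
# formulations/code paths from the package implementations.

# mean pairwise difference per site over all chromosome pairs, summed
oraclePiSum <- function(hap) {
  # hap: sites x chromosomes, 0/1, no NA
  n <- ncol(hap)
  tot <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      tot <- tot + sum(hap[, a] != hap[, b])
    }
  }
  tot / choose(n, 2)
}

# Tajima's D by direct evaluation of the 1989 constants
oracleTajimaD <- function(hap) {
  n <- ncol(hap)
  freq <- rowSums(hap)
  seg <- freq > 0 & freq < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pihat <- oraclePiSum(hap) ## sum over sites of pairwise diff fractions
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pihat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham (1984) per-site components via the ANOVA (mean
# squares) formulation on individual allele-indicator sums, an
# algebraically equivalent but differently coded route.
oracleWcComponents <- function(g1, g2) {
  # g1, g2: dosage vectors (0/1/2, NA allowed) for the two populations
  # at one site; returns c(a, b, c)
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 1 || n2 < 1 || n1 + n2 < 3) return(c(NA, NA, NA))
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  # mean squares for populations, individuals-in-populations, gametes
  MSP <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) * 2 / (r - 1)
  h1 <- sum(g1 == 1); h2 <- sum(g2 == 1)
  SSI <- sum(2 * c(p1 * (1 - p1) * n1, p2 * (1 - p2) * n2)) -
    (h1 + h2) / 2
  MSI <- SSI / (n1 + n2 - r)
  MSG <- (h1 + h2) / (2 * (n1 + n2))
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  c(a, b, cc)
}

# haplotype r2 from the 2x2 haplotype count table
oracleR2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  pAB <- sum(x == 1 & y == 1) / n
  pA <- mean(x); pB <- mean(y)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# EHH / EHHS by explicit extended-haplotype string grouping
oracleEhhAt <- function(hap, core, x, allele) {
  carriers <- which(hap[core, ] == allele)
  nc <- length(carriers)
  span <- min(core, x):max(core, x)
  key <- apply(hap[span, carriers, drop = FALSE], 2, paste, collapse = "")
  sum(choose(table(key), 2)) / choose(nc, 2)
}

oracleEhhsAt <- function(hap, core, x) {
  n <- ncol(hap)
  span <- min(core, x):max(core, x)
  key <- apply(hap[span, , drop = FALSE], 2, paste, collapse = "")
  num <- sum(choose(table(key), 2))
  den <- sum(choose(table(hap[core, ]), 2))
  num / den
}

# Benjamini-Hochberg step-up, written out literally
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# interval coverage fraction by per-bp bitmap counting
oracleCoverageFrac <- function(winStart, winEnd, ivStart, ivEnd) {
  bp <- rep(FALSE, winEnd - winStart + 1)
  for (i in seq_along(ivStart)) {
    a <- max(winStart, ivStart[i]); b <- min(winEnd, ivEnd[i])
    if (a <= b) bp[(a:b) - winStart + 1] <- TRUE
  }
  mean(bp)
}

# random small haplotype/genotype instances
randomHaps <- function(nSites, nChrom, p = 0.5) {
  matrix(rbinom(nSites * nChrom, 1, p), nSites, nChrom)
}
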