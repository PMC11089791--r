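## Windowed and per-sample classical population-genetic statistics.
## Window grid: non-overlapping, anchored at position 1 of each scaffold;
## the final partial window is retained with its true bp length.

.scafLengths <- function(x, scaffoldLengths = NULL) {
  if (!is.null(scaffoldLengths)) return(scaffoldLengths)
  ml <- S4Vectors::metadata(x)$scaffoldLengths
  if (!is.null(ml)) return(ml)
  tapply(positions(x), scaffolds(x), max)
}

.windowGrid <- function(lens, windowSize) {
  out <- lapply(names(lens), function(sc) {
    L <- lens[[sc]]
    s <- seq(1L, L, by = windowSize)
    data.frame(scaffold = sc, start = s,
               end = pmin(s + windowSize - 1L, L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.windowIndex <- function(grid, scaffold, pos, windowSize) {
  key <- paste0(grid$scaffold, ":", (grid$start - 1L) %/% windowSize)
  match(paste0(scaffold, ":", (pos - 1L) %/% windowSize), key)
}

## per-site allele counts over non-missing calls in a sample subset
.alleleCounts <- function(x, samples) {
  d <- dosage(x)[, samples, drop = FALSE]
  pl <- ploidy(x)[match(samples, sampleIds(x))]
  plm <- matrix(pl, nrow(d), length(pl), byrow = TRUE)
  plm[is.na(d)] <- 0L
  nAll <- rowSums(plm)
  cAlt <- rowSums(d, na.rm = TRUE)
  list(n = nAll, alt = cAlt, ref = nAll - cAlt)
}

.popSamples <- function(x, population, dropExcluded = TRUE) {
  cd <- SummarizedExperiment::colData(x)
  keep <- cd$population %in% population
  if (dropExcluded) keep <- keep & !cd$excluded
  rownames(cd)[keep]
}

#' Windowed nucleotide diversity (pi)
#'
#' Per-site pi is the probability that two distinct chromosomes sampled
#' without replacement differ: \code{cRef*cAlt / choose(n, 2)} from the
#' non-missing allele counts. Window pi is the sum over sites divided by
#' the full window length in bp (the \code{--window-pi} convention), so
#' monomorphic and missing sites contribute 0.
#'
#' @param x A \linkS4class{GenotypeMatrix}.
#' @param population Population label.
#' @param windowSize Window size in bp (default 100 kb).
#' @param scaffoldLengths Optional named vector of scaffold lengths; falls
#'   back to \code{metadata(x)$scaffoldLengths}, then to max position.
#' @return data.frame: scaffold, start, end, nSnps, pi.
#' @export
windowedPi <- function(x, population, windowSize = 1e5L,
                       scaffoldLengths = NULL) {
  smp <- .popSamples(x, population)
  pl <- ploidy(x)[match(smp, sampleIds(x))]
  if (sum(pl) < 2) stop("population '", population,
                        "' has fewer than 2 chromosomes")
  ac <- .alleleCounts(x, smp)
  piSite <- ifelse(ac$n >= 2, ac$ref * ac$alt / choose(ac$n, 2), 0)
  lens <- .scafLengths(x, scaffoldLengths)
  grid <- .windowGrid(lens, windowSize)
  wi <- .windowIndex(grid, scaffolds(x), positions(x), windowSize)
  segSum <- rep(0, nrow(grid)); nsnp <- rep(0L, nrow(grid))
  tt <- tapply(piSite, wi, sum)
  segSum[as.integer(names(tt))] <- tt
  ct <- tapply(rep(1L, length(wi)), wi, sum)
  nsnp[as.integer(names(ct))] <- ct
  data.frame(grid, nSnps = nsnp,
             pi = segSum / (grid$end - grid$start + 1),
             row.names = NULL)
}

## Tajima (1989) normalizing constants for n chromosomes
.tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Uses only sites with no missing genotype in the population, so the
#' number of sampled chromosomes n is constant (2 x diploids + haploids).
#' Windows with no segregating site get \code{NA} (undefined), not 0.
#'
#' @inheritParams windowedPi
#' @return data.frame: scaffold, start, end, nSnps (segregating, fully
#'   genotyped), tajimaD.
#' @export
windowedTajimaD <- function(x, population, windowSize = 1e5L,
                            scaffoldLengths = NULL) {
  smp <- .popSamples(x, population)
  pl <- ploidy(x)[match(smp, sampleIds(x))]
  n <- sum(pl)
  if (n < 2) stop("population '", population,
                  "' has fewer than 2 chromosomes")
  d <- dosage(x)[, smp, drop = FALSE]
  full <- rowSums(is.na(d)) == 0L
  cAlt <- rowSums(d)
  seg <- full & cAlt > 0L & cAlt < n
  piSite <- ifelse(seg, (n - cAlt) * cAlt / choose(n, 2), 0)
  k <- .tajimaConstants(n)
  lens <- .scafLengths(x, scaffoldLengths)
  grid <- .windowGrid(lens, windowSize)
  wi <- .windowIndex(grid, scaffolds(x), positions(x), windowSize)
  S <- rep(0L, nrow(grid)); pihat <- rep(0, nrow(grid))
  tt <- tapply(as.integer(seg), wi, sum)
  S[as.integer(names(tt))] <- tt
  ps <- tapply(piSite, wi, sum)
  pihat[as.integer(names(ps))] <- ps
  D <- rep(NA_real_, nrow(grid))
  ok <- S > 0
  D[ok] <- (pihat[ok] - S[ok] / k$a1) /
    sqrt(k$e1 * S[ok] + k$e2 * S[ok] * (S[ok] - 1))
  data.frame(grid, nSnps = S, tajimaD = D, row.names = NULL)
}

#' Per-site Weir-Cockerham variance components
#'
#' Returns the among-population (a), among-individual (b) and
#' within-individual (c) components of the Weir & Cockerham (1984)
#' two-population FST estimator computed from diploid genotype counts.
#' Sites where either population has no genotyped individual, or where
#' fewer than 3 individuals are genotyped in total, are NA.
#'
#' @param x A \linkS4class{GenotypeMatrix}.
#' @param popA,popB The two population labels.
#' @return data.frame with columns a, b, c (one row per site).
#' @export
wcFstComponents <- function(x, popA, popB) {
  comp <- lapply(c(popA, popB), function(p) {
    smp <- .popSamples(x, p)
    pl2 <- ploidy(x)[match(smp, sampleIds(x))] == 2L
    d <- dosage(x)[, smp[pl2], drop = FALSE]
    nI <- rowSums(!is.na(d))
    pAlt <- rowSums(d, na.rm = TRUE) / (2 * nI)
    hobs <- rowSums(d == 1L, na.rm = TRUE) / nI
    list(n = nI, p = pAlt, h = hobs)
  })
  n1 <- comp[[1]]$n; n2 <- comp[[2]]$n
  p1 <- comp[[1]]$p; p2 <- comp[[2]]$p
  h1 <- comp[[1]]$h; h2 <- comp[[2]]$h
  r <- 2
  nbar <- (n1 + n2) / r
  ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) >= 3
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
    s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  data.frame(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST
#'
#' Ratio-of-sums window estimate \code{sum(a) / sum(a+b+c)} over sites
#' genotyped in both populations. Negative values are reported, not
#' clamped; windows with zero denominator are NA.
#'
#' @inheritParams wcFstComponents
#' @inheritParams windowedPi
#' @return data.frame: scaffold, start, end, nSnps, fst.
#' @export
windowedFst <- function(x, popA, popB, windowSize = 1e5L,
                        scaffoldLengths = NULL) {
  vc <- wcFstComponents(x, popA, popB)
  ok <- !is.na(vc$a)
  lens <- .scafLengths(x, scaffoldLengths)
  grid <- .windowGrid(lens, windowSize)
  wi <- .windowIndex(grid, scaffolds(x), positions(x), windowSize)
  num <- den <- rep(0, nrow(grid)); nsnp <- rep(0L, nrow(grid))
  tt <- tapply(ifelse(ok, vc$a, 0), wi, sum)
  num[as.integer(names(tt))] <- tt
  tt <- tapply(ifelse(ok, vc$a + vc$b + vc$c, 0), wi, sum)
  den[as.integer(names(tt))] <- tt
  tt <- tapply(as.integer(ok), wi, sum)
  nsnp[as.integer(names(tt))] <- tt
  fst <- ifelse(den != 0, num / den, NA_real_)
  data.frame(grid, nSnps = nsnp, fst = fst, row.names = NULL)
}

#' Per-sample heterozygosity and inbreeding coefficient
#'
#' Method-of-moments F as in the VCFtools \code{--het} computation: over
#' sites genotyped in the sample and polymorphic in the population,
#' \code{O} = observed homozygote count, \code{E} = expected under HWE
#' using the small-sample correction \code{1 - 2 p q n/(n-1)} from the
#' population allele counts, \code{F = (O - E)/(L - E)},
#' heterozygosity \code{= 1 - O/L}.
#'
#' @inheritParams windowedPi
#' @return data.frame: sampleId, O, E, L, F, het.
#' @export
sampleHetInbreeding <- function(x, population) {
  smp <- .popSamples(x, population)
  pl2 <- ploidy(x)[match(smp, sampleIds(x))] == 2L
  smp <- smp[pl2]
  if (!length(smp)) stop("no diploid samples in population")
  ac <- .alleleCounts(x, smp)
  poly <- ac$alt > 0 & ac$alt < ac$n & ac$n >= 2
  p <- ac$alt / ac$n
  eSite <- 1 - 2 * p * (1 - p) * ac$n / (ac$n - 1)
  d <- dosage(x)[, smp, drop = FALSE]
  out <- lapply(seq_along(smp), function(j) {
    use <- poly & !is.na(d[, j])
    L <- sum(use)
    O <- sum(d[use, j] != 1L)
    E <- sum(eSite[use])
    F <- if (abs(L - E) < .Machine$double.eps^0.5) NA_real_ else
      (O - E) / (L - E)
    data.frame(sampleId = smp[j], O = O, E = E, L = L, F = F,
               het = 1 - O / L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' LD decay: mean haplotype r-squared in distance bins
#'
#' Pairwise haplotype \eqn{r^2 = (p_{AB} - p_A p_B)^2 /
#' (p_A(1-p_A) p_B(1-p_B))} for every intra-scaffold marker pair within
#' \code{maxDist}, after a minor-allele-frequency filter, averaged in
#' fixed-width distance bins.
#'
#' @inheritParams windowedPi
#' @param maxDist Maximum pair distance in bp (default 200 kb).
#' @param maf Minimum minor-allele frequency (default 0.2).
#' @param binSize Distance bin width in bp (default 100).
#' @return data.frame: binMid, meanR2, nPairs.
#' @export
ldDecay <- function(x, population, maxDist = 2e5L, maf = 0.2,
                    binSize = 100L) {
  H <- haplotypes(x, .popSamples(x, population))
  f <- rowMeans(H, na.rm = TRUE)
  keep <- pmin(f, 1 - f) >= maf & !is.na(f)
  H <- H[keep, , drop = FALSE]
  sc <- scaffolds(x)[keep]; po <- positions(x)[keep]
  nBins <- as.integer(ceiling(maxDist / binSize))
  sumR2 <- rep(0, nBins); nPairs <- rep(0L, nBins)
  for (s in unique(sc)) {
    idx <- which(sc == s)
    Hs <- H[idx, , drop = FALSE]; ps <- po[idx]
    m <- length(idx)
    if (m < 2) next
    for (k in seq_len(m - 1)) {
      i1 <- seq_len(m - k); i2 <- i1 + k
      dist <- ps[i2] - ps[i1]
      use <- which(dist <= maxDist)
      if (!length(use)) break
      A <- Hs[i1[use], , drop = FALSE]; B <- Hs[i2[use], , drop = FALSE]
      ok <- !is.na(A) & !is.na(B)
      A0 <- A; A0[!ok] <- 0L; B0 <- B; B0[!ok] <- 0L
      n <- rowSums(ok)
      pA <- rowSums(A0) / n; pB <- rowSums(B0) / n
      pAB <- rowSums(A0 * B0) / n
      denom <- pA * (1 - pA) * pB * (1 - pB)
      r2 <- ifelse(denom > 0, (pAB - pA * pB)^2 / denom, NA_real_)
      bin <- pmin(pmax(ceiling(dist[use] / binSize), 1L), nBins)
      val <- !is.na(r2)
      tt <- tapply(r2[val], bin[val], sum)
      sumR2[as.integer(names(tt))] <- sumR2[as.integer(names(tt))] + tt
      ct <- tapply(rep(1L, sum(val)), bin[val], sum)
      nPairs[as.integer(names(ct))] <- nPairs[as.integer(names(ct))] + ct
    }
  }
  data.frame(binMid = (seq_len(nBins) - 0.5) * binSize,
             meanR2 = ifelse(nPairs > 0, sumR2 / nPairs, NA_real_),
             nPairs = nPairs)
}

#' Hardy-Weinberg chi-squared test from genotype counts
#'
#' Plain chi-squared (df = 1, no continuity correction) against the
#' p^2 : 2pq : q^2 expectation, with the allele frequency estimated from
#' the counts. An expected count of 0 with observed 0 contributes 0.
#'
#' @param counts Integer vector (homRef, het, homAlt).
#' @return list: counts, expected, chi2, df, p.
#' @export
hweChisq <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3 || any(counts < 0)) {
    stop("counts must be 3 non-negative numbers (homRef, het, homAlt)")
  }
  N <- sum(counts)
  if (N < 1) stop("N must be >= 1")
  p <- (2 * counts[1] + counts[2]) / (2 * N)
  q <- 1 - p
  expected <- N * c(p^2, 2 * p * q, q^2)
  term <- ifelse(expected == 0 & counts == 0, 0,
                 (counts - expected)^2 / expected)
  chi2 <- sum(term)
  list(counts = counts, expected = expected, chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Pairwise relatedness (Yang et al. 2010 A_jk, off-diagonal)
#'
#' \deqn{A_{jk} = \frac{1}{L}\sum_s \frac{(x_{js}-2p_s)(x_{ks}-2p_s)}
#' {2p_s(1-p_s)}} over polymorphic sites genotyped in both samples, with
#' x the alt-allele dosage and p the population allele frequency.
#'
#' @inheritParams windowedPi
#' @return Symmetric matrix with NA diagonal.
#' @export
relatednessMatrix <- function(x, population) {
  smp <- .popSamples(x, population)
  pl2 <- ploidy(x)[match(smp, sampleIds(x))] == 2L
  smp <- smp[pl2]
  ac <- .alleleCounts(x, smp)
  p <- ac$alt / ac$n
  poly <- ac$alt > 0 & ac$alt < ac$n
  d <- dosage(x)[poly, smp, drop = FALSE]
  p <- p[poly]
  Z <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  obs <- !is.na(Z)
  Z0 <- Z; Z0[!obs] <- 0
  num <- crossprod(Z0)
  L <- crossprod(obs * 1)
  A <- num / L
  diag(A) <- NA_real_
  dimnames(A) <- list(smp, smp)
  A
}

#' Assemble the per-window statistics table
#'
#' Joins windowed pi (both populations), Tajima's D (both populations) and
#' Weir-Cockerham FST on one window grid, with a window QC flag
#' (\code{qcPass}: at least \code{minSnps} genotyped SNPs).
#'
#' @inheritParams windowedFst
#' @param minSnps Minimum SNPs for a window to pass QC (default 10).
#' @return data.frame with columns scaffold, start, end, nSnps, pi_A,
#'   pi_B, tajimaD_A, tajimaD_B, fst, qcPass (A = popA, B = popB).
#' @export
windowTable <- function(x, popA, popB, windowSize = 1e5L, minSnps = 10L,
                        scaffoldLengths = NULL) {
  pa <- windowedPi(x, popA, windowSize, scaffoldLengths)
  pb <- windowedPi(x, popB, windowSize, scaffoldLengths)
  da <- windowedTajimaD(x, popA, windowSize, scaffoldLengths)
  db <- windowedTajimaD(x, popB, windowSize, scaffoldLengths)
  fs <- windowedFst(x, popA, popB, windowSize, scaffoldLengths)
  out <- data.frame(pa[, c("scaffold", "start", "end")],
                    nSnps = pa$nSnps,
                    pi_A = pa$pi, pi_B = pb$pi,
                    tajimaD_A = da$tajimaD, tajimaD_B = db$tajimaD,
                    fst = fs$fst)
  out$qcPass <- out$nSnps >= minSnps & !is.na(out$fst)
  attr(out, "populations") <- c(A = popA, B = popB)
  out
}
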