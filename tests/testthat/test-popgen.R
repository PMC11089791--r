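test_that("windowed pi matches closed forms and the pairwise oracle", {
  # one site 2:2 among 4 chromosomes in a 10-kb window
  hap <- matrix(c(0L, 0L, 1L, 1L), 1, 4)
  x <- gmFromHaps(hap, population = c("A", "A"), pos = 500L)
  S4Vectors::metadata(x)$scaffoldLengths <- c(s1 = 10000L)
  p <- windowedPi(x, "A", windowSize = 10000L)
  expect_equal(p$pi, (2 * 2 / 6) / 10000)
  # 2 chromosomes differing at 3 of 1000 bp
  hap2 <- matrix(0L, 3, 2); hap2[, 2] <- 1L
  x2 <- gmFromHaps(hap2, population = "A", pos = c(10L, 20L, 30L))
  S4Vectors::metadata(x2)$scaffoldLengths <- c(s1 = 1000L)
  expect_equal(windowedPi(x2, "A", windowSize = 1000L)$pi, 0.003)
  # no SNPs in the window -> 0 (window 2 of a 2-window scaffold)
  S4Vectors::metadata(x2)$scaffoldLengths <- c(s1 = 2000L)
  expect_equal(windowedPi(x2, "A", windowSize = 1000L)$pi[2], 0)
  # property: equals brute-force mean pairwise differences / length
  set.seed(7)
  for (i in 1:20) {
    nC <- 2 * sample(2:5, 1); nS <- sample(5:20, 1)
    hap <- randomHaps(nS, nC)
    x <- gmFromHaps(hap, population = rep("A", nC / 2),
                    pos = sort(sample.int(5000L, nS)))
    S4Vectors::metadata(x)$scaffoldLengths <- c(s1 = 5000L)
    got <- windowedPi(x, "A", windowSize = 5000L)$pi
    expect_equal(got, oraclePiSum(hap) / 5000, tolerance = 1e-12)
  }
})

test_that("Tajima's D: undefined at S=0, matches the 1989 constants", {
  hap <- matrix(0L, 5, 4)
  x <- gmFromHaps(hap, population = c("A", "A"))
  S4Vectors::metadata(x)$scaffoldLengths <- c(s1 = 1000L)
  expect_true(is.na(windowedTajimaD(x, "A", 1000L)$tajimaD))
  # n=4, S=3, all singletons -> about -0.75
  hap <- matrix(0L, 3, 4)
  hap[1, 1] <- 1L; hap[2, 2] <- 1L; hap[3, 3] <- 1L
  x <- gmFromHaps(hap, population = c("A", "A"))
  S4Vectors::metadata(x)$scaffoldLengths <- c(s1 = 1000L)
  D <- windowedTajimaD(x, "A", 1000L)$tajimaD
  expect_equal(D, oracleTajimaD(hap), tolerance = 1e-12)
  expect_equal(D, -0.75, tolerance = 0.01)
  # excess of intermediate-frequency variants -> D > 0
  hap <- matrix(rep(c(0L, 0L, 1L, 1L), each = 1), 4, 4, byrow = TRUE)
  x <- gmFromHaps(hap, population = c("A", "A"))
  S4Vectors::metadata(x)$scaffoldLengths <- c(s1 = 1000L)
  expect_gt(windowedTajimaD(x, "A", 1000L)$tajimaD, 0)
})

test_that("Weir-Cockerham FST: fixed difference gives 1, no structure ~0", {
  hap <- rbind(rep(c(0L, 1L), each = 8))[rep(1, 5), ]
  x <- gmFromHaps(hap, population = rep(c("A", "B"), each = 4))
  S4Vectors::metadata(x)$scaffoldLengths <- c(s1 = 1000L)
  expect_equal(windowedFst(x, "A", "B", 1000L)$fst, 1)
  # identical genotype arrays in both populations (n large enough that
  # the estimator's small-sample term -1/(2(n-1)) sits inside the band)
  set.seed(11)
  h <- randomHaps(200, 40)
  x <- gmFromHaps(cbind(h, h), population = rep(c("A", "B"), each = 20))
  S4Vectors::metadata(x)$scaffoldLengths <- c(s1 = 2010L)
  expect_lt(abs(windowedFst(x, "A", "B", 2010L)$fst), 0.05)
})

test_that("per-site W&C components equal the ANOVA-form oracle", {
  set.seed(3)
  for (i in 1:25) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    hap <- randomHaps(10, 2 * (n1 + n2), p = runif(1, 0.2, 0.8))
    x <- gmFromHaps(hap, population = rep(c("A", "B"), c(n1, n2)))
    vc <- wcFstComponents(x, "A", "B")
    d <- dosage(x)
    for (s in 1:10) {
      o <- oracleWcComponents(d[s, 1:n1], d[s, n1 + (1:n2)])
      expect_equal(unlist(vc[s, ]), o, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("windowed FST on permuted population labels centres on zero", {
  set.seed(21)
  hap <- randomHaps(300, 40, p = 0.4)
  vals <- replicate(100, {
    pops <- sample(rep(c("A", "B"), each = 10))
    x <- gmFromHaps(hap, population = pops)
    S4Vectors::metadata(x)$scaffoldLengths <- c(s1 = 3010L)
    windowedFst(x, "A", "B", 3010L)$fst
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("per-sample het/inbreeding matches the hand formula", {
  set.seed(5)
  hap <- randomHaps(5, 10, p = 0.5)
  x <- gmFromHaps(hap, population = rep("A", 5))
  r <- sampleHetInbreeding(x, "A")
  d <- dosage(x)
  ac <- colSums(matrix(rowSums(d), 5, 1))  # not used; direct check below
  for (j in 1:5) {
    n <- 10; pAlt <- rowSums(d) / n
    poly <- pAlt > 0 & pAlt < 1
    E <- sum((1 - 2 * pAlt * (1 - pAlt) * n / (n - 1))[poly])
    O <- sum(d[poly, j] != 1L)
    L <- sum(poly)
    expect_equal(r$F[j], (O - E) / (L - E), tolerance = 1e-12)
    expect_equal(r$het[j], 1 - O / L)
  }
  # all-het sample has F < 0; all-hom F approaches 1
  hapH <- cbind(rep(0L, 6), rep(1L, 6), randomHaps(6, 8))
  xh <- gmFromHaps(hapH, population = rep("A", 5))
  rh <- sampleHetInbreeding(xh, "A")
  expect_lt(rh$F[1], 0)
})

test_that("LD r2: duplicates, perfect coupling, oracle, and decay", {
  # duplicated column pair -> r2 = 1; counts AB=2, ab=2 -> r2 = 1
  hap <- rbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))
  x <- gmFromHaps(hap, population = c("A", "A"), pos = c(10L, 60L))
  ld <- ldDecay(x, "A", maxDist = 1000L, maf = 0.2, binSize = 100L)
  expect_equal(ld$meanR2[ld$nPairs > 0], 1)
  # matches the table-based oracle on random data
  set.seed(9)
  hap <- randomHaps(30, 20, p = 0.5)
  x <- gmFromHaps(hap, population = rep("A", 10),
                  pos = sort(sample.int(2000L, 30)))
  ld <- ldDecay(x, "A", maxDist = 2000L, maf = 0.2, binSize = 2000L)
  f <- rowMeans(hap)
  keep <- which(pmin(f, 1 - f) >= 0.2)
  r2s <- c()
  for (a in seq_along(keep)) for (b in seq_along(keep)) {
    if (b > a) r2s <- c(r2s, oracleR2(hap[keep[a], ], hap[keep[b], ]))
  }
  expect_equal(ld$meanR2[1], mean(r2s), tolerance = 1e-12)
  # mean r2 decays with distance on recombining synthetic data
  cfg <- simConfig(seed = 2, nScaffolds = 2L, scaffoldLength = 2e5L,
                   supergene = NULL, sweeps = NULL, admixed = FALSE)
  co <- simulateCohort(cfg)
  ldd <- ldDecay(co$geno, "H", maxDist = 5e4L, maf = 0.2, binSize = 5000L)
  rho <- suppressWarnings(
    cor(ldd$binMid, ldd$meanR2, method = "spearman",
        use = "complete.obs"))
  expect_lt(rho, 0)
})

test_that("HWE chi-squared: exact proportions, allele-label symmetry", {
  expect_equal(hweChisq(c(25, 50, 25))$chi2, 0)
  set.seed(13)
  for (i in 1:20) {
    cts <- as.numeric(sample.int(30, 3))
    expect_equal(hweChisq(cts)$chi2, hweChisq(rev(cts))$chi2,
                 tolerance = 1e-12)
  }
  expect_error(hweChisq(c(0, 0, 0)))
})

test_that("relatedness: duplicates near 1, unrelated near 0, L=1 exact", {
  set.seed(17)
  p <- runif(1500, 0.1, 0.9)
  d <- sapply(1:30, function(i) rbinom(1500, 2, p))
  colnames(d) <- paste0("i", 1:30)
  d <- cbind(d, dup = d[, 1])
  x <- GenotypeMatrix(d, scaffold = rep("s1", 1500),
                      pos = seq_len(1500), ref = rep("A", 1500),
                      alt = rep("T", 1500),
                      population = rep("A", 31))
  A <- relatednessMatrix(x, "A")
  expect_equal(A["i1", "dup"], 1, tolerance = 0.1)
  unrel <- A[paste0("i", 1:30), paste0("i", 1:30)]
  expect_lt(abs(mean(unrel[upper.tri(unrel)])), 0.1)
  # single polymorphic site evaluates the formula exactly
  d1 <- matrix(c(0L, 1L, 2L, 1L), 1, 4)
  x1 <- GenotypeMatrix(d1, scaffold = "s1", pos = 1L, ref = "A",
                       alt = "T", population = rep("A", 4))
  A1 <- relatednessMatrix(x1, "A")
  p1 <- sum(d1) / 8
  expect_equal(A1[1, 2],
               (d1[1] - 2 * p1) * (d1[2] - 2 * p1) / (2 * p1 * (1 - p1)),
               tolerance = 1e-12)
})

test_that("window table assembles stats on one grid with QC", {
  cfg <- simConfig(seed = 3, nScaffolds = 2L, scaffoldLength = 2e5L,
                   supergene = NULL, sweeps = NULL, admixed = FALSE)
  co <- simulateCohort(cfg)
  wt <- windowTable(co$geno, "H", "P", windowSize = 5e4L)
  expect_equal(nrow(wt), 8L)
  expect_true(all(wt$pi_A >= 0 & wt$pi_B >= 0))
  expect_true(all(wt$fst <= 1, na.rm = TRUE))
  expect_true(all(diff(wt$start[wt$scaffold == "scaffold_1"]) == 5e4))
})
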