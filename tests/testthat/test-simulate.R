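test_that("config validation catches infeasible settings", {
  expect_error(simConfig(seed = 1, sweeps = data.frame(
    scaffold = "scaffold_2", start = 150000L, end = 250000L)),
    "overlaps the supergene")
  expect_error(simConfig(seed = 1,
    genotypesH = c(ShSh = 0L, ShSp = 0L, SpSp = 16L)), "brood mother")
})

smallSg <- list(scaffold = "scaffold_2", start = 20001L, end = 180000L,
                divergenceDensity = 0.2, privateMutProb = 0.002)
smallSweeps <- data.frame(scaffold = "scaffold_3", start = 50001L,
                          end = 150000L, stringsAsFactors = FALSE)

test_that("the generator is deterministic given a seed", {
  cfg <- simConfig(seed = 99, nScaffolds = 3L, scaffoldLength = 2e5L,
                   supergene = smallSg, sweeps = smallSweeps)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(dosage(a$geno), dosage(b$geno))
  expect_identical(a$truth$supergene, b$truth$supergene)
  ba <- simulateBrood(cfg, a)
  bb <- simulateBrood(cfg, b)
  expect_identical(dosage(ba$geno), dosage(bb$geno))
  # a different seed changes the data
  c2 <- simulateCohort(simConfig(seed = 100, nScaffolds = 3L,
                                 scaffoldLength = 2e5L,
                                 supergene = smallSg,
                                 sweeps = smallSweeps))
  expect_false(identical(dosage(a$geno), dosage(c2$geno)))
})

test_that("zero mosaic rate makes every chromosome one founder copy", {
  cfg <- simConfig(seed = 12, nScaffolds = 2L, scaffoldLength = 1e5L,
                   mosaicRate = 0, supergene = NULL, sweeps = NULL,
                   admixed = FALSE, missingRate = 0)
  co <- simulateCohort(cfg)
  # rebuild the founder pools deterministically and check membership
  h1 <- SummarizedExperiment::assay(co$geno, "hap1")
  # with no breakpoints each chromosome is constant per scaffold: its
  # alleles must match one founder column exactly; verify via the
  # population allele-frequency structure instead: a chromosome equals
  # itself across the scaffold -> any two sites fully linked within a
  # chromosome's origin. Weak proxy: per-scaffold, each haplotype
  # equals one of at most foundersPerPop distinct patterns.
  sc <- scaffolds(co$geno)
  for (s in unique(sc)) {
    pats <- apply(h1[sc == s, populations(co$geno) == "H",
                     drop = FALSE], 2, paste, collapse = "")
    expect_lte(length(unique(pats)), cfg$foundersPerPop)
  }
})

test_that("supergene genotype tables are reproduced by construction", {
  cfg <- simConfig(seed = 31)
  co <- simulateCohort(cfg)
  gt <- co$truth$supergene$queenGenotype
  pop <- populations(co$geno)
  expect_equal(unname(table(gt[pop == "H"])[c("ShSh", "ShSp", "SpSp")]),
               c(6L, 8L, 2L), ignore_attr = TRUE)
  expect_equal(sum(gt[pop == "P"] == "SpSp"), 16L)
  expect_equal(sum(gt[pop == "P"] == "ShSp"), 3L)
  # the admixed queen is a P queen carrying an Sh haplotype
  adm <- co$truth$admixedId
  expect_true(adm %in% sampleIds(co$geno)[pop == "P"])
  expect_true(gt[adm] %in% c("ShSp", "ShSh"))
  expect_true(SummarizedExperiment::colData(co$geno)[adm, "excluded"])
})

test_that("brood construction: gametes, supergene integrity, crossovers", {
  cfg <- simConfig(seed = 13)
  co <- simulateCohort(cfg)
  # zero crossover rate: each son is exactly one maternal haplotype
  cfg0 <- simConfig(seed = 13, crossoverRate = 0, broodSize = 20L,
                    missingRate = 0)
  co0 <- simulateCohort(cfg0)
  br0 <- simulateBrood(cfg0, co0)
  mh <- co0$truth$motherHaplotypes
  mk <- match(paste0(scaffolds(br0$geno), ":", positions(br0$geno)),
              paste0(co0$truth$siteScaffold, ":", co0$truth$sitePos))
  G <- dosage(br0$geno)
  sc <- scaffolds(br0$geno)
  for (son in seq_len(ncol(G))) {
    for (s in unique(sc)) {
      ii <- sc == s
      expect_true(all(G[ii, son] == mh[mk[ii], 1]) ||
                    all(G[ii, son] == mh[mk[ii], 2]))
    }
  }
  # with recombination: no son switches haplotype inside the supergene
  br <- simulateBrood(cfg, co)
  sg <- co$truth$supergene
  inSg <- scaffolds(br$geno) == sg$scaffold &
    positions(br$geno) >= sg$start & positions(br$geno) <= sg$end
  Gs <- dosage(br$geno)[inSg, , drop = FALSE]
  mks <- match(paste0(sg$scaffold, ":", positions(br$geno)[inSg]),
               paste0(co$truth$siteScaffold, ":", co$truth$sitePos))
  mhs <- co$truth$motherHaplotypes[mks, ]
  for (son in seq_len(ncol(Gs))) {
    ok <- !is.na(Gs[, son])
    expect_true(all(Gs[ok, son] == mhs[ok, 1]) ||
                  all(Gs[ok, son] == mhs[ok, 2]))
  }
  # genome-wide crossover counts look Poisson with the configured mean
  cfgX <- simConfig(seed = 14, broodSize = 300L)
  coX <- simulateCohort(cfgX)
  brX <- simulateBrood(cfgX, coX)
  # supergene crossovers are rejected, thinning the Poisson mean by the
  # non-recombining interval on one scaffold
  lam <- cfgX$crossoverRate *
    (cfgX$nScaffolds * cfgX$scaffoldLength -
       (cfgX$supergene$end - cfgX$supergene$start + 1))
  counts <- brX$crossoverCounts
  brks <- c(-Inf, quantile(qpois(seq(0.1, 0.9, 0.2), lam)), Inf)
  obs <- table(cut(counts, brks))
  pr <- diff(c(0, ppois(brks[-c(1, length(brks))], lam), 1))
  gof <- suppressWarnings(chisq.test(as.integer(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("fixtures are deterministic, 1-based, and round-trip", {
  cfg <- simConfig(seed = 77, nScaffolds = 3L, scaffoldLength = 2e5L,
                   supergene = smallSg, sweeps = smallSweeps)
  co <- simulateCohort(cfg)
  br <- simulateBrood(cfg, co)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  f1 <- writeFixtures(co, br, cfg, d1)
  f2 <- writeFixtures(co, br, cfg, d2)
  for (nm in names(f1)) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     info = nm)
  }
  truth <- jsonlite::read_json(f1$truth)
  expect_equal(truth$supergene$start, smallSg$start)
  expect_equal(truth$seed, 77L)
  # the cohort VCF reads back to the same dosage matrix
  man <- readSampleManifest(f1$cohortManifest)
  back <- readGenotypeVcf(f1$cohortVcf, man)
  expect_equal(dosage(back), dosage(co$geno))
  # the reference FASTA carries the ref allele at every site
  genome <- Biostrings::readDNAStringSet(f1$genomeFa)
  names(genome) <- sub(" .*", "", names(genome))
  idx <- sample(length(positions(co$geno)), 50)
  got <- vapply(idx, function(i) as.character(Biostrings::subseq(
    genome[[scaffolds(co$geno)[i]]], positions(co$geno)[i],
    positions(co$geno)[i])), "")
  expect_equal(got, refAllele(co$geno)[idx])
})

test_that("neutral windowed FST agrees with a per-site frequency oracle", {
  cfg <- simConfig(seed = 15, supergene = NULL, sweeps = NULL,
                   admixed = FALSE)
  co <- simulateCohort(cfg)
  wt <- windowedFst(co$geno, "H", "P")
  vc <- wcFstComponents(co$geno, "H", "P")
  ok <- !is.na(vc$a)
  implied <- sum(vc$a[ok]) / sum((vc$a + vc$b + vc$c)[ok])
  expect_equal(weighted.mean(wt$fst, wt$nSnps, na.rm = TRUE), implied,
               tolerance = 0.02)
  # and the sweep/supergene structure raises FST where planted
  cfg2 <- simConfig(seed = 15)
  co2 <- simulateCohort(cfg2)
  wt2 <- windowedFst(co2$geno, "H", "P")
  sgw <- wt2$scaffold == "scaffold_2" & wt2$start >= 100001 &
    wt2$end <= 900000
  expect_gt(mean(wt2$fst[sgw], na.rm = TRUE),
            median(wt2$fst, na.rm = TRUE))
})
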