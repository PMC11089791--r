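# A tiny two-gene fixture built in code: plus- and minus-strand genes on
# a 600-bp scaffold with known codons.
mkGenome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

mkGene <- function(geneId, scaffold, start, end, strand, cds,
                   exons = cds, cdsOk = TRUE) {
  gr <- function(m) GenomicRanges::GRanges(
    scaffold, IRanges::IRanges(m[, 1], m[, 2]))
  ex <- GenomicRanges::reduce(gr(exons))
  cd <- GenomicRanges::reduce(gr(cds))
  span <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(start, end))
  introns <- GenomicRanges::setdiff(GenomicRanges::GRanges(
    scaffold, IRanges::IRanges(min(GenomicRanges::start(ex)),
                               max(GenomicRanges::end(ex)))), ex)
  nonCds <- GenomicRanges::setdiff(ex, cd)
  left <- nonCds[GenomicRanges::end(nonCds) <
                   min(GenomicRanges::start(cd))]
  right <- nonCds[GenomicRanges::start(nonCds) >
                    max(GenomicRanges::end(cd))]
  list(geneId = geneId, scaffold = scaffold, strand = strand,
       span = span, exons = ex, cds = cd, introns = introns,
       utr5 = if (strand == "+") left else right,
       utr3 = if (strand == "+") right else left, cdsOk = cdsOk)
}

test_that("codon-level effect calls are strand-aware", {
  # genome: positions 101..109 hold AAA TTT GGG (a + strand CDS)
  seq1 <- paste0(strrep("C", 100), "AAATTTGGG", strrep("C", 491))
  genome <- mkGenome(c(s1 = seq1))
  gPlus <- mkGene("gp", "s1", 101, 109, "+", cbind(101, 109))
  # AAA -> AAG at pos 103: Lys -> Lys synonymous
  eff <- annotateEffects(data.frame(scaffold = "s1", pos = 103,
                                    ref = "A", alt = "G"),
                         list(gp = gPlus), genome)
  expect_equal(eff$category, "synonymous_variant")
  # AAA -> GAA at pos 101: Lys -> Glu non-synonymous
  eff2 <- annotateEffects(data.frame(scaffold = "s1", pos = 101,
                                     ref = "A", alt = "G"),
                          list(gp = gPlus), genome)
  expect_equal(eff2$category, "non_synonymous_variant")
  expect_equal(eff2$aaChange, "K1E")
  # stop gain is "other": TTT codon -> TAA needs pos 105 T->A? use
  # AAA -> TAA via pos 101 A->T (K -> *)
  eff3 <- annotateEffects(data.frame(scaffold = "s1", pos = 101,
                                     ref = "A", alt = "T"),
                          list(gp = gPlus), genome)
  expect_equal(eff3$category, "other")
  # minus strand: the same bases read reverse-complemented
  gMinus <- mkGene("gm", "s1", 101, 109, "-", cbind(101, 109))
  # genome codons CCC AAA TTT read on minus (revcomp of AAATTTGGG)
  eff4 <- annotateEffects(data.frame(scaffold = "s1", pos = 109,
                                     ref = "G", alt = "T"),
                          list(gm = gMinus), genome)
  # minus CDS starts at 109: first codon CCC -> ACC (G>T on plus is
  # C>A on minus): Pro -> Thr, non-synonymous
  expect_equal(eff4$category, "non_synonymous_variant")
})

test_that("non-coding categories: UTR, intron, splice, flanks, intergenic", {
  seq1 <- paste0(strrep("A", 50), strrep("C", 550))
  genome <- mkGenome(c(s1 = seq1))
  # exon1 201..260 (CDS 231..260), intron 261..300, exon2 301..360
  g <- mkGene("g", "s1", 201, 360, "+",
              cds = rbind(c(231, 260), c(301, 330)),
              exons = rbind(c(201, 260), c(301, 360)))
  ann <- function(pos) annotateEffects(
    data.frame(scaffold = "s1", pos = pos, ref = "C", alt = "T"),
    list(g = g), genome)$category
  expect_equal(ann(210), "5'UTR")
  expect_equal(ann(340), "3'UTR")
  expect_equal(ann(280), "intron")
  expect_equal(ann(262), "other")        # splice-adjacent (<=2 bp)
  expect_equal(ann(299), "other")
  expect_equal(ann(150), "upstream")     # within 5 kb, + strand, left
  expect_equal(ann(400), "downstream")
  # minus-strand gene: 1 kb left of the span is downstream
  gm <- mkGene("gm", "s1", 201, 360, "-",
               cds = rbind(c(231, 260), c(301, 330)),
               exons = rbind(c(201, 260), c(301, 360)))
  effm <- annotateEffects(data.frame(scaffold = "s1", pos = 150,
                                     ref = "C", alt = "T"),
                          list(gm = gm), genome)
  expect_equal(effm$category, "downstream")
  # no gene within the flank -> exactly one intergenic record
  g2 <- annotateEffects(data.frame(scaffold = "s1", pos = 150,
                                   ref = "C", alt = "T"),
                        list(), genome, flank = 10)
  expect_equal(g2$category, "intergenic")
  expect_equal(nrow(g2), 1L)
  # bad-CDS gene yields no codon-level category
  gBad <- mkGene("gb", "s1", 201, 360, "+", cds = cbind(231, 260),
                 exons = rbind(c(201, 260), c(301, 360)), cdsOk = FALSE)
  effb <- annotateEffects(data.frame(scaffold = "s1", pos = 240,
                                     ref = "C", alt = "T"),
                          list(gb = gBad), genome)
  expect_equal(effb$category, "other")
})

test_that("every SNP yields at least one effect record", {
  seq1 <- paste0(strrep("A", 50), strrep("C", 550))
  genome <- mkGenome(c(s1 = seq1))
  g <- mkGene("g", "s1", 201, 290, "+", cds = cbind(201, 290))
  snps <- data.frame(scaffold = "s1", pos = c(10, 250, 500),
                     ref = "C", alt = "T")
  eff <- annotateEffects(snps, list(g = g), genome, flank = 100)
  expect_true(all(paste0(snps$scaffold, ":", snps$pos) %in%
                    paste0(eff$scaffold, ":", eff$pos)))
})

test_that("effect summary recomputes counts and percentages", {
  counts <- c("3'UTR" = 13, "5'UTR" = 1, downstream = 1391,
              intergenic = 3022, intron = 181,
              non_synonymous_variant = 73, synonymous_variant = 70,
              upstream = 1319, other = 7)
  sm <- effectSummary(counts)
  expect_equal(sum(sm$count), 6077)
  expect_equal(sm$percent, round(100 * sm$count / 6077, 2))
  # empty input -> all zeros
  sm0 <- effectSummary(data.frame(category = character(0)))
  expect_true(all(sm0$count == 0))
  # proportions sum to ~100
  expect_equal(sum(sm$percent), 100, tolerance = 0.1)
})

test_that("candidate-gene cascade applies the TE/support filters", {
  flags <- data.frame(
    geneId = c("g1", "g2", "g3", "g4"),
    is_te = c(TRUE, FALSE, FALSE, FALSE),
    has_expression = c(TRUE, FALSE, TRUE, FALSE),
    has_homology = c(TRUE, FALSE, FALSE, TRUE))
  eff <- data.frame(scaffold = "s1", pos = c(1, 2), ref = "A", alt = "T",
                    geneId = c("g3", "g4"),
                    category = c("non_synonymous_variant",
                                 "synonymous_variant"))
  fl <- suppressMessages(
    filterCandidateGenes(c("g1", "g2", "g3", "g4", "g5"), flags, eff))
  expect_setequal(fl$tier1, c("g3", "g4"))
  expect_equal(fl$tier2, "g3")
})

test_that("the 90/90 association rule uses strict inequalities", {
  # 16 H diploids, 18 P diploids
  mkDos <- function(hAlt, pRef) {
    c(ifelse(seq_len(16) <= hAlt, 1L, 0L),
      ifelse(seq_len(18) <= pRef, 0L, 2L))
  }
  d <- rbind(mkDos(15, 18),   # 15/16 = 0.9375 H alt; 18/18 P ref
             mkDos(16, 18),   # all pass
             c(rep(1L, 14), rep(0L, 2), rep(0L, 18)))
  # third SNP: 14/16 H alt = 0.875 -> fail
  x <- GenotypeMatrix(d, scaffold = rep("s1", 3), pos = c(10L, 20L, 30L),
                      ref = rep("A", 3), alt = rep("T", 3),
                      population = rep(c("H", "P"), c(16, 18)))
  snps <- data.frame(scaffold = "s1", pos = c(10L, 20L, 30L))
  ar <- associationRule(x, snps, "H", "P")
  expect_equal(ar$pass, c(TRUE, TRUE, FALSE))
  # exactly 90% on one side fails (strict >)
  d2 <- rbind(c(rep(1L, 18), rep(0L, 2), rep(0L, 18)))  # 18/20 H alt = 0.9
  x2 <- GenotypeMatrix(d2, scaffold = "s1", pos = 10L, ref = "A",
                       alt = "T",
                       population = rep(c("H", "P"), c(20, 18)))
  ar2 <- associationRule(x2, data.frame(scaffold = "s1", pos = 10L),
                         "H", "P")
  expect_false(ar2$pass)
  # planted association sites in the simulator all pass; background <1%
  cfg <- simConfig(seed = 6)
  co <- simulateCohort(cfg)
  truthSnps <- co$truth$assocSites[, c("scaffold", "pos")]
  arT <- associationRule(co$geno, truthSnps, "H", "P")
  expect_true(all(arT$pass))
  allSnps <- data.frame(scaffold = scaffolds(co$geno),
                        pos = positions(co$geno))
  inSweep <- rep(FALSE, nrow(allSnps))
  for (i in seq_len(nrow(cfg$sweeps))) {
    inSweep <- inSweep | (allSnps$scaffold == cfg$sweeps$scaffold[i] &
                            allSnps$pos >= cfg$sweeps$start[i] &
                            allSnps$pos <= cfg$sweeps$end[i])
  }
  arBg <- associationRule(co$geno, allSnps[!inSweep, ], "H", "P")
  expect_lt(mean(arBg$pass), 0.01)
})

test_that("classification is invariant under reverse-complementing", {
  seq1 <- paste0(strrep("C", 100), "AAATTTGGG", strrep("C", 491))
  L <- nchar(seq1)
  genome <- mkGenome(c(s1 = seq1))
  gPlus <- mkGene("g", "s1", 101, 109, "+", cbind(101, 109))
  seqM <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq1)))
  genomeM <- mkGenome(c(s1 = seqM))
  gMir <- mkGene("g", "s1", L - 109 + 1, L - 101 + 1, "-",
                 cbind(L - 109 + 1, L - 101 + 1))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (snp in list(c(103, "A", "G"), c(101, "A", "G"),
                   c(101, "A", "T"), c(105, "T", "C"))) {
    pos <- as.integer(snp[1])
    eff <- annotateEffects(data.frame(scaffold = "s1", pos = pos,
                                      ref = snp[2], alt = snp[3]),
                           list(g = gPlus), genome)
    effM <- annotateEffects(data.frame(scaffold = "s1",
                                       pos = L - pos + 1,
                                       ref = comp[[snp[2]]],
                                       alt = comp[[snp[3]]]),
                            list(g = gMir), genomeM)
    expect_equal(effM$category, eff$category)
  }
})
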