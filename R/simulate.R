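## Seeded generator of a two-population diploid cohort and a haploid
## brood with the statistical structure the pipeline assumes: founder-
## mosaic background with distance-decaying LD, population divergence,
## one non-recombining supergene with two haplotype archetypes at
## configured genotype frequencies, planted sweeps in the P population,
## an admixed individual, and a single-mother recombinant brood.

#' Simulation configuration
#'
#' Defaults emulate the study cohort: 16 "H" + 19 "P" diploid queens, an
#' 0.8-Mb non-recombining supergene (two haplotype groups Sh/Sp at
#' genotype counts H = 6/8/2, P = 0/3/16, one admixed P queen), three
#' planted sweeps in the P population, and a 108-son haploid brood from
#' one Sh/Sp H mother, on a 10 x 1 Mb desk-scale genome (1/10 the real
#' aspect ratio).
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param nScaffolds,scaffoldLength Genome shape (default 10 x 1 Mb).
#' @param snpDensity SNPs per bp (default 1/500).
#' @param foundersPerPop Founder haplotypes per population pool.
#' @param divergenceProb Per-site probability of a pool-divergent site.
#' @param divergentFreqs Alt-allele frequencies (high, low) at divergent
#'   sites.
#' @param sfsShape Beta(a, b) parameters for shared allele frequencies.
#' @param mosaicRate Founder-mosaic breakpoint rate per bp (shapes
#'   cohort LD decay; an effective many-generation rate).
#' @param crossoverRate Per-bp per-meiosis crossover rate for the brood
#'   (default 2.5e-6: each 1-Mb desk-scale scaffold stands for a full
#'   chromosome, preserving a ~250 cM per-chromosome map length).
#' @param genotypesH,genotypesP Supergene genotype count tables
#'   (ShSh, ShSp, SpSp); their sums set the population sizes.
#' @param supergene NULL, or list(scaffold, start, end,
#'   divergenceDensity, privateMutProb): the non-recombining interval,
#'   the per-site probability of an Sh/Sp fixed difference, and the
#'   per-chromosome private mutation probability inside it.
#' @param sweeps NULL, or data.frame(scaffold, start, end) of planted
#'   sweep intervals (must be disjoint from the supergene).
#' @param sweepCarrierFraction Probability a P chromosome carries the
#'   sweep haplotype inside a sweep interval.
#' @param postSweepMutProb Per-site allele-toggle probability on sweep
#'   haplotype copies (recovering variation after the sweep).
#' @param assocSitesPerSweep Sites per sweep planted as near-perfect
#'   genotype-phenotype association sites (H pool fixed alt, P ref).
#' @param admixed Plant one admixed (F1-like) P queen?
#' @param broodSize Number of haploid sons (default 108).
#' @param broodMarkersPerMb ddRAD-like marker density for the brood (one
#'   marker per 1e6/broodMarkersPerMb-bp bin, emulating restriction-site
#'   spacing).
#' @param missingRate Per-call missing-genotype probability.
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(seed,
                      nScaffolds = 10L, scaffoldLength = 1e6L,
                      snpDensity = 0.002, foundersPerPop = 16L,
                      divergenceProb = 0.005,
                      divergentFreqs = c(0.9, 0.1),
                      sfsShape = c(0.5, 2),
                      mosaicRate = 2e-5, crossoverRate = 2.5e-6,
                      genotypesH = c(ShSh = 6L, ShSp = 8L, SpSp = 2L),
                      genotypesP = c(ShSh = 0L, ShSp = 3L, SpSp = 16L),
                      supergene = list(scaffold = "scaffold_2",
                                       start = 100001L, end = 900000L,
                                       divergenceDensity = 0.2,
                                       privateMutProb = 0.002),
                      sweeps = data.frame(
                        scaffold = c("scaffold_4", "scaffold_6",
                                     "scaffold_8"),
                        start = c(300001L, 500001L, 100001L),
                        end = c(400000L, 600000L, 200000L),
                        stringsAsFactors = FALSE),
                      sweepCarrierFraction = 0.9,
                      postSweepMutProb = 0.002,
                      assocSitesPerSweep = 30L,
                      admixed = TRUE, broodSize = 108L,
                      broodMarkersPerMb = 40,
                      missingRate = 0.02) {
  cfg <- as.list(environment())
  cfg$nH <- sum(genotypesH); cfg$nP <- sum(genotypesP)
  scafs <- sprintf("scaffold_%d", seq_len(nScaffolds))
  if (!is.null(supergene)) {
    if (!supergene$scaffold %in% scafs ||
        supergene$end > scaffoldLength || supergene$start < 1) {
      stop("supergene interval outside the simulated genome")
    }
  }
  if (!is.null(sweeps) && nrow(sweeps) > 0) {
    if (!all(sweeps$scaffold %in% scafs) ||
        any(sweeps$end > scaffoldLength) || any(sweeps$start < 1)) {
      stop("sweep interval outside the simulated genome")
    }
  }
  if (!is.null(supergene)) {
    if (any(genotypesH < 0) || any(genotypesP < 0)) {
      stop("negative genotype counts")
    }
    if (!is.null(sweeps) && nrow(sweeps) > 0) {
      clash <- sweeps$scaffold == supergene$scaffold &
        sweeps$start <= supergene$end & sweeps$end >= supergene$start
      if (any(clash)) stop("sweep interval overlaps the supergene")
    }
    if (genotypesH[["ShSp"]] + genotypesH[["ShSh"]] < 1) {
      stop("need at least one Sh-carrying H queen as brood mother")
    }
  }
  class(cfg) <- "SimConfig"
  cfg
}

.scafNames <- function(cfg) sprintf("scaffold_%d", seq_len(cfg$nScaffolds))

## assemble one founder-mosaic chromosome over all scaffolds
.mosaicChromosome <- function(cfg, founders, siteScaf, sitePos) {
  out <- integer(length(sitePos))
  K <- ncol(founders)
  for (s in unique(siteScaf)) {
    ii <- which(siteScaf == s)
    nb <- stats::rpois(1, cfg$mosaicRate * cfg$scaffoldLength)
    bp <- sort(stats::runif(nb, 1, cfg$scaffoldLength))
    seg <- findInterval(sitePos[ii], bp) + 1L
    segF <- sample.int(K, max(seg), replace = TRUE)
    out[ii] <- founders[cbind(ii, segF[seg])]
  }
  out
}

#' Simulate the two-population diploid cohort
#'
#' See \code{\link{simConfig}} for the generative model: per population,
#' founder haplotypes drawn from site-wise allele frequencies; each
#' chromosome is a founder mosaic with Poisson breakpoints; inside the
#' supergene every chromosome copies its assigned Sh or Sp archetype
#' (plus rare private mutations) with no breakpoints; inside sweep
#' intervals P chromosomes copy a designated founder haplotype with the
#' configured carrier probability; one admixed queen draws one full
#' haplotype set from each population's pool.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return list: \code{geno} (a phased \linkS4class{GenotypeMatrix} with
#'   \code{metadata(geno)$scaffoldLengths} set) and \code{truth} (planted
#'   intervals, assignments and unmasked maternal haplotypes).
#' @export
simulateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  scafs <- .scafNames(cfg)
  L <- cfg$scaffoldLength
  nPer <- round(L * cfg$snpDensity)
  siteScaf <- rep(scafs, each = nPer)
  sitePos <- as.integer(unlist(lapply(scafs, function(s)
    sort(sample.int(L, nPer)))))
  S <- length(sitePos)
  K <- cfg$foundersPerPop

  isDiv <- stats::runif(S) < cfg$divergenceProb
  hHigh <- stats::runif(S) < 0.5
  pShared <- stats::rbeta(S, cfg$sfsShape[1], cfg$sfsShape[2])
  freqH <- ifelse(isDiv, ifelse(hHigh, cfg$divergentFreqs[1],
                                cfg$divergentFreqs[2]), pShared)
  freqP <- ifelse(isDiv, ifelse(hHigh, cfg$divergentFreqs[2],
                                cfg$divergentFreqs[1]), pShared)

  ## planted association sites inside sweeps: H pool fixed alt, P ref
  assoc <- NULL
  if (!is.null(cfg$sweeps) && nrow(cfg$sweeps) > 0) {
    assoc <- do.call(rbind, lapply(seq_len(nrow(cfg$sweeps)), function(i) {
      inSweep <- which(siteScaf == cfg$sweeps$scaffold[i] &
                         sitePos >= cfg$sweeps$start[i] &
                         sitePos <= cfg$sweeps$end[i])
      pick <- sort(sample(inSweep, min(cfg$assocSitesPerSweep,
                                       length(inSweep))))
      data.frame(site = pick, sweep = i)
    }))
    freqH[assoc$site] <- 1
    freqP[assoc$site] <- 0
  }
  FH <- matrix(stats::rbinom(S * K, 1, freqH), nrow = S, ncol = K)
  FP <- matrix(stats::rbinom(S * K, 1, freqP), nrow = S, ncol = K)

  ## supergene archetypes (Sp = reference-like all-0; Sh = divergent)
  sg <- cfg$supergene
  sgSites <- integer(0); shArch <- integer(0)
  if (!is.null(sg)) {
    sgSites <- which(siteScaf == sg$scaffold & sitePos >= sg$start &
                       sitePos <= sg$end)
    shArch <- stats::rbinom(length(sgSites), 1, sg$divergenceDensity)
  }

  ## supergene genotype labels per queen (H first, then P)
  lab <- function(tab) c(rep("ShSh", tab[["ShSh"]]),
                         rep("ShSp", tab[["ShSp"]]),
                         rep("SpSp", tab[["SpSp"]]))
  sgGeno <- if (!is.null(sg)) c(lab(cfg$genotypesH), lab(cfg$genotypesP))
    else rep(NA_character_, cfg$nH + cfg$nP)
  nQ <- cfg$nH + cfg$nP
  ids <- c(sprintf("H%02d", seq_len(cfg$nH)),
           sprintf("P%02d", seq_len(cfg$nP)))
  popLab <- c(rep("H", cfg$nH), rep("P", cfg$nP))
  ## the admixed queen is an Sh/Sp P queen (the last one)
  admixId <- NA_character_
  if (cfg$admixed) {
    cand <- which(popLab == "P" &
                    (is.na(sgGeno) | sgGeno %in% c("ShSp", "ShSh")))
    if (!length(cand)) cand <- which(popLab == "P")
    admixId <- ids[max(cand)]
  }

  sweepSiteList <- list()
  if (!is.null(cfg$sweeps) && nrow(cfg$sweeps) > 0) {
    sweepSiteList <- lapply(seq_len(nrow(cfg$sweeps)), function(i) {
      which(siteScaf == cfg$sweeps$scaffold[i] &
              sitePos >= cfg$sweeps$start[i] &
              sitePos <= cfg$sweeps$end[i])
    })
  }

  makeChrom <- function(pool, sgLabel, founderCols = NULL) {
    founders <- if (pool == "H") FH else FP
    if (!is.null(founderCols)) {
      founders <- founders[, founderCols, drop = FALSE]
    }
    chrom <- .mosaicChromosome(cfg, founders, siteScaf, sitePos)
    if (pool == "P" && length(sweepSiteList)) {
      for (ss in sweepSiteList) {
        if (stats::runif(1) < cfg$sweepCarrierFraction) {
          v <- FP[ss, 1]
          mut <- stats::runif(length(ss)) < cfg$postSweepMutProb
          v[mut] <- 1L - v[mut]
          chrom[ss] <- v
        }
      }
    }
    if (!is.null(sg) && !is.na(sgLabel)) {
      v <- if (sgLabel == "Sh") shArch else integer(length(sgSites))
      mut <- stats::runif(length(sgSites)) < sg$privateMutProb
      v[mut] <- 1L - v[mut]
      chrom[sgSites] <- v
    }
    chrom
  }

  ## the brood mother: an Sh/Sp H queen, drawn outbred (her two
  ## haplotypes use disjoint founder subsets) so that maternal-het
  ## markers are informative genome-wide
  motherIdx <- if (!is.null(sg)) {
    mi <- which(popLab == "H" & sgGeno == "ShSp")[1]
    if (is.na(mi)) which(popLab == "H")[1] else mi
  } else 1L
  motherId <- ids[motherIdx]
  half <- seq_len(floor(K / 2))

  hap1 <- matrix(NA_integer_, S, nQ)
  hap2 <- matrix(NA_integer_, S, nQ)
  for (q in seq_len(nQ)) {
    g <- sgGeno[q]
    a1 <- if (is.na(g)) NA else if (g == "SpSp") "Sp" else "Sh"
    a2 <- if (is.na(g)) NA else if (g == "ShSh") "Sh" else "Sp"
    if (!is.na(admixId) && ids[q] == admixId) {
      hap1[, q] <- makeChrom("H", a1)   # the H-derived haplotype set
      hap2[, q] <- makeChrom("P", a2)
    } else if (q == motherIdx) {
      hap1[, q] <- makeChrom(popLab[q], a1, founderCols = half)
      hap2[, q] <- makeChrom(popLab[q], a2, founderCols = setdiff(
        seq_len(K), half))
    } else {
      hap1[, q] <- makeChrom(popLab[q], a1)
      hap2[, q] <- makeChrom(popLab[q], a2)
    }
  }
  motherHap <- cbind(hap1[, motherIdx], hap2[, motherIdx])

  ## reference/alternate bases (reference = allele 0)
  refBase <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
  altBase <- vapply(refBase, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")

  ## missing-data mask (applied jointly to dosage and phase)
  mask <- matrix(stats::runif(S * nQ) < cfg$missingRate, S, nQ)
  h1m <- hap1; h2m <- hap2
  h1m[mask] <- NA_integer_; h2m[mask] <- NA_integer_
  dos <- h1m + h2m

  geno <- GenotypeMatrix(dos, siteScaf, sitePos, refBase, altBase,
                         hap1 = h1m, hap2 = h2m,
                         population = popLab,
                         role = rep("queen", nQ),
                         ploidy = rep(2L, nQ), phased = TRUE,
                         excluded = if (is.na(admixId)) rep(FALSE, nQ)
                           else ids == admixId,
                         sampleIds = ids)
  S4Vectors::metadata(geno)$scaffoldLengths <-
    stats::setNames(rep(L, cfg$nScaffolds), scafs)
  truth <- list(
    config = cfg,
    scaffoldLengths = stats::setNames(rep(L, cfg$nScaffolds), scafs),
    supergene = if (!is.null(sg)) list(
      scaffold = sg$scaffold, start = sg$start, end = sg$end,
      queenGenotype = stats::setNames(sgGeno, ids),
      diagnosticPos = sitePos[sgSites][shArch == 1L]) else NULL,
    sweeps = cfg$sweeps,
    assocSites = if (!is.null(assoc)) data.frame(
      scaffold = siteScaf[assoc$site], pos = sitePos[assoc$site],
      sweep = assoc$sweep, stringsAsFactors = FALSE) else NULL,
    admixedId = admixId, motherId = motherId,
    motherHaplotypes = motherHap,
    refBase = refBase, altBase = altBase,
    siteScaffold = siteScaf, sitePos = sitePos)
  list(geno = geno, truth = truth)
}

#' Simulate the haploid brood of one Sh/Sp mother
#'
#' Each son is one recombinant maternal gamete: per scaffold,
#' Poisson(\code{crossoverRate} x length) crossovers, none inside the
#' supergene interval. Only maternal-heterozygous sites are informative;
#' they are down-sampled to \code{broodMarkersPerMb} to emulate ddRAD
#' marker sparsity.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param cohort Output of \code{\link{simulateCohort}} (supplies the
#'   mother's unmasked phased genotype).
#' @return list: \code{geno} (haploid \linkS4class{GenotypeMatrix}),
#'   \code{crossoverCounts} (per son), \code{markers} (site info).
#' @export
simulateBrood <- function(cfg, cohort) {
  truth <- cohort$truth
  set.seed(cfg$seed + 1000L)
  mh <- truth$motherHaplotypes
  het <- which(mh[, 1] != mh[, 2])
  if (!length(het)) stop("mother is homozygous at every site")
  ## ddRAD-like markers: one maternal-het site per equally spaced bin
  binWidth <- 1e6 / cfg$broodMarkersPerMb
  binKey <- paste0(truth$siteScaffold[het], ":",
                   (truth$sitePos[het] - 1) %/% binWidth)
  mk <- sort(vapply(split(het, binKey), function(ii)
    if (length(ii) == 1) ii else sample(ii, 1), 1L))
  names(mk) <- NULL
  scafs <- .scafNames(cfg)
  siteScaf <- truth$siteScaffold[mk]
  sitePos <- truth$sitePos[mk]
  sg <- cfg$supergene
  G <- matrix(NA_integer_, length(mk), cfg$broodSize)
  xoCounts <- integer(cfg$broodSize)
  for (son in seq_len(cfg$broodSize)) {
    allele <- integer(length(mk))
    for (s in scafs) {
      ii <- which(siteScaf == s)
      nb <- stats::rpois(1, cfg$crossoverRate * cfg$scaffoldLength)
      bp <- sort(stats::runif(nb, 1, cfg$scaffoldLength))
      if (!is.null(sg) && s == sg$scaffold) {
        bp <- bp[bp < sg$start | bp > sg$end]
      }
      xoCounts[son] <- xoCounts[son] + length(bp)
      startPhase <- sample(1:2, 1)
      if (length(ii)) {
        phase <- (startPhase - 1L + findInterval(sitePos[ii], bp)) %% 2L + 1L
        allele[ii] <- mh[cbind(mk[ii], phase)]
      }
    }
    G[, son] <- allele
  }
  mask <- matrix(stats::runif(length(G)) < cfg$missingRate,
                 nrow(G), ncol(G))
  G[mask] <- NA_integer_
  ids <- sprintf("son%03d", seq_len(cfg$broodSize))
  geno <- GenotypeMatrix(G, siteScaf, sitePos,
                         truth$refBase[mk], truth$altBase[mk],
                         hap1 = G,
                         population = rep("brood", cfg$broodSize),
                         role = rep("male", cfg$broodSize),
                         ploidy = rep(1L, cfg$broodSize), phased = TRUE,
                         sampleIds = ids)
  S4Vectors::metadata(geno)$scaffoldLengths <- truth$scaffoldLengths
  list(geno = geno, crossoverCounts = xoCounts,
       markers = data.frame(scaffold = siteScaf, pos = sitePos,
                            stringsAsFactors = FALSE))
}

## reference genome consistent with the cohort's ref alleles
.simGenome <- function(cfg, truth) {
  set.seed(cfg$seed + 2000L)
  scafs <- .scafNames(cfg)
  seqs <- lapply(scafs, function(s) {
    x <- sample(c("A", "C", "G", "T"), cfg$scaffoldLength, replace = TRUE)
    ii <- which(truth$siteScaffold == s)
    x[truth$sitePos[ii]] <- truth$refBase[ii]
    paste(x, collapse = "")
  })
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- scafs
  g
}

## toy gene models overlapping the sweep intervals, anchored so that a
## few planted association sites fall inside CDS
.simGeneTable <- function(cfg, truth) {
  if (is.null(truth$assocSites) || nrow(truth$assocSites) == 0) {
    return(NULL)
  }
  rows <- list()
  gid <- 0L
  for (i in sort(unique(truth$assocSites$sweep))) {
    as_i <- truth$assocSites[truth$assocSites$sweep == i, ]
    sw <- cfg$sweeps[i, ]
    anchor <- as_i$pos[ceiling(nrow(as_i) / 2)]
    s <- max(sw$start, anchor - 700L)
    for (k in 1:2) {
      gid <- gid + 1L
      strand <- if (k == 1) "+" else "-"
      gs <- s + (k - 1L) * 12000L
      rows[[length(rows) + 1L]] <- data.frame(
        geneId = sprintf("GENE_%03d", gid), scaffold = sw$scaffold,
        start = gs, strand = strand, is_te = FALSE,
        has_expression = TRUE, has_homology = (k == 1),
        stringsAsFactors = FALSE)
    }
    # a TE-protein gene and an unsupported gene for the filter cascade
    gid <- gid + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      geneId = sprintf("GENE_%03d", gid), scaffold = sw$scaffold,
      start = s + 24000L, strand = "+", is_te = TRUE,
      has_expression = TRUE, has_homology = TRUE,
      stringsAsFactors = FALSE)
    gid <- gid + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      geneId = sprintf("GENE_%03d", gid), scaffold = sw$scaffold,
      start = s + 36000L, strand = "+", is_te = FALSE,
      has_expression = FALSE, has_homology = FALSE,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.writeGff3 <- function(tab, path) {
  ln <- c("##gff-version 3")
  for (i in seq_len(nrow(tab))) {
    g <- tab[i, ]
    ge <- g$start + 8499L
    mid <- paste0(g$geneId, ".t1")
    feats <- rbind(
      data.frame(type = "gene", s = g$start, e = ge,
                 attr = paste0("ID=", g$geneId)),
      data.frame(type = "mRNA", s = g$start, e = ge,
                 attr = paste0("ID=", mid, ";Parent=", g$geneId)),
      data.frame(type = "exon", s = g$start, e = g$start + 1999L,
                 attr = paste0("ID=", mid, ".e1;Parent=", mid)),
      data.frame(type = "exon", s = g$start + 4000L, e = ge,
                 attr = paste0("ID=", mid, ".e2;Parent=", mid)),
      data.frame(type = "CDS", s = g$start + 500L, e = g$start + 1999L,
                 attr = paste0("ID=", mid, ".c1;Parent=", mid)),
      data.frame(type = "CDS", s = g$start + 4000L, e = g$start + 5499L,
                 attr = paste0("ID=", mid, ".c2;Parent=", mid)))
    ln <- c(ln, sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                        g$scaffold, feats$type, feats$s, feats$e,
                        g$strand, feats$attr))
  }
  writeLines(ln, path)
  invisible(path)
}

## TE intervals: enriched inside the supergene, sparse elsewhere
.simTeIntervals <- function(cfg, truth) {
  set.seed(cfg$seed + 3000L)
  scafs <- .scafNames(cfg)
  rows <- list()
  for (s in scafs) {
    n <- 20L
    st <- sort(sample.int(cfg$scaffoldLength - 2000L, n))
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold = s, start = st, end = st + 999L)
  }
  if (!is.null(truth$supergene)) {
    sgl <- truth$supergene
    n <- 160L
    st <- sort(sample(seq(sgl$start, sgl$end - 2000L), n))
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold = sgl$scaffold, start = st, end = st + 999L)
  }
  out <- do.call(rbind, rows)
  out[order(out$scaffold, out$start), ]
}

#' Write the simulated study as an on-disk fixture set
#'
#' Deterministic file set: phased cohort VCF, haploid brood VCF, sample
#' manifests, toy GFF3 gene models with a per-gene flag table, TE BED,
#' reference FASTA, and a truth JSON (1-based coordinates).
#'
#' @param cohort From \code{\link{simulateCohort}}.
#' @param brood From \code{\link{simulateBrood}} (or NULL to skip).
#' @param cfg The \code{\link{simConfig}} used.
#' @param outdir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
writeFixtures <- function(cohort, brood, cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  truth <- cohort$truth
  writeGenotypeVcf(cohort$geno, p("cohort.vcf"))
  cd <- SummarizedExperiment::colData(cohort$geno)
  utils::write.table(
    data.frame(sample_id = rownames(cd), population = cd$population,
               role = cd$role, excluded = cd$excluded),
    p("cohort_manifest.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  files <- list(cohortVcf = p("cohort.vcf"),
                cohortManifest = p("cohort_manifest.tsv"))
  if (!is.null(brood)) {
    writeGenotypeVcf(brood$geno, p("brood.vcf"))
    bd <- SummarizedExperiment::colData(brood$geno)
    utils::write.table(
      data.frame(sample_id = rownames(bd), population = bd$population,
                 role = bd$role, excluded = bd$excluded),
      p("brood_manifest.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    files$broodVcf <- p("brood.vcf")
    files$broodManifest <- p("brood_manifest.tsv")
  }
  geneTab <- .simGeneTable(cfg, truth)
  if (!is.null(geneTab)) {
    .writeGff3(geneTab, p("genes.gff3"))
    utils::write.table(
      geneTab[, c("geneId", "is_te", "has_expression", "has_homology")],
      p("gene_flags.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    files$gff3 <- p("genes.gff3")
    files$geneFlags <- p("gene_flags.tsv")
  }
  te <- .simTeIntervals(cfg, truth)
  writeLines(sprintf("%s\t%d\t%d", te$scaffold, te$start - 1L, te$end),
             p("repeats.bed"))
  files$teBed <- p("repeats.bed")
  genome <- .simGenome(cfg, truth)
  Biostrings::writeXStringSet(genome, p("genome.fa"))
  files$genomeFa <- p("genome.fa")
  truthOut <- list(
    supergene = truth$supergene, sweeps = truth$sweeps,
    assocSites = truth$assocSites, admixedId = truth$admixedId,
    motherId = truth$motherId, seed = cfg$seed)
  jsonlite::write_json(truthOut, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  files$truth <- p("truth.json")
  files
}
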