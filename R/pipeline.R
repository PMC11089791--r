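## End-to-end orchestration: simulate -> windowed stats -> scans ->
## intersection -> linkage map / supergene -> region genotypes & HWE ->
## effects & candidate genes -> (optional) dating -> run report.

.stageMsg <- function(verbose, ...) if (verbose) message("[supersweep] ", ...)

#' Run the full genome-scan pipeline on a simulated cohort
#'
#' Executes the analysis stages in order: windowed statistics (pi,
#' Tajima's D, FST), per-sample heterozygosity, xpEHH scan, FST outlier
#' clustering, candidate intersection, brood linkage map and
#' non-recombining-block detection, exclusion of supergene-linked
#' candidates, marker PCA and region genotype calls with HWE tests,
#' variant effect annotation with the candidate-gene filter cascade and
#' association rule, and (when a tree is supplied) ratio-calibrated
#' dating. Every stage's output is kept in the returned report; when
#' \code{outdir} is given, fixtures and result tables are also written.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param outdir Optional artifact directory (default: a tempdir).
#' @param windowSize,minSnps Window grid and QC (100 kb, 10 SNPs).
#' @param fstQuantile FST outlier quantile (0.95).
#' @param groupDist,flank xpEHH clustering parameters (100 kb each).
#' @param ehhsLimit,alpha EHHS truncation limit and FDR threshold.
#' @param maxRf,minCallRate Linkage-map parameters (0.25; call rate 0.7,
#'   the relaxed-map setting used for supergene linkage assignment).
#' @param assocThreshold Association-rule fraction (0.9).
#' @param effectFlank Upstream/downstream flank for effects (5 kb).
#' @param tree,targetTips,calibTips,calibAge,calibHpd Dating inputs
#'   (stage skipped when \code{tree} is NULL).
#' @param skip Character vector of stage names to skip
#'   (\code{"effects"}, \code{"dating"}).
#' @param verbose Emit stage messages.
#' @return list of class \code{RunReport}.
#' @export
runPipeline <- function(cfg, outdir = NULL,
                        windowSize = 1e5L, minSnps = 10L,
                        fstQuantile = 0.95, groupDist = 1e5L,
                        flank = 1e5L, ehhsLimit = 0.05, alpha = 0.05,
                        maxRf = 0.25, minCallRate = 0.7,
                        assocThreshold = 0.9, effectFlank = 5000L,
                        tree = NULL, targetTips = NULL, calibTips = NULL,
                        calibAge = 18, calibHpd = 8,
                        skip = character(0), verbose = TRUE) {
  stopifnot(inherits(cfg, "SimConfig"))
  report <- list(seed = cfg$seed, config = cfg,
                 version = as.character(utils::packageVersion("supersweep")))
  .stageMsg(verbose, "simulating cohort (seed ", cfg$seed, ")")
  cohort <- simulateCohort(cfg)
  geno <- cohort$geno
  truth <- cohort$truth
  brood <- tryCatch(simulateBrood(cfg, cohort), error = function(e) NULL)
  report$truth <- truth[c("supergene", "sweeps", "assocSites",
                          "admixedId", "motherId")]
  if (!is.null(outdir)) {
    .stageMsg(verbose, "writing fixtures to ", outdir)
    report$files <- writeFixtures(cohort, brood, cfg, outdir)
  }

  .stageMsg(verbose, "windowed statistics")
  wt <- windowTable(geno, popA = "H", popB = "P",
                    windowSize = windowSize, minSnps = minSnps)
  report$windows <- wt
  report$het <- list(H = sampleHetInbreeding(geno, "H"),
                     P = sampleHetInbreeding(geno, "P"))

  .stageMsg(verbose, "xpEHH scan (P vs H)")
  xp <- xpehhScan(geno, pop1 = "P", pop2 = "H", limit = ehhsLimit,
                  alpha = alpha)
  report$xpehh <- xp

  .stageMsg(verbose, "FST outliers and clustering")
  wt <- fstOutlierWindows(wt, quantile = fstQuantile)
  report$fstThreshold <- attr(wt, "threshold")
  fstCl <- clusterOutlierWindows(wt)
  report$fstClusters <- fstCl
  xpCl <- xpehhClusters(xp, groupDist = groupDist, flank = flank,
                        scaffoldLengths = truth$scaffoldLengths,
                        pop1 = "P", pop2 = "H")
  report$xpehhClusters <- xpCl
  cand <- intersectCandidates(fstCl, xpCl)
  report$candidatesAll <- cand

  supergeneRegions <- NULL
  scaffoldGroups <- data.frame(scaffold = character(0),
                               group = integer(0))
  supergeneGroups <- integer(0)
  blockMarkers <- NULL
  if (!is.null(brood)) {
    .stageMsg(verbose, "linkage map from ", ncol(brood$geno), " sons")
    lm <- buildLinkageMap(brood$geno, maxRf = maxRf,
                          minCallRate = minCallRate)
    report$linkageGroups <- length(unique(lm$groups))
    report$linkageMap <- lm$map
    scaffoldGroups <- lm$scaffoldGroups
    .stageMsg(verbose, "non-recombining block detection")
    blocks <- detectNonrecombBlock(brood$geno)
    report$blocks <- lapply(blocks, function(b)
      b[c("markers", "intervals")])
    if (length(blocks)) {
      blk <- blocks[[1]]
      blockMarkers <- blk$markers
      supergeneRegions <- blk$intervals[, c("scaffold", "start", "end")]
      blkGroups <- lm$groups[intersect(blockMarkers, names(lm$groups))]
      if (length(blkGroups)) {
        supergeneGroups <- as.integer(names(which.max(table(blkGroups))))
      }
      report$supergeneBlock <- blk
    }
  }
  ex <- excludeLinked(cand, scaffoldGroups, supergeneGroups,
                      supergeneRegions)
  report$candidates <- ex$retained
  report$candidatesInSupergene <- ex$excluded

  if (!is.null(brood) && !is.null(blockMarkers)) {
    .stageMsg(verbose, "marker PCA and region genotypes")
    shared <- intersect(blockMarkers, .markerIds(geno))
    if (length(shared) >= 2) {
      pca <- markerPca(brood$geno, geno, shared)
      report$markerPca <- pca
      dg <- diagnosticSites(brood$geno, pca$maleClass, shared)
      report$diagnosticSites <- dg
      rg <- callRegionGenotype(geno, dg)
      rg$population <- populations(geno)[match(rg$sampleId,
                                               sampleIds(geno))]
      report$regionGenotypes <- rg
      tabFor <- function(p) {
        calls <- rg$call[rg$population == p]
        c(hom1 = sum(calls == "Sp/Sp"), het = sum(calls == "Sh/Sp"),
          hom2 = sum(calls == "Sh/Sh"),
          ambiguous = sum(calls == "ambiguous"))
      }
      report$genotypeTables <- list(H = tabFor("H"), P = tabFor("P"))
      hweFor <- function(tab) hweChisq(c(tab[["hom1"]], tab[["het"]],
                                         tab[["hom2"]]))
      report$hwe <- list(H = hweFor(report$genotypeTables$H),
                         P = hweFor(report$genotypeTables$P))
    }
  }

  if (!("effects" %in% skip) && !is.null(report$files$gff3) &&
      nrow(report$candidates) > 0) {
    .stageMsg(verbose, "effect annotation and candidate genes")
    gm <- readGeneModels(report$files$gff3)
    genome <- Biostrings::readDNAStringSet(report$files$genomeFa)
    names(genome) <- sub(" .*", "", names(genome))
    flags <- utils::read.table(report$files$geneFlags, header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
    rc <- report$candidates
    inCand <- rep(FALSE, nrow(geno))
    sc <- scaffolds(geno); po <- positions(geno)
    for (i in seq_len(nrow(rc))) {
      inCand <- inCand | (sc == rc$scaffold[i] & po >= rc$start[i] &
                            po <= rc$end[i])
    }
    snps <- data.frame(scaffold = sc[inCand], pos = po[inCand],
                       ref = refAllele(geno)[inCand],
                       alt = altAllele(geno)[inCand],
                       stringsAsFactors = FALSE)
    eff <- annotateEffects(snps, gm, genome, flank = effectFlank)
    report$effects <- eff
    report$effectSummary <- effectSummary(eff)
    genesInRegions <- unique(eff$geneId[!is.na(eff$geneId)])
    filt <- filterCandidateGenes(genesInRegions, flags, eff)
    report$geneTiers <- filt
    nsSnps <- unique(eff[eff$category == "non_synonymous_variant",
                         c("scaffold", "pos")])
    if (nrow(nsSnps) > 0) {
      assoc <- associationRule(geno, nsSnps, popH = "H", popP = "P",
                               threshold = assocThreshold,
                               effects = eff)
      report$association <- assoc
      gp <- attr(assoc, "genePass")
      report$associationGenes <-
        intersect(names(gp)[gp], filt$tier2)
    }
  } else if ("effects" %in% skip) {
    report$effects <- "skipped"
  }

  if (!("dating" %in% skip) && !is.null(tree)) {
    .stageMsg(verbose, "ratio-calibrated dating")
    report$dating <- dateDivergence(tree, targetTips, calibTips,
                                    calibAge, calibHpd)
  }

  class(report) <- "RunReport"
  if (!is.null(outdir)) .writeReportArtifacts(report, outdir)
  report
}

.writeReportArtifacts <- function(report, outdir) {
  wt <- report$windows
  utils::write.table(wt, file.path(outdir, "windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$xpehh, file.path(outdir, "xpehh.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$candidates,
                     file.path(outdir, "candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$regionGenotypes)) {
    utils::write.table(report$regionGenotypes,
                       file.path(outdir, "region_genotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    seed = report$seed,
    fstThreshold = report$fstThreshold,
    nFstClusters = nrow(report$fstClusters),
    nXpehhOutliers = sum(report$xpehh$outlier, na.rm = TRUE),
    nXpehhClusters = nrow(report$xpehhClusters),
    nCandidates = nrow(report$candidates),
    nCandidatesInSupergene = nrow(report$candidatesInSupergene),
    linkageGroups = report$linkageGroups,
    genotypeTables = report$genotypeTables)
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("supersweep run report (seed ", x$seed, ")\n", sep = "")
  cat("  windows: ", nrow(x$windows), " (FST threshold ",
      signif(x$fstThreshold, 3), ")\n", sep = "")
  cat("  FST clusters: ", nrow(x$fstClusters),
      "; xpEHH outlier SNPs: ", sum(x$xpehh$outlier, na.rm = TRUE),
      " in ", nrow(x$xpehhClusters), " cluster(s)\n", sep = "")
  cat("  final candidates: ", nrow(x$candidates),
      " (", nrow(x$candidatesInSupergene), " excluded as supergene-linked)\n",
      sep = "")
  if (!is.null(x$linkageGroups)) {
    cat("  linkage groups: ", x$linkageGroups, "\n", sep = "")
  }
  if (!is.null(x$genotypeTables)) {
    cat("  region genotypes H (hom1/het/hom2): ",
        paste(x$genotypeTables$H[1:3], collapse = "/"),
        "; P: ", paste(x$genotypeTables$P[1:3], collapse = "/"), "\n",
        sep = "")
    cat(sprintf("  HWE chi2: H %.4f, P %.4f\n", x$hwe$H$chi2,
                x$hwe$P$chi2))
  }
  if (!is.null(x$dating) && inherits(x$dating, "DatingResult")) {
    print(x$dating)
  }
  invisible(x)
}
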