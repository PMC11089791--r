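## Non-recombining-block detection, marker-PCA haplotype classification,
## region-level genotype calls, LD matrices, TE/exon content windows, and
## ratio-calibrated divergence dating.

#' Detect non-recombining marker blocks in a haploid brood
#'
#' Markers are partitioned so that within a block every pair has zero
#' recombinants after phase-polarity alignment (a marker and its
#' complement pattern are the same signal). Blocks with at least
#' \code{minMarkers} members are reported with their physical extent and
#' the shared male segregation pattern (two haplotype classes).
#'
#' @param brood \linkS4class{GenotypeMatrix} of haploid males at
#'   maternal-heterozygous markers.
#' @param minMarkers Minimum markers per reported block (default 5).
#' @param maxMissing Exclude markers missing in more than this fraction
#'   of males (default 0.1, logged).
#' @return List of blocks, largest first; each is a list with
#'   \code{markers}, \code{intervals} (scaffold, start, end, nMarkers),
#'   \code{maleClass} (integer 1/2 per male, NA if ambiguous).
#' @export
detectNonrecombBlock <- function(brood, minMarkers = 5L,
                                 maxMissing = 0.1) {
  G <- dosage(brood)
  rownames(G) <- paste0(scaffolds(brood), ":", positions(brood))
  missFrac <- rowMeans(is.na(G))
  drop <- missFrac > maxMissing
  if (any(drop)) message("detectNonrecombBlock: excluded ", sum(drop),
                         " marker(s) with >", 100 * maxMissing,
                         "% missing")
  G <- G[!drop, , drop = FALSE]
  sc <- scaffolds(brood)[!drop]; po <- positions(brood)[!drop]
  rf <- recombFractions(G, minShared = 2L)
  memb <- buildLinkageGroups(rf, maxRf = 0)
  ## complete linkage is a pairwise property: refine each zero-rf
  ## component to a clique by peeling the worst offender
  components <- split(seq_len(nrow(G)), memb)
  cliques <- lapply(components, function(ii) {
    repeat {
      bad <- rowSums(rf[ii, ii, drop = FALSE] > 0, na.rm = TRUE)
      if (all(bad == 0) || length(ii) == 0) break
      ii <- ii[-which.max(bad)]
    }
    ii
  })
  cliques <- cliques[vapply(cliques, length, 1L) >= minMarkers]
  blocks <- lapply(cliques, function(ii) {
    Gb <- G[ii, , drop = FALSE]
    # polarity-align every pattern to the first marker, then consensus
    refPat <- Gb[1, ]
    aligned <- t(apply(Gb, 1, function(p) {
      ok <- !is.na(p) & !is.na(refPat)
      if (mean(p[ok] != refPat[ok]) > 0.5) 1L - p else p
    }))
    cons <- colMeans(aligned, na.rm = TRUE)
    maleClass <- ifelse(is.nan(cons) | cons == 0.5, NA_integer_,
                        ifelse(cons > 0.5, 2L, 1L))
    iv <- do.call(rbind, lapply(split(po[ii], sc[ii]), function(p) {
      data.frame(start = min(p), end = max(p), nMarkers = length(p))
    }))
    intervals <- data.frame(scaffold = rownames(iv), iv,
                            row.names = NULL, stringsAsFactors = FALSE)
    list(markers = rownames(G)[ii], intervals = intervals,
         maleClass = maleClass)
  })
  blocks[order(-vapply(blocks, function(b) length(b$markers), 1L))]
}

.markerIds <- function(x) paste0(scaffolds(x), ":", positions(x))

#' PCA haplotype classification of males and queens at block markers
#'
#' The PCA is fitted on mean-centered male dosages (haploid dosage
#' doubled to share the diploid scale); queens are projected onto the
#' male-derived axes. Males are classified by the sign of PC1 into two
#' haplotype groups; queens by nearest of the two male centroids and
#' their midpoint (hom1 / het / hom2). PC1 sign is canonicalized so that
#' the reference-allele-rich male class scores positive. Missing dosages
#' are mean-imputed for the fit/projection only.
#'
#' @param males,queens \linkS4class{GenotypeMatrix} objects (haploid
#'   males, diploid queens).
#' @param markers Character marker IDs (\code{"scaffold:pos"}) shared by
#'   both matrices; monomorphic-in-males markers are dropped from the fit.
#' @return list: \code{maleScores}, \code{maleClass} (1 = positive PC1),
#'   \code{queenScores}, \code{queenClass} (\code{"hom1"}, \code{"het"},
#'   \code{"hom2"}), \code{varExplained}, \code{markers}.
#' @export
markerPca <- function(males, queens, markers) {
  mi <- match(markers, .markerIds(males))
  qi <- match(markers, .markerIds(queens))
  if (anyNA(mi) || anyNA(qi)) stop("marker(s) absent from male or queen matrix")
  M <- t(dosage(males)[mi, , drop = FALSE]) * 2  # males x markers
  Q <- t(dosage(queens)[qi, , drop = FALSE])
  poly <- apply(M, 2, function(v) length(unique(v[!is.na(v)])) > 1)
  M <- M[, poly, drop = FALSE]; Q <- Q[, poly, drop = FALSE]
  mu <- colMeans(M, na.rm = TRUE)
  imp <- function(X) {
    for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
    X
  }
  M <- imp(M); Q <- imp(Q)
  fit <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  ms <- fit$x[, 1]
  # canonical sign: the ref-rich class (lower mean dosage) scores positive
  cls <- ifelse(ms >= 0, 1L, 2L)
  flip <- mean(rowSums(M)[cls == 1L]) > mean(rowSums(M)[cls == 2L])
  if (flip) {
    fit$rotation[, 1] <- -fit$rotation[, 1]
    ms <- -ms
  }
  maleClass <- ifelse(ms >= 0, 1L, 2L)
  qs <- scale(Q, center = fit$center, scale = FALSE) %*% fit$rotation[, 1]
  c1 <- mean(ms[maleClass == 1L]); c2 <- mean(ms[maleClass == 2L])
  anchors <- c(hom1 = c1, het = (c1 + c2) / 2, hom2 = c2)
  queenClass <- names(anchors)[apply(abs(outer(qs[, 1], anchors, "-")),
                                     1, which.min)]
  names(queenClass) <- rownames(Q)
  varExpl <- fit$sdev^2 / sum(fit$sdev^2)
  list(maleScores = stats::setNames(ms, rownames(M)),
       maleClass = stats::setNames(maleClass, rownames(M)),
       queenScores = stats::setNames(qs[, 1], rownames(Q)),
       queenClass = queenClass, varExplained = varExpl,
       markers = markers[poly])
}

#' Diagnostic sites: fixed differences between the two male classes
#'
#' @param males Haploid \linkS4class{GenotypeMatrix}.
#' @param maleClass Integer 1/2 class per male (from
#'   \code{\link{detectNonrecombBlock}} or \code{\link{markerPca}}).
#' @param markers Marker IDs to consider (default: all).
#' @return data.frame: marker, scaffold, pos, class1Allele.
#' @export
diagnosticSites <- function(males, maleClass, markers = NULL) {
  ids <- .markerIds(males)
  if (is.null(markers)) markers <- ids
  ii <- match(markers, ids)
  G <- dosage(males)[ii, , drop = FALSE]
  c1 <- which(maleClass == 1L); c2 <- which(maleClass == 2L)
  a1 <- apply(G[, c1, drop = FALSE], 1, function(v) {
    u <- unique(v[!is.na(v)]); if (length(u) == 1) u else NA_integer_
  })
  a2 <- apply(G[, c2, drop = FALSE], 1, function(v) {
    u <- unique(v[!is.na(v)]); if (length(u) == 1) u else NA_integer_
  })
  fixedDiff <- !is.na(a1) & !is.na(a2) & a1 != a2
  data.frame(marker = markers[fixedDiff],
             scaffold = scaffolds(males)[ii][fixedDiff],
             pos = positions(males)[ii][fixedDiff],
             class1Allele = a1[fixedDiff], stringsAsFactors = FALSE)
}

#' Region-level supergene genotype call per queen
#'
#' At the diagnostic sites (fixed differences between the two male
#' haplotype classes, oriented by \code{class1Allele}) each queen's
#' genotypes are tallied; if the fraction homozygous for the class-1
#' allele is at least \code{threshold} the call is \code{hom1}
#' (e.g. Sp/Sp when class 1 is the reference-like haplotype), likewise
#' \code{hom2} and \code{het}; otherwise \code{ambiguous}. Queens with
#' fewer than \code{minSites} genotyped diagnostic sites are ambiguous.
#'
#' @param queens Diploid \linkS4class{GenotypeMatrix}.
#' @param diag data.frame from \code{\link{diagnosticSites}}.
#' @param threshold Majority fraction for a call (default 0.8).
#' @param minSites Minimum genotyped diagnostic sites (default 10).
#' @param labels Call labels for (hom1, het, hom2).
#' @return data.frame: sampleId, nHom1, nHet, nHom2, nGenotyped, call.
#' @export
callRegionGenotype <- function(queens, diag, threshold = 0.8,
                               minSites = 10L,
                               labels = c("Sp/Sp", "Sh/Sp", "Sh/Sh")) {
  ii <- match(diag$marker, .markerIds(queens))
  if (anyNA(ii)) stop("diagnostic site(s) absent from queen matrix")
  D <- dosage(queens)[ii, , drop = FALSE]
  # orient so that dosage counts class-2 alleles
  flip <- diag$class1Allele == 1L
  D[flip, ] <- 2L - D[flip, , drop = FALSE]
  out <- lapply(seq_len(ncol(D)), function(j) {
    v <- D[, j]; v <- v[!is.na(v)]
    n <- length(v)
    nHom1 <- sum(v == 0L); nHet <- sum(v == 1L); nHom2 <- sum(v == 2L)
    call <- if (n < minSites) "ambiguous"
      else if (nHom1 / n >= threshold) labels[1]
      else if (nHet / n >= threshold) labels[2]
      else if (nHom2 / n >= threshold) labels[3]
      else "ambiguous"
    data.frame(sampleId = sampleIds(queens)[j], nHom1 = nHom1,
               nHet = nHet, nHom2 = nHom2, nGenotyped = n, call = call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pairwise LD (r-squared) matrix for a sample subset in a region
#'
#' Full pairwise haplotype r-squared over the region's sites; sites
#' invariant within the subset are reported as NA (the white cells of an
#' LD heatmap).
#'
#' @param x Phased \linkS4class{GenotypeMatrix}.
#' @param samples Sample IDs (at least 2 diploid samples).
#' @param region data.frame (scaffold, start, end) or \code{GRanges}.
#' @return Symmetric matrix (sites x sites) named \code{scaffold:pos}.
#' @export
ldMatrix <- function(x, samples, region) {
  cd <- SummarizedExperiment::colData(x)
  idx <- match(samples, rownames(cd))
  if (sum(cd$ploidy[idx] == 2L) < 2) {
    stop("need at least 2 diploid samples")
  }
  if (is.data.frame(region)) {
    region <- GenomicRanges::GRanges(region$scaffold,
      IRanges::IRanges(region$start, region$end))
  }
  hit <- GenomicRanges::findOverlaps(SummarizedExperiment::rowRanges(x),
                                     region)
  sites <- sort(unique(S4Vectors::queryHits(hit)))
  xs <- x[sites, ]
  H <- haplotypes(xs, samples)
  r <- suppressWarnings(stats::cor(t(H), use = "pairwise.complete.obs"))
  r2 <- r^2
  f <- rowMeans(H, na.rm = TRUE)
  invariant <- is.na(f) | f == 0 | f == 1
  r2[invariant, ] <- NA_real_
  r2[, invariant] <- NA_real_
  diag(r2)[!invariant] <- 1
  dimnames(r2) <- list(.markerIds(xs), .markerIds(xs))
  r2
}

#' TE and exon bp fractions in windows across a region
#'
#' Per non-overlapping window, the fraction of bp covered by the merged
#' repeat intervals and by the merged exon intervals.
#'
#' @param region data.frame (scaffold, start, end) or single-interval
#'   \code{GRanges}.
#' @param geneModels Gene-model list from \code{\link{readGeneModels}}
#'   (exons are pooled and merged), or NULL.
#' @param teIntervals \code{GRanges} of repeats, or NULL.
#' @param windowSize Window size in bp (default 100 kb).
#' @return data.frame: scaffold, start, end, teFrac, exonFrac.
#' @export
contentWindows <- function(region, geneModels = NULL, teIntervals = NULL,
                           windowSize = 1e5L) {
  if (is.data.frame(region)) {
    region <- GenomicRanges::GRanges(region$scaffold,
      IRanges::IRanges(region$start, region$end))
  }
  covFrac <- function(win, iv) {
    if (is.null(iv) || length(iv) == 0) return(rep(0, length(win)))
    iv <- GenomicRanges::reduce(iv)
    hits <- GenomicRanges::findOverlaps(win, iv)
    ow <- GenomicRanges::width(GenomicRanges::pintersect(
      win[S4Vectors::queryHits(hits)], iv[S4Vectors::subjectHits(hits)]))
    out <- rep(0, length(win))
    agg <- tapply(ow, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- agg
    out / GenomicRanges::width(win)
  }
  exons <- NULL
  if (!is.null(geneModels)) {
    exons <- GenomicRanges::reduce(do.call(
      c, unname(lapply(geneModels, `[[`, "exons"))))
  }
  out <- lapply(seq_along(region), function(i) {
    s0 <- GenomicRanges::start(region)[i]
    e0 <- GenomicRanges::end(region)[i]
    ws <- seq(s0, e0, by = windowSize)
    we <- pmin(ws + windowSize - 1L, e0)
    win <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(region))[i],
      IRanges::IRanges(ws, we))
    data.frame(scaffold = as.character(GenomicRanges::seqnames(win)),
               start = ws, end = we,
               teFrac = covFrac(win, teIntervals),
               exonFrac = covFrac(win, exons),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.roundAway <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

.nodeHeight <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("tip(s) not in tree: ",
                       paste(tips[is.na(idx)], collapse = ", "))
  node <- if (length(idx) == 1) idx else ape::getMRCA(tree, idx)
  depth <- ape::node.depth.edgelength(tree)
  desc <- if (node <= length(tree$tip.label)) node else {
    match(ape::extract.clade(tree, node)$tip.label, tree$tip.label)
  }
  mean(depth[desc] - depth[node])
}

#' Ratio-calibrated divergence dating from a phylogram
#'
#' Node height is the mean root-to-tip path length below the node (so
#' non-ultrametric trees are tolerated). The target/calibration
#' height ratio scales the calibration age and its HPD half-width;
#' results are rounded to 2 decimals, half away from zero.
#'
#' @param tree An \code{ape} \code{phylo} object, or a newick file path
#'   or string.
#' @param targetTips Tip labels whose MRCA is the target node (e.g. the
#'   two supergene haplotype clades).
#' @param calibTips Tip labels whose MRCA is the calibration node.
#' @param calibAge Calibration age (MY).
#' @param calibHpd Calibration 95\% HPD half-width (MY), or NA.
#' @return list of class \code{DatingResult}: rho, age, hpdHalfWidth,
#'   hpdLower, hpdUpper (rounded), plus the unrounded \code{ageRaw}.
#' @export
dateDivergence <- function(tree, targetTips, calibTips, calibAge,
                           calibHpd = NA) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
      else ape::read.tree(text = tree)
  }
  hT <- .nodeHeight(tree, targetTips)
  hC <- .nodeHeight(tree, calibTips)
  if (hC <= 0) stop("calibration node height is zero")
  rho <- hT / hC
  if (rho > 1) warning("target node is older than the calibration node")
  age <- calibAge * rho
  hpd <- calibHpd * rho
  structure(list(calibAge = calibAge, calibHpd = calibHpd, rho = rho,
                 ageRaw = age,
                 age = .roundAway(age),
                 hpdHalfWidth = .roundAway(hpd),
                 hpdLower = .roundAway((calibAge - calibHpd) * rho),
                 hpdUpper = .roundAway((calibAge + calibHpd) * rho)),
            class = "DatingResult")
}

#' @export
print.DatingResult <- function(x, ...) {
  cat(sprintf(
    "Ratio-calibrated divergence: %.2f MY (95%% HPD %.2f-%.2f; rho = %.4g)\n",
    x$age, x$hpdLower, x$hpdUpper, x$rho))
  invisible(x)
}
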