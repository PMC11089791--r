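## The outlier-intersection sweep-candidate procedure: FST top-quantile
## window clusters with sweep signatures, xpEHH SNP clusters, their
## genomic intersection, and exclusion of supergene-linked candidates.

#' Flag FST outlier windows
#'
#' QC-passing windows with FST strictly greater than the empirical
#' \code{quantile} (type-7, linear interpolation) are flagged. The
#' realized threshold is attached as attribute \code{"threshold"}.
#'
#' @param wt Window table from \code{\link{windowTable}}.
#' @param quantile Outlier quantile (default 0.95 = top 5\%).
#' @return \code{wt} with a logical \code{fstOutlier} column.
#' @export
fstOutlierWindows <- function(wt, quantile = 0.95) {
  use <- wt$qcPass & !is.na(wt$fst)
  if (sum(use) < 20) stop("fewer than 20 usable windows: quantile unstable")
  thr <- stats::quantile(wt$fst[use], probs = quantile, type = 7,
                         names = FALSE)
  wt$fstOutlier <- use & wt$fst > thr
  attr(wt, "threshold") <- thr
  wt
}

#' Cluster adjacent FST outlier windows and classify the swept population
#'
#' Strictly consecutive outlier windows (sharing a boundary on the same
#' scaffold) are merged. A cluster is classified as swept in population X
#' iff its mean Tajima's D in X is negative AND its mean pi in X is lower
#' than in the other population; clusters matching neither population are
#' dropped (count reported via message).
#'
#' @param wt Output of \code{\link{fstOutlierWindows}} (carries the
#'   \code{"populations"} attribute from \code{\link{windowTable}}).
#' @return data.frame: scaffold, start, end, nWindows, sweptPop, meanFst,
#'   meanPi_A, meanPi_B, meanD_A, meanD_B.
#' @export
clusterOutlierWindows <- function(wt) {
  pops <- attr(wt, "populations")
  o <- wt[wt$fstOutlier, , drop = FALSE]
  o <- o[order(o$scaffold, o$start), , drop = FALSE]
  if (nrow(o) == 0) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), nWindows = integer(0),
                      sweptPop = character(0), meanFst = numeric(0),
                      meanPi_A = numeric(0), meanPi_B = numeric(0),
                      meanD_A = numeric(0), meanD_B = numeric(0)))
  }
  newClust <- c(TRUE, !(o$scaffold[-1] == o$scaffold[-nrow(o)] &
                          o$start[-1] == o$end[-nrow(o)] + 1L))
  cid <- cumsum(newClust)
  out <- lapply(split(seq_len(nrow(o)), cid), function(ii) {
    cl <- o[ii, , drop = FALSE]
    mDA <- mean(cl$tajimaD_A, na.rm = TRUE)
    mDB <- mean(cl$tajimaD_B, na.rm = TRUE)
    mPA <- mean(cl$pi_A); mPB <- mean(cl$pi_B)
    swept <- if (!is.na(mDA) && mDA < 0 && mPA < mPB) pops[["A"]]
      else if (!is.na(mDB) && mDB < 0 && mPB < mPA) pops[["B"]]
      else NA_character_
    data.frame(scaffold = cl$scaffold[1], start = min(cl$start),
               end = max(cl$end), nWindows = nrow(cl), sweptPop = swept,
               meanFst = mean(cl$fst), meanPi_A = mPA, meanPi_B = mPB,
               meanD_A = mDA, meanD_B = mDB, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  nDrop <- sum(is.na(out$sweptPop))
  if (nDrop > 0) message("clusterOutlierWindows: dropped ", nDrop,
                         " cluster(s) without a sweep signature")
  out <- out[!is.na(out$sweptPop), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster xpEHH outlier SNPs into candidate sweep regions
#'
#' Outlier SNPs (\code{q < alpha} flag from \code{\link{xpehhScan}}) are
#' grouped by single linkage within \code{groupDist} on the same
#' scaffold. The candidate interval is the most significant SNP (largest
#' |z|; ties broken by smaller coordinate) +/- \code{flank}, clipped to
#' the scaffold; the swept population comes from the sign of z.
#'
#' @param xp Output of \code{\link{xpehhScan}}.
#' @param groupDist Single-linkage grouping distance (default 100 kb).
#' @param flank Candidate flank around the top SNP (default 100 kb).
#' @param scaffoldLengths Named vector of scaffold lengths for clipping;
#'   if NULL, clipping uses the last SNP position per scaffold.
#' @param pop1,pop2 Population labels matching the scan's orientation.
#' @return data.frame: scaffold, start, end, topPos, topZ, nSnps,
#'   sweptPop.
#' @export
xpehhClusters <- function(xp, groupDist = 1e5L, flank = 1e5L,
                          scaffoldLengths = NULL,
                          pop1 = "pop1", pop2 = "pop2") {
  o <- xp[xp$outlier, , drop = FALSE]
  if (nrow(o) == 0) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), topPos = integer(0),
                      topZ = numeric(0), nSnps = integer(0),
                      sweptPop = character(0)))
  }
  o <- o[order(o$scaffold, o$pos), , drop = FALSE]
  newClust <- c(TRUE, !(o$scaffold[-1] == o$scaffold[-nrow(o)] &
                          o$pos[-1] - o$pos[-nrow(o)] <= groupDist))
  cid <- cumsum(newClust)
  out <- lapply(split(seq_len(nrow(o)), cid), function(ii) {
    cl <- o[ii, , drop = FALSE]
    top <- which(abs(cl$z) == max(abs(cl$z)))
    top <- top[which.min(cl$pos[top])]
    L <- if (!is.null(scaffoldLengths)) {
      scaffoldLengths[[cl$scaffold[1]]]
    } else max(xp$pos[xp$scaffold == cl$scaffold[1]])
    data.frame(scaffold = cl$scaffold[1],
               start = max(1L, cl$pos[top] - flank),
               end = min(L, cl$pos[top] + flank),
               topPos = cl$pos[top], topZ = cl$z[top], nSnps = nrow(cl),
               sweptPop = if (cl$z[top] > 0) pop1 else pop2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.mergeIntervals <- function(df) {
  df <- df[order(df$scaffold, df$start), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(df))) {
    n <- length(out)
    if (n > 0 && out[[n]]$scaffold == df$scaffold[i] &&
        df$start[i] <= out[[n]]$end &&
        identical(out[[n]]$sweptPop, df$sweptPop[i])) {
      out[[n]]$end <- max(out[[n]]$end, df$end[i])
      out[[n]]$provenance <- paste(out[[n]]$provenance, df$provenance[i],
                                   sep = ";")
    } else {
      out[[n + 1L]] <- as.list(df[i, , drop = FALSE])
    }
  }
  do.call(rbind, lapply(out, as.data.frame))
}

#' Intersect FST-cluster and xpEHH-cluster candidate regions
#'
#' A candidate is the union interval of every (FST cluster, xpEHH
#' cluster) pair that overlaps by at least 1 bp with the same
#' swept-population label; overlapping candidates are merged. Provenance
#' (source cluster rows) is kept in the \code{provenance} column.
#'
#' @param fstClusters From \code{\link{clusterOutlierWindows}}.
#' @param xpClusters From \code{\link{xpehhClusters}}.
#' @return data.frame: scaffold, start, end, sweptPop, provenance.
#' @export
intersectCandidates <- function(fstClusters, xpClusters) {
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), sweptPop = character(0),
                      provenance = character(0))
  if (nrow(fstClusters) == 0 || nrow(xpClusters) == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(fstClusters))) {
    for (j in seq_len(nrow(xpClusters))) {
      if (fstClusters$scaffold[i] != xpClusters$scaffold[j]) next
      if (!identical(fstClusters$sweptPop[i], xpClusters$sweptPop[j])) next
      if (fstClusters$start[i] > xpClusters$end[j] ||
          xpClusters$start[j] > fstClusters$end[i]) next
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = fstClusters$scaffold[i],
        start = min(fstClusters$start[i], xpClusters$start[j]),
        end = max(fstClusters$end[i], xpClusters$end[j]),
        sweptPop = fstClusters$sweptPop[i],
        provenance = paste0("fst:", i, "+xpehh:", j),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- .mergeIntervals(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Remove candidates linked to the supergene
#'
#' Candidates on scaffolds assigned to a supergene linkage group, or
#' overlapping a supergene interval, are removed and reported separately.
#' Candidates on unplaced scaffolds are retained and flagged.
#'
#' @param candidates From \code{\link{intersectCandidates}}.
#' @param scaffoldGroups data.frame (scaffold, group): scaffold-to-
#'   linkage-group assignment.
#' @param supergeneGroups Character vector of linkage-group IDs in the
#'   supergene block.
#' @param supergeneRegions Optional data.frame (scaffold, start, end) of
#'   supergene intervals.
#' @return list: \code{retained} (with logical \code{unplaced} column)
#'   and \code{excluded}.
#' @export
excludeLinked <- function(candidates, scaffoldGroups,
                          supergeneGroups = character(0),
                          supergeneRegions = NULL) {
  if (nrow(candidates) == 0) {
    return(list(retained = cbind(candidates, unplaced = logical(0)),
                excluded = candidates))
  }
  grp <- scaffoldGroups$group[match(candidates$scaffold,
                                    scaffoldGroups$scaffold)]
  linked <- !is.na(grp) & grp %in% supergeneGroups
  if (!is.null(supergeneRegions) && nrow(supergeneRegions) > 0) {
    for (i in seq_len(nrow(supergeneRegions))) {
      hit <- candidates$scaffold == supergeneRegions$scaffold[i] &
        candidates$start <= supergeneRegions$end[i] &
        candidates$end >= supergeneRegions$start[i]
      linked <- linked | hit
    }
  }
  retained <- candidates[!linked, , drop = FALSE]
  retained$unplaced <- is.na(grp[!linked])
  rownames(retained) <- NULL
  excluded <- candidates[linked, , drop = FALSE]
  rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}
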