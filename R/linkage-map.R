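## Genetic map from a haploid single-mother brood: pairwise recombination
## fractions, single-linkage grouping, greedy ordering, Kosambi cM.

#' Kosambi mapping function
#'
#' \deqn{cM = 25 \ln\left(\frac{1+2r}{1-2r}\right)} converting a
#' recombination fraction to map distance allowing for interference.
#'
#' @param r Recombination fraction(s) in [0, 0.5).
#' @return Map distance in centimorgans.
#' @export
kosambi <- function(r) 25 * log((1 + 2 * r) / (1 - 2 * r))

#' Pairwise recombination fractions from a haploid brood
#'
#' For markers i, j over the males genotyped at both, d is the mismatch
#' fraction of the two 0/1 patterns and \code{rf = min(d, 1 - d)} (phase
#' polarity is unknown, so a pattern and its complement are the same
#' signal). Pairs sharing fewer than \code{minShared} males get NA.
#'
#' @param G Integer 0/1 matrix, markers x males (NA = missing), or a
#'   \linkS4class{GenotypeMatrix} of haploid samples.
#' @param minShared Minimum shared genotyped males per pair (default 20).
#' @return Symmetric matrix of recombination fractions (diagonal 0).
#' @export
recombFractions <- function(G, minShared = 20L) {
  if (is(G, "GenotypeMatrix")) {
    ids <- paste0(scaffolds(G), ":", positions(G))
    G <- dosage(G)
    rownames(G) <- ids
  }
  A <- (G == 1L); A[is.na(A)] <- FALSE
  B <- (G == 0L); B[is.na(B)] <- FALSE
  mism <- tcrossprod(A * 1, B * 1)
  mism <- mism + t(mism)
  shared <- tcrossprod((A | B) * 1)
  d <- mism / shared
  rf <- pmin(d, 1 - d)
  rf[shared < minShared] <- NA_real_
  diag(rf) <- 0
  dimnames(rf) <- list(rownames(G), rownames(G))
  rf
}

#' Single-linkage grouping of markers into linkage groups
#'
#' Markers i, j belong to one group iff they are connected by a chain of
#' pairs with \code{rf <= maxRf}.
#'
#' @param rf Recombination fraction matrix from
#'   \code{\link{recombFractions}}.
#' @param maxRf Maximum linking recombination fraction (default 0.25).
#' @return Integer vector of group memberships (named by marker).
#' @export
buildLinkageGroups <- function(rf, maxRf = 0.25) {
  adj <- !is.na(rf) & rf <= maxRf
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  names(memb) <- rownames(rf)
  memb
}

#' Greedy marker ordering and Kosambi map for one linkage group
#'
#' The two members of the largest-rf pair are taken as the chain
#' termini: the path starts at one of them and grows by repeatedly
#' appending the unplaced marker with the smallest rf to either current
#' endpoint. Cumulative cM comes from adjacent-pair Kosambi distances;
#' adjacent rf >= 0.5 is capped at 0.49 with a warning.
#'
#' @param markers Marker names (or indices) of one linkage group.
#' @param rf Recombination fraction matrix covering those markers.
#' @return data.frame: marker, orderIndex, rfAdj (to previous marker),
#'   cM (cumulative).
#' @export
orderAndMap <- function(markers, rf) {
  rfg <- rf[markers, markers, drop = FALSE]
  m <- length(markers)
  if (m == 1) {
    return(data.frame(marker = markers, orderIndex = 1L, rfAdj = NA_real_,
                      cM = 0, stringsAsFactors = FALSE))
  }
  rfw <- rfg
  rfw[is.na(rfw)] <- -Inf
  diag(rfw) <- -Inf
  start <- which(rfw == max(rfw), arr.ind = TRUE)[1, ]
  path <- start[[1]]
  placed <- rep(FALSE, m); placed[path] <- TRUE
  rfd <- rfg
  rfd[is.na(rfd)] <- Inf
  while (any(!placed)) {
    un <- which(!placed)
    ends <- c(path[1], path[length(path)])
    cand <- rfd[un, ends, drop = FALSE]
    ij <- which(cand == min(cand), arr.ind = TRUE)[1, ]
    k <- un[ij[[1]]]
    if (ij[[2]] == 1L) path <- c(k, path) else path <- c(path, k)
    placed[k] <- TRUE
  }
  rfAdj <- c(NA_real_, rfg[cbind(path[-m], path[-1])])
  capped <- !is.na(rfAdj) & rfAdj >= 0.5
  if (any(capped)) {
    warning(sum(capped), " adjacent rf value(s) >= 0.5 capped at 0.49")
    rfAdj[capped] <- 0.49
  }
  steps <- ifelse(is.na(rfAdj), 0, kosambi(rfAdj))
  data.frame(marker = markers[path], orderIndex = seq_len(m),
             rfAdj = rfAdj, cM = cumsum(steps), stringsAsFactors = FALSE)
}

#' Build a complete linkage map from a haploid brood
#'
#' Filters markers by call rate, computes recombination fractions, groups
#' at \code{maxRf}, and orders each group. Also reports a majority-vote
#' scaffold-to-linkage-group assignment.
#'
#' @param brood \linkS4class{GenotypeMatrix} of haploid males at
#'   maternal-heterozygous markers.
#' @param maxRf Grouping threshold (default 0.25).
#' @param minCallRate Keep markers genotyped in at least this fraction of
#'   males (default 1 = no missing data; 0.7 for a relaxed map).
#' @param minShared Minimum shared males per marker pair (default 20).
#' @return list: \code{map} (marker, scaffold, pos, group, orderIndex,
#'   rfAdj, cM), \code{rf} matrix, \code{groups} membership vector,
#'   \code{scaffoldGroups} (scaffold, group).
#' @export
buildLinkageMap <- function(brood, maxRf = 0.25, minCallRate = 1,
                            minShared = 20L) {
  G <- dosage(brood)
  rownames(G) <- paste0(scaffolds(brood), ":", positions(brood))
  callRate <- rowMeans(!is.na(G))
  keep <- callRate >= minCallRate
  G <- G[keep, , drop = FALSE]
  sc <- scaffolds(brood)[keep]; po <- positions(brood)[keep]
  rf <- recombFractions(G, minShared)
  groups <- buildLinkageGroups(rf, maxRf)
  maps <- lapply(sort(unique(groups)), function(g) {
    om <- orderAndMap(names(groups)[groups == g], rf)
    om$group <- g
    om
  })
  map <- do.call(rbind, maps)
  idx <- match(map$marker, rownames(G))
  map <- data.frame(marker = map$marker, scaffold = sc[idx],
                    pos = po[idx], group = map$group,
                    orderIndex = map$orderIndex, rfAdj = map$rfAdj,
                    cM = map$cM, stringsAsFactors = FALSE)
  sg <- do.call(rbind, lapply(split(map$group, map$scaffold), function(g) {
    tab <- table(g)
    data.frame(group = as.integer(names(tab)[which.max(tab)]))
  }))
  scaffoldGroups <- data.frame(scaffold = rownames(sg), group = sg$group,
                               stringsAsFactors = FALSE)
  rownames(scaffoldGroups) <- NULL
  list(map = map, rf = rf, groups = groups,
       scaffoldGroups = scaffoldGroups)
}
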