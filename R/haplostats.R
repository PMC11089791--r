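## Extended-haplotype-homozygosity statistics (EHH, EHHS, iES, xpEHH).
##
## Haplotype inputs are 0/1 integer matrices, sites x chromosomes, on a
## single scaffold, with a parallel vector of physical positions.

.ehhProfileSide <- function(hap, positions, core, members, initGrp,
                            denomPairs, dir, limit) {
  side <- cpp_ehh_side(hap, core - 1L, members - 1L, initGrp,
                       denomPairs, as.integer(dir), limit)
  mk <- side$markers + 1L
  truncReason <- if (length(mk) == 0) {
    "chromosome_end"
  } else if (utils::tail(side$values, 1) < limit) "limit_reached"
  else "chromosome_end"
  data.frame(marker = mk, pos = positions[mk], value = side$values)
}

#' Extended haplotype homozygosity (EHH) around a core site
#'
#' For the chromosomes carrying \code{coreAllele} at \code{coreSite},
#' EHH at marker x is the probability that two carriers are identical at
#' every marker between the core and x inclusive:
#' \eqn{\sum_h \binom{k_h}{2} / \binom{n_c}{2}} over the identity groups
#' of sizes \eqn{k_h}. Computed marker-by-marker left and right; the value
#' at the core itself is 1 and profiles are non-increasing.
#'
#' @param hap Integer 0/1 matrix, sites x chromosomes (one scaffold).
#' @param positions Physical positions (bp) per site.
#' @param coreSite Site index (row of \code{hap}).
#' @param coreAllele Core allele (0 or 1).
#' @param limit Truncate when EHH drops below this value (default 0:
#'   extend to the chromosome end or total decay).
#' @return List of class \code{EHHProfile}: \code{core}, \code{allele},
#'   \code{left}/\code{right} data.frames (marker, pos, value).
#' @export
ehh <- function(hap, positions, coreSite, coreAllele = 1L, limit = 0) {
  a <- hap[coreSite, ]
  members <- which(!is.na(a) & a == coreAllele)
  if (length(members) < 2) {
    stop("fewer than 2 carriers of allele ", coreAllele,
         " at the core site: EHH undefined")
  }
  denom <- choose(length(members), 2)
  initGrp <- rep(0L, length(members))
  structure(list(
    core = coreSite, corePos = positions[coreSite], allele = coreAllele,
    left = .ehhProfileSide(hap, positions, coreSite, members, initGrp,
                           denom, -1L, limit),
    right = .ehhProfileSide(hap, positions, coreSite, members, initGrp,
                            denom, 1L, limit)),
    class = "EHHProfile")
}

#' Site-specific extended haplotype homozygosity (EHHS)
#'
#' All chromosomes pooled; identity groups extend from the core to x and
#' are normalized by the core-site allele-class homozygosity:
#' \eqn{EHHS(x) = \sum_h \binom{k_h}{2} / \sum_g \binom{m_g}{2}} with
#' \eqn{m_g} the core allele-class sizes, so \eqn{EHHS(core) = 1}.
#'
#' @inheritParams ehh
#' @return List of class \code{EHHProfile} (no \code{allele} element).
#' @export
ehhs <- function(hap, positions, coreSite, limit = 0) {
  a <- hap[coreSite, ]
  members <- which(!is.na(a))
  alleles <- a[members]
  if (length(unique(alleles)) < 2) stop("core site is monomorphic")
  denom <- sum(choose(table(alleles), 2))
  if (denom <= 0) stop("no homozygous pair at the core site")
  structure(list(
    core = coreSite, corePos = positions[coreSite], allele = NA,
    left = .ehhProfileSide(hap, positions, coreSite, members,
                           as.integer(alleles), denom, -1L, limit),
    right = .ehhProfileSide(hap, positions, coreSite, members,
                            as.integer(alleles), denom, 1L, limit)),
    class = "EHHProfile")
}

#' Integrate an EHHS profile into iES
#'
#' Trapezoidal integral of EHHS over physical bp on each side of the core
#' (starting from value 1 at the core position), truncated at the first
#' marker where EHHS < \code{limit} (that marker included as the
#' boundary); the two sides are summed. A core with no flanking marker on
#' either side yields iES = 0 with attribute \code{unscorable = TRUE}.
#'
#' @param profile An \code{EHHProfile} from \code{\link{ehhs}} (or a list
#'   with \code{corePos}, \code{left}, \code{right}).
#' @param limit Truncation level (default 0.05).
#' @return iES in bp units.
#' @export
integrateIes <- function(profile, limit = 0.05) {
  sideArea <- function(df) {
    if (nrow(df) == 0) return(0)
    prevVal <- 1; prevPos <- profile$corePos; area <- 0
    for (i in seq_len(nrow(df))) {
      v <- df$value[i]; p <- df$pos[i]
      area <- area + (prevVal + v) / 2 * abs(p - prevPos)
      prevVal <- v; prevPos <- p
      if (v < limit) break
    }
    area
  }
  if (nrow(profile$left) == 0 && nrow(profile$right) == 0) {
    return(structure(0, unscorable = TRUE))
  }
  sideArea(profile$left) + sideArea(profile$right)
}

#' Cross-population xpEHH scan
#'
#' For every site scorable in both populations, the raw score is
#' \eqn{\ln(iES_1 / iES_2)}; scores are standardized globally (all
#' scaffolds pooled) to z-scores, two-sided normal p-values are computed,
#' and Benjamini-Hochberg q-values flag outliers at \code{q < alpha}.
#' Positive scores indicate longer haplotype homozygosity (a sweep) in
#' population 1. Sites monomorphic in a population, or with iES = 0, are
#' unscorable and excluded before standardization.
#'
#' @param x A \linkS4class{GenotypeMatrix} with phased samples.
#' @param pop1,pop2 Population labels (positive score = sweep in pop1).
#' @param limit EHHS integration truncation limit (default 0.05).
#' @param alpha FDR threshold for the outlier flag (default 0.05).
#' @return data.frame: scaffold, pos, ies1, ies2, raw, z, p, q, outlier;
#'   unscorable sites carry NA statistics.
#' @export
xpehhScan <- function(x, pop1, pop2, limit = 0.05, alpha = 0.05) {
  H1 <- haplotypes(x, .popSamples(x, pop1))
  H2 <- haplotypes(x, .popSamples(x, pop2))
  sc <- scaffolds(x); po <- positions(x)
  ies1 <- ies2 <- rep(NA_real_, nrow(x))
  ok1 <- ok2 <- logical(nrow(x))
  for (s in unique(sc)) {
    idx <- which(sc == s)
    r1 <- cpp_ies_scan(H1[idx, , drop = FALSE], po[idx], limit)
    r2 <- cpp_ies_scan(H2[idx, , drop = FALSE], po[idx], limit)
    ies1[idx] <- r1$ies; ok1[idx] <- r1$scorable
    ies2[idx] <- r2$ies; ok2[idx] <- r2$scorable
  }
  scorable <- ok1 & ok2 & !is.na(ies1) & !is.na(ies2) &
    ies1 > 0 & ies2 > 0
  raw <- z <- p <- q <- rep(NA_real_, nrow(x))
  raw[scorable] <- log(ies1[scorable] / ies2[scorable])
  mu <- mean(raw[scorable]); sdev <- stats::sd(raw[scorable])
  z[scorable] <- (raw[scorable] - mu) / sdev
  p[scorable] <- 2 * stats::pnorm(-abs(z[scorable]))
  q[scorable] <- stats::p.adjust(p[scorable], method = "BH")
  data.frame(scaffold = sc, pos = po, ies1 = ies1, ies2 = ies2,
             raw = raw, z = z, p = p, q = q,
             outlier = !is.na(q) & q < alpha)
}
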