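## SnpEff-style effect classification against gene models, effect summary
## tables, the candidate-gene filter cascade, and the genotype-phenotype
## association rule.

.EFFECT_CATEGORIES <- c("3'UTR", "5'UTR", "downstream", "intergenic",
                        "intron", "non_synonymous_variant",
                        "synonymous_variant", "upstream", "other")

.inRanges <- function(scaffold, pos, gr) {
  if (length(gr) == 0) return(FALSE)
  any(as.character(GenomicRanges::seqnames(gr)) == scaffold &
        GenomicRanges::start(gr) <= pos & GenomicRanges::end(gr) >= pos)
}

.complementBase <- c(A = "T", C = "G", G = "C", T = "A")

## codon-level call for a SNP inside the CDS of one gene
.codonEffect <- function(scaffold, pos, ref, alt, gene, genome) {
  cds <- gene$cds
  ord <- order(GenomicRanges::start(cds))
  cds <- cds[ord]
  w <- GenomicRanges::width(cds)
  hit <- which(GenomicRanges::start(cds) <= pos &
                 GenomicRanges::end(cds) >= pos)
  off <- sum(w[seq_len(hit - 1)]) + (pos - GenomicRanges::start(cds)[hit] + 1)
  seqs <- vapply(seq_along(cds), function(i) {
    as.character(Biostrings::subseq(genome[[scaffold]],
                                    GenomicRanges::start(cds)[i],
                                    GenomicRanges::end(cds)[i]))
  }, "")
  coding <- paste(seqs, collapse = "")
  total <- nchar(coding)
  if (gene$strand == "-") {
    coding <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(coding)))
    off <- total - off + 1
    refC <- .complementBase[[ref]]; altC <- .complementBase[[alt]]
  } else {
    refC <- ref; altC <- alt
  }
  ci <- ceiling(off / 3)
  wi <- off - 3 * (ci - 1)
  refCodon <- substr(coding, 3 * ci - 2, 3 * ci)
  altCodon <- refCodon
  substr(altCodon, wi, wi) <- altC
  code <- Biostrings::GENETIC_CODE
  aaRef <- unname(code[refCodon]); aaAlt <- unname(code[altCodon])
  cat <- if (is.na(aaRef) || is.na(aaAlt)) "other"
    else if (aaRef == "*" || aaAlt == "*") {
      if (aaRef == aaAlt) "synonymous_variant" else "other"
    } else if (aaRef == aaAlt) "synonymous_variant"
    else "non_synonymous_variant"
  list(category = cat,
       codonChange = paste0(refCodon, ">", altCodon),
       aaChange = paste0(aaRef, ci, aaAlt))
}

#' Annotate SNP effects against gene models
#'
#' One record per (SNP, overlapping gene context) pair: CDS SNPs are
#' translated strand-aware against the reference sequence
#' (synonymous/non-synonymous; stop gain or loss is \code{"other"});
#' intronic SNPs within 2 bp of an intron end are splice-adjacent
#' (\code{"other"}), otherwise \code{"intron"}; exon non-CDS positions
#' are 5'/3' UTR by side and strand; positions within \code{flank} of a
#' gene are upstream/downstream by strand; SNPs with no gene within
#' \code{flank} get a single \code{"intergenic"} record. Genes flagged
#' with a bad CDS yield only non-coding categories (their CDS hits are
#' \code{"other"}).
#'
#' @param sites data.frame (scaffold, pos, ref, alt) of SNPs.
#' @param geneModels List from \code{\link{readGeneModels}}.
#' @param genome Named \code{DNAStringSet} of scaffold sequences.
#' @param flank Upstream/downstream flank in bp (default 5 kb).
#' @return data.frame: scaffold, pos, ref, alt, geneId, category,
#'   codonChange, aaChange.
#' @export
annotateEffects <- function(sites, geneModels, genome, flank = 5000L) {
  rows <- list()
  addRow <- function(i, geneId, category, codonChange = NA_character_,
                     aaChange = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scaffold = sites$scaffold[i], pos = sites$pos[i],
      ref = sites$ref[i], alt = sites$alt[i], geneId = geneId,
      category = category, codonChange = codonChange,
      aaChange = aaChange, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(sites))) {
    sc <- sites$scaffold[i]; pos <- sites$pos[i]
    hitAny <- FALSE
    for (gene in geneModels) {
      if (gene$scaffold != sc) next
      gs <- GenomicRanges::start(gene$span)
      ge <- GenomicRanges::end(gene$span)
      if (pos < gs - flank || pos > ge + flank) next
      hitAny <- TRUE
      if (pos >= gs && pos <= ge) {
        inCds <- .inRanges(sc, pos, gene$cds)
        if (inCds) {
          if (gene$cdsOk) {
            eff <- .codonEffect(sc, pos, sites$ref[i], sites$alt[i],
                                gene, genome)
            addRow(i, gene$geneId, eff$category, eff$codonChange,
                   eff$aaChange)
          } else addRow(i, gene$geneId, "other")
        } else if (.inRanges(sc, pos, gene$utr5)) {
          addRow(i, gene$geneId, "5'UTR")
        } else if (.inRanges(sc, pos, gene$utr3)) {
          addRow(i, gene$geneId, "3'UTR")
        } else if (.inRanges(sc, pos, gene$introns)) {
          nearEnd <- any(abs(pos - GenomicRanges::start(gene$introns)) <= 2 |
                           abs(pos - GenomicRanges::end(gene$introns)) <= 2)
          addRow(i, gene$geneId, if (nearEnd) "other" else "intron")
        } else {
          addRow(i, gene$geneId, "other")
        }
      } else {
        before <- pos < gs
        up <- (gene$strand == "+" && before) ||
          (gene$strand == "-" && !before)
        addRow(i, gene$geneId, if (up) "upstream" else "downstream")
      }
    }
    if (!hitAny) addRow(i, NA_character_, "intergenic")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effect category counts and proportions
#'
#' Counts and percentages (of total effect records) per category, in the
#' fixed category order. Percentages are rounded to 2 decimals.
#'
#' @param records data.frame from \code{\link{annotateEffects}}, or a
#'   named count vector.
#' @return data.frame: category, count, percent.
#' @export
effectSummary <- function(records) {
  counts <- if (is.data.frame(records)) {
    table(factor(records$category, levels = .EFFECT_CATEGORIES))
  } else {
    full <- stats::setNames(rep(0L, length(.EFFECT_CATEGORIES)),
                            .EFFECT_CATEGORIES)
    full[names(records)] <- records
    full
  }
  counts <- as.integer(counts)
  total <- sum(counts)
  pct <- if (total > 0) round(100 * counts / total, 2) else
    rep(0, length(counts))
  data.frame(category = .EFFECT_CATEGORIES, count = counts,
             percent = pct, stringsAsFactors = FALSE)
}

#' Candidate-gene filter cascade
#'
#' Tier 1 (putatively functional): not TE-encoded AND (expressed OR with
#' protein homology). Tier 2: tier 1 genes carrying at least one
#' non-synonymous effect record. Genes missing from the flag table fail
#' and are logged.
#'
#' @param genes Character vector of gene IDs in the candidate regions.
#' @param flags data.frame: geneId, is_te, has_expression, has_homology.
#' @param effects data.frame from \code{\link{annotateEffects}}.
#' @return list: \code{tier1}, \code{tier2} (gene ID vectors) and
#'   \code{table} (per-gene provenance).
#' @export
filterCandidateGenes <- function(genes, flags, effects) {
  idx <- match(genes, flags$geneId)
  if (anyNA(idx)) {
    message("filterCandidateGenes: ", sum(is.na(idx)),
            " gene(s) missing flags (treated as failing)")
  }
  isTe <- ifelse(is.na(idx), TRUE, flags$is_te[idx])
  expr <- ifelse(is.na(idx), FALSE, flags$has_expression[idx])
  hom <- ifelse(is.na(idx), FALSE, flags$has_homology[idx])
  tier1 <- !isTe & (expr | hom)
  nsGenes <- unique(effects$geneId[
    effects$category == "non_synonymous_variant"])
  tier2 <- tier1 & genes %in% nsGenes
  tab <- data.frame(geneId = genes, is_te = isTe, has_expression = expr,
                    has_homology = hom, hasNonSyn = genes %in% nsGenes,
                    tier1 = tier1, tier2 = tier2,
                    stringsAsFactors = FALSE)
  list(tier1 = genes[tier1], tier2 = genes[tier2], table = tab)
}

#' Genotype-phenotype association rule for candidate SNPs
#'
#' A SNP passes iff strictly more than \code{threshold} of the genotyped
#' individuals of population H carry the alternative allele (dosage >= 1)
#' AND strictly more than \code{threshold} of the genotyped individuals
#' of population P carry the reference allele (dosage <= 1). A gene
#' passes iff at least one of its non-synonymous SNPs passes (when
#' \code{effects} is supplied).
#'
#' @param x A \linkS4class{GenotypeMatrix}.
#' @param snps data.frame (scaffold, pos) of SNPs to test.
#' @param popH,popP Population labels (H = alt-carrying, P =
#'   ref-carrying side of the rule).
#' @param threshold Fraction threshold, strict inequality (default 0.9).
#' @param effects Optional effect records for the per-gene verdicts.
#' @return data.frame per SNP: scaffold, pos, fracAltH, fracRefP, pass,
#'   flag; with attribute \code{genePass} (named logical) when
#'   \code{effects} is given.
#' @export
associationRule <- function(x, snps, popH, popP, threshold = 0.9,
                            effects = NULL) {
  ids <- .markerIds(x)
  ii <- match(paste0(snps$scaffold, ":", snps$pos), ids)
  if (anyNA(ii)) stop("SNP(s) absent from the genotype matrix")
  dH <- dosage(x)[ii, .popSamples(x, popH), drop = FALSE]
  dP <- dosage(x)[ii, .popSamples(x, popP), drop = FALSE]
  nH <- rowSums(!is.na(dH)); nP <- rowSums(!is.na(dP))
  fH <- rowSums(dH >= 1L, na.rm = TRUE) / nH
  fP <- rowSums(dP <= 1L, na.rm = TRUE) / nP
  flag <- ifelse(nH == 0 | nP == 0, "no_genotypes", "")
  pass <- nH > 0 & nP > 0 & fH > threshold & fP > threshold
  out <- data.frame(scaffold = snps$scaffold, pos = snps$pos,
                    fracAltH = fH, fracRefP = fP, pass = pass,
                    flag = flag, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(effects)) {
    key <- paste0(out$scaffold, ":", out$pos)
    ns <- effects[effects$category == "non_synonymous_variant", ,
                  drop = FALSE]
    nsKey <- paste0(ns$scaffold, ":", ns$pos)
    genes <- unique(ns$geneId)
    genePass <- vapply(genes, function(g) {
      any(out$pass[key %in% nsKey[ns$geneId == g]])
    }, TRUE)
    attr(out, "genePass") <- genePass
  }
  out
}
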