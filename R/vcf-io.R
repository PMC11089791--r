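#' Read a sample manifest
#'
#' Headered TSV with columns \code{sample_id}, \code{population},
#' \code{role} (queen/male) and optionally \code{excluded} (TRUE/FALSE,
#' relatedness or hybrid exclusions).
#'
#' @param path Path to the TSV file.
#' @return data.frame with one row per sample.
#' @export
readSampleManifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "role")
  if (!all(need %in% colnames(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id in manifest")
  if (any(!nzchar(m$population))) stop("empty population label in manifest")
  if (is.null(m$excluded)) m$excluded <- FALSE
  m$excluded <- as.logical(m$excluded)
  m
}

.gt_first_field <- function(x) sub(":.*$", "", x)

#' Read genotypes from a VCF file
#'
#' Retains biallelic SNP records only (multi-allelic sites and indels are
#' dropped, with a message giving the count). Missing genotypes are kept as
#' \code{NA}. A sample is flagged phased when every non-missing diploid
#' call uses the \code{|} separator. Haploid samples (manifest role
#' \code{male}) must carry single-allele GT calls.
#'
#' @param path VCF file (>= v4.1, GT field present).
#' @param manifest data.frame from \code{\link{readSampleManifest}}. Only
#'   manifest samples are read; a manifest sample absent from the VCF is an
#'   error.
#' @param regionFilter optional \code{GRanges}; only overlapping sites kept.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeVcf <- function(path, manifest, regionFilter = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  fmt <- gt[, "FORMAT"]
  if (!all(grepl("^GT", fmt))) stop("GT must be the first FORMAT field")
  vcfSamples <- colnames(gt)[-1]
  missing <- setdiff(manifest$sample_id, vcfSamples)
  if (length(missing)) {
    stop("manifest sample(s) absent from VCF: ",
         paste(missing, collapse = ", "))
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  nDropped <- sum(!snp)
  if (nDropped > 0) {
    message("readGenotypeVcf: dropped ", nDropped,
            " non-biallelic-SNP record(s)")
  }
  keep <- which(snp)
  scaffold <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  ref <- ref[keep]; alt <- alt[keep]
  gt <- gt[keep, manifest$sample_id, drop = FALSE]
  gt <- apply(gt, 2, .gt_first_field)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(keep))
  nS <- length(keep); nI <- nrow(manifest)
  hapRole <- manifest$role == "male"
  dosageM <- matrix(NA_integer_, nS, nI)
  hap1 <- matrix(NA_integer_, nS, nI)
  hap2 <- matrix(NA_integer_, nS, nI)
  phasedFlag <- logical(nI)
  for (j in seq_len(nI)) {
    g <- gt[, j]
    if (hapRole[j]) {
      if (any(grepl("[/|]", g))) {
        stop("haploid sample ", manifest$sample_id[j],
             " carries diploid GT calls")
      }
      a <- suppressWarnings(as.integer(g))
      if (any(a > 1L, na.rm = TRUE)) {
        stop("non-biallelic allele index in sample ", manifest$sample_id[j])
      }
      dosageM[, j] <- a
      hap1[, j] <- a
      phasedFlag[j] <- TRUE
    } else {
      sep <- ifelse(grepl("\\|", g), "|", ifelse(grepl("/", g), "/", NA))
      parts <- strsplit(g, "[/|]")
      a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
      a2 <- suppressWarnings(as.integer(vapply(parts, function(p)
        if (length(p) >= 2) p[2] else NA_character_, "")))
      ok <- !is.na(a1) & !is.na(a2)
      dosageM[ok, j] <- a1[ok] + a2[ok]
      nonmiss <- which(ok)
      phasedFlag[j] <- length(nonmiss) > 0 && all(sep[nonmiss] == "|")
      if (phasedFlag[j]) {
        hap1[ok, j] <- a1[ok]
        hap2[ok, j] <- a2[ok]
      }
    }
  }
  x <- GenotypeMatrix(dosageM, scaffold, pos, ref, alt,
                      hap1 = hap1, hap2 = hap2,
                      population = manifest$population,
                      role = manifest$role,
                      ploidy = ifelse(hapRole, 1L, 2L),
                      phased = phasedFlag,
                      excluded = manifest$excluded,
                      sampleIds = manifest$sample_id)
  o <- order(scaffolds(x), positions(x))
  x <- x[o, ]
  if (!is.null(regionFilter)) {
    hit <- GenomicRanges::findOverlaps(
      SummarizedExperiment::rowRanges(x), regionFilter)
    x <- x[sort(unique(S4Vectors::queryHits(hit))), ]
  }
  x
}

#' Write a GenotypeMatrix as a GT-only VCF 4.2 file
#'
#' Haploids are written as single-allele GT; phased diploids use
#' \code{|}, unphased \code{/}; missing calls as \code{.} (haploid) or
#' \code{./.}. Record order is scaffold then position (deterministic).
#'
#' @param x A \linkS4class{GenotypeMatrix}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeGenotypeVcf <- function(x, path) {
  cd <- SummarizedExperiment::colData(x)
  o <- order(scaffolds(x), positions(x))
  x <- x[o, ]
  d <- dosage(x); h1 <- SummarizedExperiment::assay(x, "hap1")
  h2 <- SummarizedExperiment::assay(x, "hap2")
  nS <- nrow(x); nI <- ncol(x)
  gtcols <- matrix("", nS, nI)
  for (j in seq_len(nI)) {
    if (cd$ploidy[j] == 1L) {
      g <- as.character(d[, j]); g[is.na(g)] <- "."
    } else if (cd$phased[j]) {
      g <- paste0(h1[, j], "|", h2[, j])
      g[is.na(h1[, j]) | is.na(h2[, j])] <- ".|."
    } else {
      g <- c("0/0", "0/1", "1/1")[d[, j] + 1L]
      g[is.na(d[, j])] <- "./."
    }
    gtcols[, j] <- g
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=supersweep",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleIds(x)), collapse = "\t"))
  if (nS > 0) {
    body <- paste(scaffolds(x), positions(x), ".", refAllele(x),
                  altAllele(x), ".", "PASS", ".", "GT",
                  sep = "\t")
    body <- paste(body, apply(gtcols, 1, paste, collapse = "\t"),
                  sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene models from GFF3 and repeat intervals from BED
#'
#' Expects gene/mRNA/exon/CDS features with \code{Parent} links (one mRNA
#' per gene). UTRs are inferred as exon minus CDS (5' or 3' by strand);
#' introns as gaps between exons. Genes whose total CDS length is not a
#' multiple of 3 are flagged (\code{cdsOk = FALSE}) and are excluded from
#' codon-level effect calls downstream.
#'
#' @param gff3Path GFF3 file of gene models.
#' @return A list of gene records: \code{geneId}, \code{scaffold},
#'   \code{strand}, \code{span}, \code{exons}, \code{cds}, \code{introns},
#'   \code{utr5}, \code{utr3} (GRanges), \code{cdsOk}.
#' @export
readGeneModels <- function(gff3Path) {
  g <- rtracklayer::import(gff3Path, format = "gff3")
  type <- as.character(g$type)
  genes <- g[type == "gene"]
  mrnas <- g[type == "mRNA"]
  exons <- g[type == "exon"]
  cdss <- g[type == "CDS"]
  out <- vector("list", length(genes))
  nBad <- 0L
  for (i in seq_along(genes)) {
    gid <- genes$ID[i]
    mid <- mrnas$ID[vapply(mrnas$Parent, function(p) gid %in% p, TRUE)]
    ex <- exons[vapply(exons$Parent, function(p) any(mid %in% p), TRUE)]
    cd <- cdss[vapply(cdss$Parent, function(p) any(mid %in% p), TRUE)]
    ex <- GenomicRanges::reduce(sort(ex))
    cd <- GenomicRanges::reduce(sort(cd))
    str <- as.character(GenomicRanges::strand(genes)[i])
    introns <- GenomicRanges::setdiff(
      GenomicRanges::GRanges(GenomicRanges::seqnames(genes)[i],
        IRanges::IRanges(min(GenomicRanges::start(ex)),
                         max(GenomicRanges::end(ex)))), ex,
      ignore.strand = TRUE)
    nonCds <- GenomicRanges::setdiff(ex, cd, ignore.strand = TRUE)
    if (length(cd)) {
      cdsStart <- min(GenomicRanges::start(cd))
      cdsEnd <- max(GenomicRanges::end(cd))
      left <- nonCds[GenomicRanges::end(nonCds) < cdsStart]
      right <- nonCds[GenomicRanges::start(nonCds) > cdsEnd]
    } else {
      left <- right <- nonCds[0]
    }
    if (str == "-") { utr5 <- right; utr3 <- left }
    else { utr5 <- left; utr3 <- right }
    cdsOk <- length(cd) > 0 && sum(GenomicRanges::width(cd)) %% 3L == 0L
    if (!cdsOk) nBad <- nBad + 1L
    out[[i]] <- list(geneId = gid,
                     scaffold = as.character(
                       GenomicRanges::seqnames(genes)[i]),
                     strand = str,
                     span = genes[i],
                     exons = ex, cds = cd, introns = introns,
                     utr5 = utr5, utr3 = utr3, cdsOk = cdsOk)
  }
  if (nBad > 0) message("readGeneModels: ", nBad,
                        " gene(s) flagged with CDS length not divisible by 3")
  names(out) <- vapply(out, `[[`, "", "geneId")
  out
}

#' @describeIn readGeneModels Read repeat (TE) intervals from a BED file
#'   into a 1-based GRanges.
#' @param bedPath BED3+ file of repeat intervals.
#' @export
readRepeatBed <- function(bedPath) {
  rtracklayer::import(bedPath, format = "BED")
}
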