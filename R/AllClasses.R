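#' GenotypeMatrix: sites-by-samples allele-dosage calls
#'
#' The central genotype container: a \linkS4class{RangedSummarizedExperiment}
#' whose rows are biallelic SNP sites (a \code{GRanges} with \code{ref} and
#' \code{alt} single-character alleles in its metadata columns) and whose
#' columns are samples. Assays:
#' \describe{
#'   \item{\code{dosage}}{integer alt-allele dosage. Diploids: 0, 1, 2;
#'     haploids: 0, 1. \code{NA} is the missing-genotype sentinel and is
#'     propagated, never imputed.}
#'   \item{\code{hap1}, \code{hap2}}{per-chromosome alleles (0/1) for
#'     phased samples; \code{hap2} is \code{NA} throughout for haploids and
#'     both are \code{NA} for unphased samples.}
#' }
#' Column data carries \code{population}, \code{role} (queen/male),
#' \code{ploidy} (1 or 2), \code{phased}, and \code{excluded} flags.
#'
#' @name GenotypeMatrix-class
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  contains = "RangedSummarizedExperiment"
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  an <- names(SummarizedExperiment::assays(object))
  if (!all(c("dosage", "hap1", "hap2") %in% an)) {
    msg <- c(msg, "assays must include 'dosage', 'hap1', 'hap2'")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  mc <- S4Vectors::mcols(rr)
  if (!all(c("ref", "alt") %in% colnames(mc))) {
    msg <- c(msg, "rowRanges must carry 'ref' and 'alt' metadata columns")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("population", "role", "ploidy", "phased")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, paste0("colData must carry: ",
                         paste(need, collapse = ", ")))
  } else {
    if (!all(cd$ploidy %in% c(1L, 2L))) {
      msg <- c(msg, "ploidy must be 1 or 2")
    }
    d <- SummarizedExperiment::assay(object, "dosage")
    if (ncol(d) > 0 && nrow(d) > 0) {
      hap <- which(cd$ploidy == 1L)
      if (length(hap)) {
        bad <- d[, hap, drop = FALSE]
        if (any(bad > 1L, na.rm = TRUE)) {
          msg <- c(msg, "haploid samples carry dosage > 1")
        }
      }
      dip <- which(cd$ploidy == 2L)
      if (length(dip) &&
          any(d[, dip, drop = FALSE] > 2L, na.rm = TRUE)) {
        msg <- c(msg, "diploid dosage > 2")
      }
    }
    # positions strictly increasing within a scaffold
    sc <- as.character(GenomicRanges::seqnames(rr))
    po <- GenomicRanges::start(rr)
    if (length(po) > 1) {
      same <- sc[-1] == sc[-length(sc)]
      if (any(same & diff(po) <= 0)) {
        msg <- c(msg, "positions must be strictly increasing within a scaffold")
      }
    }
  }
  if (length(msg)) msg else TRUE
})
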