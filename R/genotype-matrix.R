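#' Construct a GenotypeMatrix
#'
#' @param dosage integer matrix, sites x samples; NA = missing.
#' @param scaffold character vector of scaffold IDs per site.
#' @param pos integer 1-based positions per site.
#' @param ref,alt single-character reference/alternate alleles per site.
#' @param hap1,hap2 optional 0/1 matrices (sites x samples) with the two
#'   phased chromosomes; \code{hap2} all-NA columns for haploids.
#' @param population character per-sample population label.
#' @param role per-sample role, \code{"queen"} or \code{"male"}.
#' @param ploidy integer per-sample ploidy (1 or 2).
#' @param phased logical per-sample phase flag.
#' @param excluded logical per-sample exclusion flag (relatedness/hybrid).
#' @param sampleIds sample identifiers (column names).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosage, scaffold, pos, ref, alt,
                           hap1 = NULL, hap2 = NULL,
                           population, role = rep("queen", ncol(dosage)),
                           ploidy = rep(2L, ncol(dosage)),
                           phased = !is.null(hap1),
                           excluded = rep(FALSE, ncol(dosage)),
                           sampleIds = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n <- ncol(dosage)
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(n))
  if (length(phased) == 1) phased <- rep(phased, n)
  if (is.null(hap1)) hap1 <- matrix(NA_integer_, nrow(dosage), n)
  if (is.null(hap2)) hap2 <- matrix(NA_integer_, nrow(dosage), n)
  storage.mode(hap1) <- "integer"
  storage.mode(hap2) <- "integer"
  rr <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(pos, width = 1L),
                               ref = as.character(ref),
                               alt = as.character(alt))
  cd <- S4Vectors::DataFrame(population = as.character(population),
                             role = as.character(role),
                             ploidy = as.integer(ploidy),
                             phased = as.logical(phased),
                             excluded = as.logical(excluded),
                             row.names = sampleIds)
  dimnames(dosage) <- list(NULL, sampleIds)
  dimnames(hap1) <- list(NULL, sampleIds)
  dimnames(hap2) <- list(NULL, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage, hap1 = hap1, hap2 = hap2),
    rowRanges = rr, colData = cd)
  new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix Alt-allele dosage matrix (sites x samples).
#' @param x A GenotypeMatrix.
#' @export
dosage <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeMatrix Scaffold ID per site.
#' @export
scaffolds <- function(x) {
  as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(x)))
}

#' @describeIn GenotypeMatrix 1-based position per site.
#' @export
positions <- function(x) GenomicRanges::start(SummarizedExperiment::rowRanges(x))

#' @describeIn GenotypeMatrix Reference alleles per site.
#' @export
refAllele <- function(x) S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$ref

#' @describeIn GenotypeMatrix Alternate alleles per site.
#' @export
altAllele <- function(x) S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$alt

#' @describeIn GenotypeMatrix Sample identifiers.
#' @export
sampleIds <- function(x) rownames(SummarizedExperiment::colData(x))

#' @describeIn GenotypeMatrix Per-sample population labels.
#' @export
populations <- function(x) SummarizedExperiment::colData(x)$population

#' @describeIn GenotypeMatrix Per-sample ploidy (1 or 2).
#' @export
ploidy <- function(x) SummarizedExperiment::colData(x)$ploidy

#' Phased haplotypes for a set of samples
#'
#' Returns the chromosome-level 0/1 allele matrix (sites x chromosomes) for
#' the requested samples. Diploid phased samples contribute two columns
#' (\code{<id>_1}, \code{<id>_2}); haploids one. Unphased samples are an
#' error.
#'
#' @param x A GenotypeMatrix.
#' @param samples Sample IDs (default: all phased, non-excluded samples).
#' @return Integer matrix, sites x chromosomes.
#' @export
haplotypes <- function(x, samples = NULL) {
  cd <- SummarizedExperiment::colData(x)
  if (is.null(samples)) {
    samples <- rownames(cd)[cd$phased & !cd$excluded]
  }
  idx <- match(samples, rownames(cd))
  if (anyNA(idx)) stop("unknown sample(s): ",
                       paste(samples[is.na(idx)], collapse = ", "))
  if (!all(cd$phased[idx])) {
    stop("unphased sample(s): ",
         paste(samples[!cd$phased[idx]], collapse = ", "))
  }
  h1 <- SummarizedExperiment::assay(x, "hap1")[, idx, drop = FALSE]
  h2 <- SummarizedExperiment::assay(x, "hap2")[, idx, drop = FALSE]
  out <- vector("list", length(idx))
  nm <- character(0)
  cols <- list()
  for (i in seq_along(idx)) {
    cols[[length(cols) + 1L]] <- h1[, i]
    if (cd$ploidy[idx[i]] == 2L) {
      nm <- c(nm, paste0(samples[i], "_1"))
      cols[[length(cols) + 1L]] <- h2[, i]
      nm <- c(nm, paste0(samples[i], "_2"))
    } else {
      nm <- c(nm, samples[i])
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

#' Subset sites/samples of a GenotypeMatrix by population
#'
#' @param x A GenotypeMatrix.
#' @param population Population label(s) to keep.
#' @param dropExcluded Drop samples flagged excluded (default TRUE).
#' @return A GenotypeMatrix with the selected samples.
#' @export
subsetPopulation <- function(x, population, dropExcluded = TRUE) {
  cd <- SummarizedExperiment::colData(x)
  keep <- cd$population %in% population
  if (dropExcluded) keep <- keep & !cd$excluded
  x[, keep]
}

setMethod("show", "GenotypeMatrix", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("GenotypeMatrix:", nrow(object), "sites x", ncol(object), "samples\n")
  cat("  scaffolds:", length(unique(scaffolds(object))), "\n")
  tab <- table(cd$population)
  cat("  populations:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat("  ploidy 1/2:", sum(cd$ploidy == 1L), "/", sum(cd$ploidy == 2L),
      "; phased:", sum(cd$phased), "\n")
  miss <- mean(is.na(dosage(object)))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(NULL)
})
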