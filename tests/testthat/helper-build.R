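# build a phased diploid GenotypeMatrix from a haplotype matrix
# (sites x chromosomes, chromosomes paired consecutively)
gmFromHaps <- function(hap, population, scaffold = "s1",
                       pos = seq_len(nrow(hap)) * 10L) {
  stopifnot(ncol(hap) %% 2 == 0)
  n <- ncol(hap) / 2
  h1 <- hap[, 2 * seq_len(n) - 1, drop = FALSE]
  h2 <- hap[, 2 * seq_len(n), drop = FALSE]
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  GenotypeMatrix(h1 + h2, scaffold = rep(scaffold, nrow(hap)), pos = pos,
                 ref = rep("A", nrow(hap)), alt = rep("T", nrow(hap)),
                 hap1 = h1, hap2 = h2, population = population,
                 ploidy = rep(2L, n), phased = TRUE)
}
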