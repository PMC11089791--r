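---
title: "supersweep: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{supersweep: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`supersweep` implements a two-population genome-scan and
supergene-characterization workflow for a social-polymorphism study
design: diploid queens from a haplometrotic ("H") and a pleometrotic
("P") population, plus a haploid male brood from a single queen
heterozygous for the two supergene haplotype groups (Sh and Sp, where
Sp matches the reference assembly). This vignette records the
statistical definitions the package uses, the choices made where
several defensible options existed, what the bundled synthetic-data
generator does and does not emulate, and the package's known
limitations. The package is used from R: the exported stage functions
plus `runPipeline()` are the interface, and `scripts/acceptance.R` is a
thin command-line wrapper over them.

## Windowed statistics

All windowed statistics share one grid: non-overlapping windows
(default 100 kb) anchored at position 1 of each scaffold, with the
final partial window retained at its true bp length. A window QC flag
requires a minimum SNP count (default 10) before outlier analysis;
flagged windows are kept in the table, not deleted.

**Nucleotide diversity.** Per site, π is the probability that two
distinct chromosomes differ, computed from the non-missing allele
counts: `cRef*cAlt / choose(n, 2)`. The window value divides the sum
over sites by the *full window length*, so monomorphic and missing
sites contribute zero — the convention of the common VCF windowed-π
tools, which makes values comparable across windows with different SNP
density.

**Tajima's D.** The 1989 normalization requires a single chromosome
count *n*, so only sites fully genotyped within the population are
used, with *n* = 2 × (number of diploids). Windows with no segregating
site yield `NA` (the statistic is undefined there), never 0.

**Weir–Cockerham F~ST~.** Per-site variance components *a* (among
populations), *b* (among individuals), *c* (within individuals) from
diploid genotype counts; the window estimate is the ratio of sums
Σa/Σ(a+b+c). Negative estimates are reported, not clamped: clamping
would bias the empirical outlier quantile. Note the estimator's
small-sample behaviour: for two literally identical samples of *n*
individuals each it converges to roughly −1/(2(n−1)), not exactly 0.

**Heterozygosity/inbreeding.** Per sample, over sites genotyped in the
sample and polymorphic in its population: *F* = (O−E)/(L−E) with the
small-sample HWE expectation `1 − 2pq·n/(n−1)` per site, and
heterozygosity 1 − O/L.

**LD decay.** Haplotype r² for all intra-scaffold pairs within 200 kb
after a MAF ≥ 0.2 filter, averaged in 100-bp distance bins. The MAF
filter suppresses rare-variant noise; the bin width only affects
presentation.

**HWE.** Plain χ² against p², 2pq, q² with df = 1 and no continuity
correction; a cell with expected 0 and observed 0 contributes 0. The
plain (uncorrected) statistic is used throughout; the reported
*p*-value is the exact χ²₁ upper tail.

**Relatedness.** The unadjusted Yang et al. (2010) A~jk~ estimator
from dosages and population allele frequencies. Its known small-panel
biases (duplicate pairs shrink below 1; unrelated pairs centre at
−1/(N−1)) are properties of the estimator, not corrected here; the
intended use is flagging pairs above a relatedness threshold (0.4) in
a cohort of tens of samples.

## Haplotype-homozygosity scan

EHH at marker *x* for the carriers of a core allele is the probability
that two random carriers are identical at every marker from the core
to *x*; EHHS pools all chromosomes and normalizes by the core-site
allele-class homozygosity, so EHHS(core) = 1. Both are non-increasing
away from the core. A chromosome with a missing call is removed from
the extension at that marker (its pairs count as broken), which
preserves monotonicity and avoids imputation.

iES is the trapezoidal integral of EHHS over physical distance,
truncated at the first marker where EHHS < 0.05 (that marker included
as boundary; the 0.05 limit is the standard default of the scan tools
in this area and is configurable). Two classes of sites are unscorable
and excluded before any standardization: cores monomorphic in a
population, and sites whose EHHS is still above the limit when a
scaffold border is reached (the border would truncate the integral
arbitrarily).

xpEHH is ln(iES₁/iES₂), standardized globally (all scaffolds pooled)
to z-scores; *p* = 2(1−Φ(|z|)); outliers at Benjamini–Hochberg
q < 0.05. Positive values indicate a sweep in population 1 (the
pleometrotic population, in the pipeline's orientation). Global rather
than frequency-binned standardization follows the R scan package this
design emulates. A caveat worth recording: the null distribution of
ln(iES₁/iES₂) from ~30–40 chromosomes has slightly heavier-than-normal
tails (kurtosis ≈ 3.3–3.5 in our neutral simulations), so isolated
single-site BH rejections at |z| ≈ 4.5 occur at a low rate (of order
one per few neutral genomes of 20,000 SNPs) even without selection.
Frequency-binned standardization and MAF filtering reduce but do not
eliminate this. Downstream candidate calling is robust to it because
candidates additionally require an overlapping, direction-concordant
F~ST~ outlier cluster; in neutral simulations the final candidate count
is zero.

## Outlier intersection

F~ST~ outliers are windows strictly above the empirical 95th percentile
(type-7 linear-interpolation quantile) among QC-passing windows; the
realized threshold is reported. Strictly consecutive outlier windows
merge into clusters ("adjacent" read literally: a one-window gap breaks
a cluster; configurable). A cluster is classified as swept in
population X iff its mean Tajima's *D* in X is negative *and* its mean
π in X is below the other population's — no magnitude threshold, since
none is defensible a priori. xpEHH outlier SNPs are single-linkage
grouped within 100 kb; each cluster's candidate interval is its most
significant SNP (largest |z|, ties to the smaller coordinate) ±100 kb,
clipped to the scaffold. Final candidates are union intervals of
overlapping, same-direction F~ST~/xpEHH cluster pairs; requiring
directional concordance is a deliberate choice (configurable off) —
it costs nothing in the planted-truth simulations and removes
opposite-sign coincidences. Candidates on scaffolds assigned to the
supergene's linkage group, or overlapping the detected non-recombining
block, are reported separately rather than silently dropped; candidates
on unplaced scaffolds are retained with an `unplaced` flag.

## Linkage map and supergene

Recombination fractions from the haploid brood treat a marker and its
complement as the same signal (maternal phase polarity is unknown):
rf = min(d, 1−d) over shared genotyped sons, `NA` below 20 shared
sons. Groups are single-linkage components at rf ≤ 0.25. Ordering
within a group is a greedy chain: the two members of the largest-rf
pair are taken as termini, the chain starts at one of them, and the
unplaced marker with the smallest rf to either endpoint is appended
there; cumulative cM uses the Kosambi function on adjacent pairs
(rf ≥ 0.5 capped at 0.49 with a warning). This replaces a commercial
multipoint mapper: exact ordering inside dense clusters is not a goal
of the package — grouping and the zero-rf block are what the
downstream inferences use.

The non-recombining block is the set of markers in *complete* linkage:
zero recombinants for every pair after polarity alignment. Zero-rf
connected components are refined to cliques by iteratively peeling the
member with the most non-zero pairs, because with ~100 meioses a chain
of pairwise-zero estimates can leak past a boundary that the pairwise
criterion rejects. Markers missing in >10% of sons are excluded first.
The boundary resolution of this design is set by the meiosis count:
with 108 sons the nearest crossover to the block edge is ~1/(108·r) bp
away, so a single flanking marker occasionally co-segregates perfectly
and joins the block; two almost never do at the default marker spacing.

Marker PCA is fitted on mean-centered male dosages (haploid dosage
doubled onto the diploid scale; missing values mean-imputed for the fit
only), queens are projected onto the male axes, males split by the sign
of PC1, and queens take the nearest of the two male centroids or their
midpoint (hom/het/hom). The PC1 sign is canonicalized so the
reference-rich (Sp-like) class scores positive — eigenvector sign is
arbitrary. Region genotypes per queen use the diagnostic sites (fixed
differences between the two male classes): a call requires ≥10
genotyped diagnostic sites and a 0.8 majority of hom-Sp, het, or
hom-Sh genotypes, else `ambiguous`. The 0.8 threshold replaces manual
visual inspection with a reproducible rule; at the default diagnostic
density (~30 sites) it tolerates both missingness and the rare private
mutations the generator plants.

Dating scales a fossil-calibrated age by the ratio of node heights on a
phylogram: height = mean root-to-tip path below the node (tolerating
non-ultrametric trees), ρ = height(supergene split)/height(speciation
node), age = calibration × ρ, HPD half-width scaled likewise. Values
are rounded to 2 decimals, half away from zero, consistently for the
point estimate and both HPD endpoints. The bundled
`supergene_tree_synthetic.nwk` is a synthetic example tree constructed
with a 1:39 height ratio.

## Variant effects and candidate genes

Effects are one record per (SNP, overlapping gene context) — not
"most severe only" — so a SNP near two genes counts twice, as effect
summary tables in this literature do. CDS SNPs are translated
strand-aware against the reference sequence one SNP at a time (no
haplotype-aware codon reconstruction); stop gain/loss and
splice-adjacent positions (≤2 bp from an intron end) fall in `other`.
Exonic non-CDS positions are 5′/3′ UTR by side and strand; positions
within 5 kb of a gene (the common annotator default; configurable) are
upstream/downstream by strand; a SNP near no gene yields exactly one
`intergenic` record. Genes whose total CDS length is not a multiple of
3 are excluded from codon-level calls and their CDS hits are `other`.

The candidate-gene cascade keeps genes that are not TE-encoded and have
expression or homology support (tier 1), then those with ≥1
non-synonymous variant (tier 2). The association rule is evaluated over
genotyped individuals only, with strict inequalities: a SNP passes iff
>90% of H individuals carry the alternative allele (dosage ≥ 1) and
>90% of P individuals carry the reference allele (dosage ≤ 1); a gene
passes iff ≥1 of its non-synonymous SNPs passes.

## The synthetic-data generator

`simConfig()`/`simulateCohort()`/`simulateBrood()` generate a cohort
with the structure the analysis assumes, at desk scale: 10 scaffolds ×
1 Mb with ~1 SNP/500 bp — a 1/10-size genome preserving the ~8 Mb/252 Mb
supergene aspect ratio (0.8 Mb on one scaffold). Design choices, each
made once:

- **Founder mosaics, not a coalescent.** Each population has a pool of
  founder haplotypes (default 16) drawn from site-wise frequencies;
  every chromosome is a mosaic of founders with Poisson breakpoints
  (default 2×10⁻⁵/bp, i.e. ~50-kb segments), giving distance-decaying
  LD and direct control over the planted structures the tests assert.
  A coalescent simulator would be more realistic but would not let the
  generator plant exact genotype tables and block boundaries.
- **Divergence.** A small fraction of sites (0.005) is pool-divergent
  (frequencies 0.9 vs 0.1); the rest share a Beta(0.5, 2) frequency.
  Together with founder-pool drift this yields a genome-wide median
  windowed F~ST~ near 0.07–0.14 — two recently separated populations.
- **Supergene.** Inside the interval every chromosome copies its
  assigned archetype (Sp = reference-like, Sh differing at ~20% of
  sites) plus rare private mutations (0.002/site/chromosome), with no
  mosaic breakpoints: complete recombination suppression. Queen
  genotypes follow the configured tables exactly (H: 6 Sh/Sh, 8 Sh/Sp,
  2 Sp/Sp; P: 16 Sp/Sp, 3 Sh/Sp, 0 Sh/Sh; the one admixed P queen is
  Sh/Sp with one H-derived genome).
- **Sweeps.** Inside each sweep interval (three 100-kb intervals on
  non-supergene scaffolds), P chromosomes copy one designated founder
  haplotype with probability 0.9 and then mutate at 0.002/site. The
  0.9 carrier fraction models a *nearly* complete hard sweep: empirical
  sweeps retain minor variation, and a fully fixed region would be
  invisible to cross-population haplotype statistics, which need the
  core site polymorphic in both populations. Each sweep also carries
  ~30 planted association sites (H pool fixed alternative, reference in
  P), the signal the >90/>90 rule detects.
- **Brood.** Sons are recombinant maternal gametes with a per-meiosis
  crossover rate of 2.5×10⁻⁶/bp. Because each 1-Mb desk-scale scaffold
  stands for a whole chromosome, the rate is chosen to preserve the
  per-chromosome *map* length (~250 cM) rather than the per-bp rate;
  crossovers never fall inside the supergene. ddRAD marker sparsity is
  emulated by keeping one maternal-heterozygous site per 25-kb bin
  (~400 markers genome-wide), and the mother is drawn outbred (her two
  haplotypes use disjoint founder subsets) so informative markers exist
  genome-wide. The pipeline builds its map at a 0.7 call-rate filter
  (the relaxed-map setting appropriate for assigning scaffolds to
  linkage groups); `buildLinkageMap()`'s own default is strict (1.0).
- **Missingness** is 2% per call, masked jointly from dosage and phase;
  it is propagated, never imputed.

What the generator does **not** emulate: mutation-rate and
recombination-rate heterogeneity, genotyping error (brood markers are
error-free, so zero-recombinant detection is exact), background
selection, demographic history (bottlenecks, secondary contact), gene
conversion inside the supergene, and sequencing/phasing error (phase is
known by construction). Passing recovery tests on this generator
therefore demonstrates the pipeline's correctness on data with the
assumed structure, not robustness to every artefact of real
resequencing data.

## Numerical conventions and degenerate inputs

- Intervals are 1-based inclusive in all inputs, outputs and internal
  GRanges; BED input is converted on import.
- Quantiles are type-7 (linear interpolation); outlier calls use strict
  inequalities, so an all-tied distribution yields no outliers.
- Ties for the top SNP of an xpEHH cluster break to the smaller
  coordinate; eigenvector signs are canonicalized as described.
- Division-by-zero cases return `NA` plus a flag rather than 0:
  F~ST~ windows with zero denominator, Tajima's *D* with S = 0, F with
  L = E, invariant sites in LD matrices, unscorable xpEHH sites.
- Multi-allelic and indel VCF records are dropped (not split) with a
  logged count; splitting would change allele frequencies under the
  biallelic statistics above.
- All simulation randomness flows from the single `seed`; brood,
  genome and repeat-track generation use fixed offsets of it, so every
  artefact is reproducible from one integer.

## Problem sizes

The default generator scale (10 × 1 Mb, 20,000 SNPs, 35 queens + 108
sons, ~400 brood markers) was chosen so that a complete pipeline run
takes tens of seconds on one core while every recovery property
(block boundaries, genotype tables, sweep candidates, linkage-group
count) remains sharply testable across seeds. The test suite runs the
full pipeline across ten seeds plus ten neutral genomes at this scale.
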