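---
title: "Methods: ROH, genetic load, and historic N_E in ursaroh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH, genetic load, and historic N_E in ursaroh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ursaroh)
```

# Scope and model

ursaroh implements a per-individual diagnosis of inbreeding and genetic
load for diploid genomes, of the kind used to compare bear species and
populations: runs of homozygosity (ROH) and the genomic inbreeding
coefficient F_ROH, two observed-heterozygosity estimators, outgroup-based
partitioning of deleterious variation into potential, realized, and fixed
load, the intersection of deleterious variants with ROH tracts, and a
single-number summary of coalescence-rate trajectories as historic
effective population size (N_E). Because the real analyses of this kind
rest on tens of whole-genome sequencing runs that cannot be reproduced at
desk scale, the package also contains a pedigree genome simulator with
exact autozygosity truth; every stage is validated against that truth or
against brute-force oracles.

# Genotype filtering

Calls are kept when `GQ > 20` and `4 < DP < 300`, both bounds strict;
failing calls become missing rather than dropping the site, because the
ROH window logic has an explicit missing-call allowance and must see them.
Indels and multiallelic records are then removed entirely. Scaffold
retention supports both selection styles met in practice: an explicit
scaffold list (assemblies with a clean autosome demarcation) or a minimum
length, with 1.05 Mb as the default threshold. The summed retained length
is the denominator for F_ROH and genome-wide heterozygosity. Filters are
applied per call after merging; whether the original pipelines filtered
per-sample files before or after merging is not observable from the data,
and the per-call formulation is idempotent, which the tests assert.

# ROH detection

The detector reproduces PLINK `--homozyg` window semantics. Parameters
(defaults in parentheses, all exposed in `roh_params()`): window size in
SNPs (the L value), maximum heterozygous (5) and missing (5) calls per hit
window, window-hit proportion threshold per SNP (0.05), minimum final
segment SNPs (L) and length (100 kb), maximum density (50 kb/SNP), maximum
inter-SNP gap (500 kb), and maximum heterozygotes per final segment (1).
SNPs near scaffold ends are covered by fewer than L windows; the hit
proportion uses the number of windows actually overlapping each SNP.

The L value is calibrated so the expected number of chance ROH across the
dataset is bounded:
`L = ceil(ln(alpha/(n_snps * n_individuals)) / ln(1 - mean_het))`, with
alpha defaulting to 0.05, the convention of the sources that proposed the
calibration. L is rounded up (conservative: fewer false tracts) and used
for both the scanning window and the final-segment minimum, since the two
are set jointly wherever this calibration is used.

One step deserves explanation because the naive reading fails. With a
window threshold as lenient as 0.05, SNPs up to roughly L positions beyond
a genuine autozygous tract still have enough hit windows to "pass", so
every candidate run absorbs heterozygote-rich flanks. If the run were then
*discarded* whenever it contains more than one heterozygote, essentially
no segment would survive on realistic data — we verified that a genome
with 8% true autozygosity yields zero segments under that reading. PLINK
instead bounds heterozygotes per *final* segment: ursaroh therefore splits
candidate runs greedily from the left whenever the running heterozygote
count would exceed the allowance, and trims both ends of each piece to the
outermost homozygous non-missing call, before applying the SNP-count,
length, and density thresholds. A literal loop-based implementation of
this documented algorithm serves as the test oracle; the production
detector (vectorized with cumulative sums) must match it exactly on
hundreds of randomized instances.

Tract length classes are short [100, 400) kb, medium [400, 800) kb, and
long [800 kb, ∞). The upper-boundary assignment (400 and 800 going to the
larger class) is a package choice; "100–400 / 400–800 / >800" leaves it
ambiguous. Segments below 100 kb can only arise when `min_kb` is set below
its default and are left unclassified.

# Heterozygosity

SNP heterozygosity is the heterozygous fraction of the *cohort's variable
sites* — sites polymorphic across all samples after filtering — with each
sample's missing calls removed from its own denominator. Genome-wide
heterozygosity divides the heterozygous call count by a mapped-length
denominator. "Sites mapped in the genome" admits several readings
(assembly length, retained-scaffold length, per-sample callable sites);
ursaroh defaults to the retained-scaffold total and accepts an explicit
override, which keeps the estimator reproducible from the inputs the
package actually sees.

# Load partitioning

Polarization assigns the ancestral state from an outgroup individual
assumed to carry it: when the outgroup allele matches ref or alt, the
other allele is derived; outgroup-missing and third-allele sites are
excluded and counted. The reference allele being derived is fully
supported, which motivates dosage-based accounting: a sample's per-site
derived dosage (0/1/2) maps to absent / potential (masked heterozygous) /
realized (expressed homozygous) load. This is provably identical to the
allele-frequency filtering formulation used with per-individual VCFs
(frequency ≥ 0.05 selects carriers, ≥ 0.55 selects homozygotes: a het's
0.5 passes only the first), and the tests check the equivalence over the
exhaustive genotype-by-polarity space. Deleterious means impact LOW,
MODERATE, or HIGH (loss of function); unannotated/modifier sites are
excluded, and HIGH-only splits are available. Missing genotypes classify
as absent and are logged. Fixed load counts derived variants whose
frequency over *non-missing* called alleles exceeds 0.95, strictly; the
non-missing denominator is a package choice where the source procedure is
silent about missingness.

# ROH context

Variant-in-ROH flags use inclusive 1-based endpoints and a sorted sweep
(`findInterval`), tested against an O(n·m) oracle; BED exports convert to
0-based half-open coordinates with round-trip tests. A variant need not be
homozygous to be *located* in an ROH — zygosity stratification is a
separate axis, mirroring pipelines that intersect coordinate BED files.
The per-tract burden statistic is carried deleterious variants inside ROH
divided by the number of tracts (0 when no tracts exist).

# Demography

MSMC2 final-output files (header plus `time_index, left_time_boundary,
right_time_boundary, lambda`) are parsed and distilled to
`N_E = (1/geomean(lambda)) / (2 mu)`, mu defaulting to 1e-8. Under the
default time-segment pattern `1*2+25*1+1*2+1*3`, the exclusion of "the
first two and last three atomic segments" corresponds to dropping exactly
the first and the last *output* interval (each is one merged entry); the
drop counts are configurable to expose the alternative reading, and the
penultimate `1*2` group is retained since the exclusion rule does not name
it. The geometric mean is unweighted by interval duration — no weighting
is specified anywhere, and an unweighted mean keeps the statistic
permutation-invariant over kept entries (asserted in tests). log10(N_E) is
computed only for reporting.

# The simulator: what it emulates and what it does not

`simulate_pedigree_genomes()` draws founder haplotypes i.i.d. per site
with derived-allele frequency p solving `2p(1-p) = founder_het` (p ≤ 0.5,
ancestral = reference), then transmits them through an arbitrary pedigree
with Poisson crossover counts (rate per bp per meiosis, default 1e-8 =
1 cM/Mb), uniform breakpoints, and no interference — the standard
first-order meiosis model. Truth tracts are the maximal regions where a
focal sample's two haplotypes descend from the same founder haplotype;
abutting tracts from *different* founder haplotypes stay distinct. All
randomness flows from one seed, making outputs byte-identical across
reruns.

Defaults describe the study conditions the package is validated under:
1 SNP per 1.5 kb (chosen to make calibrated L values land in the realistic
range — published per-scaffold SNP densities are not available), founder
heterozygosity 0.3 at variable sites, impact fractions
HIGH 0.002 / MODERATE 0.01 / LOW 0.02 / NONE 0.968 (deleterious classes a
few percent of segregating sites, HIGH rarest, as in typical SnpEff
annotation tallies), GQ ~ Normal(60, 10) and DP ~ Poisson(30) per call
(depths matching ~30x cohorts), and error/missing rates 0 unless set.

The simulator deliberately omits: selection against deleterious alleles
(load classes are labels, not fitness), new mutation during transmission,
crossover interference, linkage disequilibrium among founder alleles
(sites are independent given the pedigree), sex chromosomes, and any
coalescent process deeper than the pedigree founders. Consequently,
passing tests demonstrate correctness of the *measurement machinery* —
detection, counting, conservation, calibration — under known truth; they
do not demonstrate that real genomes meet the model's assumptions, and
quantities that depend on deep LD structure (e.g., background ROH in
outbred individuals) are intentionally absent from the synthetic cohorts.

# Numerical and design choices

- Coordinates are 1-based inclusive internally (VCF convention); every BED
  export is 0-based half-open.
- A first-cousin pedigree builder is provided because its expectation
  (F = 1/16) anchors the parameter-recovery tests; the gene-dropping
  Monte-Carlo oracle in the test suite reproduces the same value
  independently of the segment machinery.
- Pedigree truth is chunky at genome scale: with 1 cM/Mb and ~100 Mb
  scaffolds a single replicate's autozygous fraction has a standard
  deviation of about 0.03 around 0.0625, so recovery is asserted on the
  mean of 50 replicates and on the truth-vs-detected correlation (≥ 0.9).
  Fixture seeds for small property tests are chosen so the instances are
  informative (a 4 × 20 Mb first-cousin genome has no autozygous tract at
  all in roughly half of replicates).
- Problem sizes in the test suite and acceptance script (50 replicates of
  20 × 100 Mb for recovery; 200 randomized oracle instances up to 5,000
  SNPs; 10 × 100 Mb cohorts for the L-robustness check) were chosen to
  keep the full validation run in the minutes range on a single core
  while leaving Monte-Carlo error well inside the asserted tolerances.
- `l_parameter` errors at mean_het of exactly 0 or 1 (log divergence);
  `classify_length` errors below the 100 kb floor; `geometric_mean_ne`
  errors when every entry is dropped; empty ROH sets yield F_ROH 0 and a
  0 per-tract rate rather than NaN.

# Known limitations

The published L values for the three bear datasets (63, 41, 61) cannot be
reproduced exactly because the mean heterozygosities entering the formula
were not printed; the package instead demonstrates, as the original
analysis did, that individual F_ROH moves by less than one percentage
point across L ∈ {41, 61, 63}. The fixed-load accounting covers the
frequency filter and per-impact tallies, not the cross-assembly remapping
used to discover reference-fixed sites. ROH-based dating of inbreeding
events is intentionally out of scope.
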