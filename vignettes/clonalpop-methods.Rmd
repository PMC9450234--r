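---
title: "Methods: population-genomic scans for clonal crop collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic scans for clonal crop collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalpop)
```

`clonalpop` analyses diploid genotype, deleterious-score, expression and
trait data for a clonally propagated crop collection structured into an
origin group (OG) and two independently domesticated cultivated groups
(CG1, CG2). This vignette records the models, the parameters that matter,
the numerical choices, and what the simulator does and does not emulate.

## The simulation model

### Genotypes

`simulate_genotypes()` uses the Balding–Nichols model: each site draws an
ancestral frequency $p_0$ from a Beta distribution truncated to
$(0.05, 0.95)$ (so every simulated site is genuinely polymorphic in the
ancestral pool), each population $i$ draws a drifted frequency
$p_i \sim \mathrm{Beta}\!\left(p_0\tfrac{1-F_i}{F_i},\,
(1-p_0)\tfrac{1-F_i}{F_i}\right)$, and diploid genotypes are binomial
draws from $p_i$. Under this model the expected pairwise Hudson
$F_{ST}$ between populations $i$ and $j$ is $(F_i+F_j)/2$, so the
per-population $F_i$ are solved directly from the requested pairwise
target matrix — exactly for three populations, by least squares
otherwise. This gives direct divergence control without a coalescent
machinery; the cost is that sites are exchangeable and unlinked (no
linkage disequilibrium, no recombination maps, no demographic
trajectories). Consequences for interpretation: passing tests demonstrate
that the estimators and the scan logic are correct and calibrated, not
that they would have the same power on data with realistic LD blocks,
where sweep signals are wider and window statistics are correlated.

Defaults are chosen to emulate a strongly structured clonal crop
collection: sample sizes 10 (OG) + 35 (CG1) + 39 (CG2); pairwise
$F_{ST}$ targets 0.35 (OG–CG1), 0.47 (OG–CG2) and 0.40 (CG1–CG2), the
level at which whole-genome divergence is observed between such groups;
10,000 SNPs on a 20-Mb chromosome, i.e. one marker per 2 kb, dense enough
that a 500-kb window holds ~250 SNPs. Multi-chromosome data are produced
by repeated independent simulation with distinct chromosome names.
Per-genotype depth is Poisson(9) and genotype quality a truncated
Poisson(40), with lognormal site QUAL, so the quality-control filters
operate on realistic margins.

In clonal mode each population consists of a small number of clone
lineages (default 4); members copy their lineage genotype and deviate
per site with the genotyping-error probability, which is the only
within-lineage variation — with error 0 the identity is exact.

### Sweeps, deleterious sites, expression

`inject_sweep()` replaces each target-population genotype in the region
by the regional major-allele homozygote with probability equal to the
diversity reduction. This is deliberately simple: it collapses local
heterozygosity towards fixation (reduction 1 gives $\pi = 0$) without
modelling hitchhiking flanks, and is sufficient to create top-tail
windows for the scans.

`assign_deleterious()` flags an exact count, `round(fraction × n_sites)`,
of sites with scores drawn uniformly in $[0, 0.05]$ (the rest in
$(0.05, 1]$). The default fraction, 0.2864, mirrors the deleterious
share typically reported for nonsynonymous sites in such collections.
With `freq_bias > 0` the flagged sites are sampled with weight
$(1-p)^{\text{bias}}$, emulating purifying selection keeping damaging
alleles rare.

`simulate_expression()` is lognormal on the FPKM scale (baseline log2
mean $\sim N(3, 1.5)$, residual SD 0.8 by default), with per-group
log2-scale mean shifts, gained genes (zeroed outside their group), lost
genes (zeroed inside), and traits built as weighted sums of driver-gene
abundances plus Gaussian noise whose SD is expressed *relative to the
signal SD* — the default of 1 gives an expected gene–trait correlation
near 0.7, comfortably detectable at $P < 0.001$ with 81 accessions. What
it does not emulate: count noise (negative binomial mean–variance),
library-size artefacts, and co-expression structure; FDR-control tests on
these matrices validate the testing machinery, not robustness to
correlated genes.

## Estimators and numerical choices

* **π.** Per-site unbiased heterozygosity $2p(1-p)\,n/(n-1)$ over
  non-missing alleles, summed per window, divided by window length in bp
  (not SNP count). Sites with fewer than two called diploids in the
  population are skipped; windows with fewer than five SNPs are emitted
  with a missing statistic so grids stay aligned across populations. The
  windowless variant divides by the total analyzed length and suits
  sparse reduced-representation data.
* **F<sub>ST</sub>.** Weir–Cockerham (1984) variance components with the
  weighted (ratio-of-sums) estimator; Hudson's estimator is available as
  an independent cross-check and is what the simulator targets map to.
  Negative windowed estimates are clamped to 0 in the `fst` column —
  keeping $-\ln(1-F_{ST})$ defined for PBS — with the raw value kept in
  `fst_raw`. Genome-wide scalars are not clamped.
* **PBS.** $T = -\ln(1-F_{ST})$ (natural log, the branch-length
  convention; log2 is reserved for the π ratio) and
  $\mathrm{PBS} = (T^{TP-CP} + T^{TP-CO} - T^{CP-CO})/2$, i.e. the third
  term is the control–outgroup divergence, which isolates the target
  branch. $F_{ST} = 1$ is clamped to $1 - 10^{-12}$ with a warning,
  negatives to 0. Windows are standardized over all non-missing windows
  and flagged by a one-sided Z-test at $\alpha = 0.05$ — one-sided and
  unadjusted because selection elevates PBS and the scan is a screening
  step whose candidates must then survive a second method; negative-PBS
  windows are never flagged. A degenerate scan with zero variance across
  windows flags nothing (with a warning) rather than erroring.
* **Outlier tails.** Top/bottom 5% quantiles use the nearest-rank method
  with inclusive ties: every window whose value reaches the threshold
  rank value is flagged. Zero or missing diversity windows are excluded
  from the quantile computation and never flagged. The two π-ratio tails
  are taken per comparison (each population pair yields its own
  thresholds).
* **Consensus sweeps.** Method flags are projected onto base pairs before
  intersection because methods may use different grids (XP-CLR windows
  are typically genetic-distance based). Maximal runs covered by at least
  two methods become regions; adjacent runs are merged. This makes the
  consensus monotone: raising the support requirement never enlarges a
  region.
* **Coordinates.** VCF and GFF3 are 1-based on disk; every internal
  interval (windows, sweeps, BED output) is 0-based half-open. Gene
  overlap requires at least 1 bp of intersection, so a gene starting
  exactly at a region's half-open end is excluded.
* **Patterson's D.** Frequency-based ABBA/BABA sums — appropriate for
  unphased diploids — with the outgroup entering through its derived
  frequency, and a delete-one block jackknife (1-Mb blocks by default)
  for the Z-score. Blocks without informative sites are dropped; at least
  two are required.
* **Burden overlap.** In the overlap ratio $(a + 0.5b + 0.25c)/d$ the
  weights are read as allele-sharing probabilities for pairs of
  accessions both carrying a site (both homozygous: 1; homozygous ×
  heterozygous: 0.5; both heterozygous: 0.25), and $d$ is the *union* of
  the two accessions' deleterious sites — under the sum reading, two
  identical all-homozygous profiles would score 0.5 rather than 1, which
  contradicts the ratio's purpose. The self-overlap identity
  $(n_{hom} + 0.25\,n_{het})/n_{total}$ follows and is asserted in the
  tests.
* **Removal and control regions.** A reference-group deleterious site
  counts as removed when *no* derived-group accession carries it — the
  only site-level reading computable from genotypes. Densities are
  compared between sweep regions and all non-overlapping 500-kb windows
  that do not touch a sweep: using the full complement as controls
  matches the size distribution without sampling noise. "Rare" is a
  derived-allele frequency ≤ 0.05 across all accessions.
* **Expression statistics.** The group ANOVA is computed from vectorized
  sums of squares (identical to `anova(lm(...))`, asserted in tests);
  zero-variance genes get $P = 1$. Pairwise group comparisons use the
  two-group ANOVA with BH correction per comparison. "Expresses" means
  abundance strictly greater than 0 — no soft threshold, matching a
  no-transcript-observed definition. In the Shannon–Wiener index the
  dispersion $\delta$ is the sample standard deviation across accessions:
  SD-width bins give unimodal data an entropy near 3 bits, whereas
  standard-error-width bins would push nearly all mass into the two open
  tails and cap H′ near 1 bit, which is incompatible with observed
  ranges; the mean and $\delta$ are computed across accessions per gene
  (a per-accession reading is not computable). A value exactly at
  $x + 2\delta$ joins the upper tail bin. $\delta = 0$ returns H′ = 0.
  Note the ten-bin design bounds H′ at $\log_2 10 \approx 3.32$ bits, and
  exactly uniform occupancy is unattainable for equal-weight samples
  (the tail bins require $|z| > 2$, which contradicts the unit sample
  SD), so the bound is approached but never reached.
* **Association support.** The Bonferroni threshold is $\alpha$ divided
  by the marker count, reported at three significant figures; an
  effective marker count can be supplied instead, though the full count
  already reproduces conventional thresholds. Gene proximity is measured
  to the nearest span edge, strand-ignored, with an inclusive cutoff.

## Filters

Genotype-level: calls with depth < 3 or genotype quality < 5 are set
missing; sites with QUAL < 20 are dropped. Population-level: minor allele
frequency below 0.05 (computed from non-missing alleles; a site exactly
at the threshold is retained) or missingness above 0.2 removes the site;
both thresholds are parameters because association scans conventionally
relax them (MAF ≥ 0.01, missingness ≤ 0.5). Multiallelic VCF records are
split into one biallelic record per alternate allele, counting copies of
that allele against all others; indels are read and counted but excluded
from the statistics. The positional annotator applies the precedence
exonic > splicing > intronic > upstream > downstream > intergenic, with
splicing defined as within 2 bp of an intron boundary; with gene-only
models every in-gene position is exonic, and coding-effect calls beyond
frame/length classification require CDS features and are reported NA
otherwise.

## Problem sizes used by the tests and the acceptance script

The validation suites run three-population simulations of 10,000 SNPs on
a 20-Mb chromosome (30/35/39 accessions for sweep recovery, with one
2.5-Mb injected sweep at diversity reduction 0.9), 50 four-population
null replicates of 4,000 SNPs for D calibration, 1,000-gene null
expression matrices for FDR control, and 60 replicates of 81 normal draws
for the H′ expectation (closed-form normal-bin entropy 3.012 bits).
These sizes give stable Monte-Carlo margins for every asserted band while
keeping a full run in well under a minute.

## Known limitations

Unlinked sites mean no LD-aware statistics (iHS, XP-EHH) and optimistic
window independence; the XP-CLR likelihood itself is not implemented —
scores are consumed from file and thresholded; the annotator does not
call codon-level consequences; dominance and GERP-style conservation are
outside the burden model; and the demographic machinery (effective
population-size trajectories) is intentionally absent.
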