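---
title: "Abundant and rare microbial co-occurrence networks with RMT threshold selection"
author: "MicroNetRMT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abundant and rare microbial co-occurrence networks with RMT threshold selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MicroNetRMT)
```

## The analysis this package implements

Soil microbial communities are dominated numerically by a handful of
abundant taxa while most taxa are rare. The two fractions are widely
analysed separately: taxa whose mean relative abundance exceeds 0.1% are
called *abundant*, those below 0.01% *rare*, and the band in between is
excluded from both groups. MicroNetRMT implements the full comparative
workflow for such partitioned communities across sample groups (e.g.
successional stages): depth standardisation, abundance-class partitioning,
diversity statistics, correlation-based co-occurrence networks with a
random-matrix-theory (RMT) criterion for the similarity threshold, network
topology with degree-preserving random-graph nulls, Zi–Pi keystone
classification, and Mantel-type tests against environmental drivers.

Real amplicon studies supply the input as an ASV count table (samples by
taxa), taxonomy strings and per-sample metadata; the package's synthetic
generator produces tables of the same shape with *known* ground truth so
that every downstream stage can be benchmarked without sequencing data.

## Model and procedure

### Partitioning and prevalence

Relative abundances are per-sample fractions. A taxon's class is decided
by its mean relative abundance across the samples in scope — the
*dataset-mean* reading; a stage-restricted scope is available through the
`samples` argument of `classifyAbundance()`, and stage-wise prevalence is
what `runPipeline()` uses when it builds one network per stage. Retention
for a network additionally requires presence in **strictly more than half**
of the samples in scope: a taxon present in exactly 5 of 10 samples is
excluded. Both cutoffs and the prevalence rule are arguments, with the
conventional defaults (0.001, 0.0001, 0.5).

### Diversity

Chao1 uses the bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$,
Shannon is reported in natural-log units (a `base` argument gives log2),
Bray–Curtis dissimilarity and ANOSIM come from vegan, and PCoA is
classical Gower-centred metric scaling. Negative PCoA eigenvalues —
expected, because Bray–Curtis is not metric — are reported as they are,
without Lingoes/Cailliez correction; coordinates are returned for positive
eigenvalues only, and explained proportions are relative to the sum of
positive eigenvalues. Group contrasts of diversity indices use two-sided
Wilcoxon rank-sum tests (exact for small tie-free samples).

### Network construction and the RMT threshold

For each stage and class, retained taxa's relative abundances are
zero-filled with a pseudo-abundance of 0.01% for taxa present in more than
half of the samples (`fillMissing()`), log10-transformed, and correlated
(Pearson by default, Spearman by flag). The entrywise absolute value of
the correlation matrix is the similarity matrix.

The log transform is a deliberate design choice. The pseudo-count fill
exists precisely to make the logarithm defined, and the log scale has two
consequences that matter here: product-moment correlations of
lognormal-like abundance data stop being driven by single extreme samples,
and strong *negative* associations become expressible — on the raw
abundance scale the Pearson correlation between two lognormal-like taxa is
bounded well above $-1$ (near $-0.36$ at unit log-variance), so no
negative edge could ever reach a 0.88 cutoff. `correlationMatrix(...,
logScale = FALSE)` restores the raw-scale behaviour.

The similarity threshold can be fixed (0.88, the conventional value for
comparing networks across groups) or chosen by the RMT scan
(`rmtThresholdScan()`): for every threshold on the grid 0.30–1.00 (step
0.01) the sub-threshold entries are zeroed, taxa with no remaining partner
dropped, and the eigenvalue spectrum of the thresholded matrix unfolded to
unit mean spacing. The nearest-neighbour spacing distribution (NNSD) of a
noisy, dense correlation matrix follows the Gaussian orthogonal ensemble
(Wigner–Dyson) law $(\pi d/2)\,e^{-\pi d^2/4}$; once the threshold removes
the noise floor and only modular structure remains, spacings follow the
Poisson law $e^{-d}$. The chosen threshold is the smallest grid value from
which the Poisson fit persists across all larger evaluable thresholds —
the transition is one-directional, so a single flip back to GOE
disqualifies a candidate. On a pure-noise matrix no persistent Poisson
regime may exist; the scan then reports `NA` rather than inventing a
threshold.

Numerical choices in the scan, stated once: eigenvalue degeneracies are
collapsed at tolerance `1e-8`; the cumulative spectral function is
smoothed by a monotone (Hyman) cubic spline through $\lceil n/10\rceil$
knots (at least 5); a threshold needs at least 20 distinct eigenvalues to
be evaluable; the NNSD histogram uses 20 bins on $[0, \max d]$, adjacent
bins are pooled until every expected count reaches 5 (Cochran's rule, so
sparse tail bins cannot distort the statistic), and the Poisson fit must
both beat the GOE fit and pass a $\chi^2$ goodness-of-fit gate at the
0.001 level with the pooled degrees of freedom.

### Topology and nulls

All report metrics are computed on the unsigned graph: average degree
$2L/N$; density $2L/(N(N-1))$; mean local clustering with degree-$<2$
nodes contributing 0 (a flag excludes them); global transitivity; mean
geodesic distance over *connected* pairs only; harmonic geodesic distance
$P/\sum 1/d_{ij}$ with disconnected pairs contributing zero reciprocal
distance; degree centralization $\sum(k_{max}-k_i)/((N-1)(N-2))$;
betweenness centralization normalized by the star-graph maximum;
Krackhardt connectedness; the OLS $R^2$ of the log–log degree-count fit
(the descriptive binned-count convention, not a maximum-likelihood
power-law estimate); and fast-greedy modularity. Random expectations come
from Maslov–Sneppen rewiring: 100 replicate graphs by default, each the
result of $10L$ double-edge swap attempts that preserve the degree
multiset exactly (asserted per replicate), summarised as mean ± sd.

### Keystone roles

Within-module connectivity $Z_i$ standardises a node's links into its own
module against that module's members (population sd, including the node;
$Z_i = 0$ when the sd is 0 — the degenerate case has no standard
definition, and 0 keeps such nodes out of the hub set). Among-module
connectivity $P_i = 1 - \sum_t (k_{it}/k_i)^2$. Roles follow the
conventional thresholds, with boundary values on the "≤" branch: a node at
exactly (2.5, 0.62) is peripheral. Connectors, module hubs and network
hubs form the putative keystone set. Keystone identification is done on
the fixed-cutoff network so that role counts are comparable across groups.

### Environmental drivers

Mantel and partial Mantel tests (999 permutations, one-sided positive by
ecological convention, plus-one p-value estimator) relate Bray–Curtis
community distances to Euclidean distances on standardized environmental
variables — the environmental distance metric is not standardised in the
literature; Euclidean-on-z-scores is the common choice and the one used
here. `runPipeline()` reports, per abundance class and per variable, the
partial Mantel correlation controlling the remaining variables. Pearson
correlations of topology metrics against environment
(`envTopologyCorrelation()`) need several networks as observations; with
one network per stage this is only testable across replicate or
resampled networks, which is how the package's own benchmarks exercise it.

## The synthetic benchmark

`generateCommunity()` draws a correlated lognormal–multinomial community:

* **Rank-abundance backbone.** Per-taxon base log-abundances are Normal
  with sd 2 (≥ 1.5 keeps the curve strongly right-skewed), so a default
  2,000-taxon table has fewer than 20% abundant and more than 40% rare
  taxa — the "few abundant, many rare" shape.
* **Planted modules.** Disjoint taxon blocks share a latent Gaussian
  factor at correlation ρ (default 0.95), with optional +/- sign patterns
  that become negative edges. Module taxa are placed at 2.1–2.5 base-sd
  (expected counts ≈ 50–120 at depth 10,065): planted correlations must
  sit clearly above the count-noise floor to be observable at all — at
  lower placement the median planted-taxon count drops near 10, where
  multinomial noise hides even ρ = 0.95 from any correlation measure.
  Planted blocks receive no group shifts, so they are group-invariant.
* **Group structure.** Per-group, per-taxon log shifts (sd 0.6) produce
  the composition turnover that PCoA/ANOSIM detect.
* **Counts.** Each sample is one multinomial draw of `depth` reads
  (default 10,065; 8,000 emulates ITS-scale libraries). Multinomial
  closure is accepted as a property of the benchmark: compositional
  artefacts of real relative-abundance data are present here too.
* **Environment.** Each variable is `coupling × group index + N(0,1)`,
  plus a pure-noise `noise_control` column for negative controls.

What the benchmark does *not* emulate: phylogenetic structure,
zero-inflation beyond multinomial sampling, sequencing error, and
domain-specific abundance distributions. Passing benchmarks therefore
demonstrates that the pipeline recovers structure it is pointed at under
realistic skew, depth and sample sizes — not that any particular field
dataset will behave as cleanly.

Default problem sizes used throughout the package's tests and the
reproduction script — 3 groups × 10 samples, 2,000 taxa, depth 10,065,
999 permutations, 100-network null ensembles (reduced where a toy graph
makes the answer exact) — mirror the scale of a typical single-gradient
amplicon study and are the package's chosen benchmark conditions.

## Degenerate inputs and tie-breaks

* All-zero samples error in `relativeAbundance()` by name; samples below
  the rarefaction depth are dropped with a warning.
* Constant taxa are removed (with a warning) before correlation; fewer
  than 4 samples is an error.
* A cutoff above the largest off-diagonal similarity errors with a
  suggestion rather than returning an empty network; `runPipeline()`
  records such stage/class networks as empty and continues — with
  realistic depths the rare class often has too few strongly correlated
  retained taxa, which is a finding, not a failure.
* Distance ties in ANOSIM use midranks; permutation p-values can never
  drop below $1/(n_{perm}+1)$.
* Graphs that admit no degree-preserving swap (e.g. a triangle) yield a
  null ensemble of identical copies with a warning and sd 0.

## Known limitations

Pearson-on-log abundances is still a composition-blind association
measure; compositionality-aware inference (SparCC-style) is out of scope.
The power-law $R^2$ is descriptive. Betweenness centralization has no
universally agreed normalization; the star-maximum convention used here
is stated so numbers are comparable across runs of this package. The
RMT scan needs enough taxa (roughly 25+ retained) to evaluate spacing
statistics; small stage-wise tables fall back to the fixed cutoff.

## A worked example

```{r example, eval = FALSE}
cfg <- runConfig(seed = 11, nNull = 30)
res <- runPipeline(cfg, outDir = "run1")
readLines(file.path("run1", "run.log"))
```

The run directory contains `partition.tsv`, `diversity.tsv`,
`anosim.tsv`, `wilcoxon.tsv`, `ordination.tsv`, one edge list per
stage/class network, `topology.tsv` (empirical block, then the
random-network block as mean ± sd), `keystone.tsv`, `mantel.tsv` and a
`manifest.tsv` naming the producing stage of every file.
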