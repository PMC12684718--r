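---
title: "phylodepth: locating the phylogenetic depth of community-level genomic trait-environment associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phylodepth methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Communities of environmental bacteria differ not only in which taxa are
present but in the *architecture* of the genomes those taxa carry: genome
size, gene and tRNA counts, GC content, coding density, and the gene
redundancy index (total KO gene copies over distinct KOs in a genome).
Along a strong environmental gradient — the motivating system is benthic
biofilms of glacier-fed streams, sampled as metagenome-assembled genomes
(MAGs) across many catchments — community-weighted means (CWM) of these
features shift with covariates such as benthic chlorophyll-a, streamwater
temperature, distance to the glacier snout, and the glacier index
$GI = \sqrt{A}/(\sqrt{A}+d)$ (area $A$, distance $d$).

A CWM trend alone does not say *where on the phylogeny* it is generated: a
signal can arise from abundance shifts among entire classes (deep) or from
sorting among closely related genomes within genera (shallow). `phylodepth`
implements a phylogeny-rooted framework that (i) localizes the phylogenetic
depth at which a CWM trait-environment association resides, (ii) attributes
the community-level signal to individual clades, and (iii) links attributed
clades to gene content.

## Quality normalization, abundances, and community-weighted means

Draft genomes are incomplete and contaminated, so extensive features are
corrected before any community summary:
$$v_{\text{norm}} = v \cdot \frac{1}{\text{completeness}} \cdot (1 - \text{contamination}),$$
applied to genome size, gene count and tRNA count; intensive ratios (GC
content, coding density, redundancy index) are used as-is. Completeness and
contamination are handled as fractions internally; percent-scaled inputs
(values above 1) are converted on read with a warning, and values already
in $[0,1]$ are never rescaled.

Abundances are trimmed-mean coverages divided by the coverage of the
single-copy *recA* gene in the same sample, i.e. genome-equivalent relative
abundances. A MAG is *present* in a sample when its recA-normalized
coverage strictly exceeds the presence threshold (default 0.1, one tenth of
the community genome equivalents; the multiplier is a configuration field
so either reading of a "10x recA" rule can be matched). The CWM of feature
$f$ in sample $s$ is the abundance-weighted mean over present MAGs,
$$\mathrm{CWM}_{sf} = \frac{\sum_{i \in \text{present}(s)} w_{is}\, v_{if}}
                           {\sum_{i \in \text{present}(s)} w_{is}},$$
which is invariant to sequencing depth because the weights are renormalized
within the sample. MAGs with a missing feature value are dropped from both
sums for that feature only.

## The depth scan

Tips are grouped into *phylogenetic bins* by average-linkage agglomeration
(`hclust`, method `"average"`) of the tree's cophenetic distances, cut at a
*relative height* $h$: the cut height as a fraction of the dendrogram's
maximum merge height, the only scale on which the unit interval spans root
to tips for the agglomeration actually used. The grid is $h_k = k/40$ for
$k = 1..40$ (excluding the trivial all-singleton cut at 0, including the
single-bin cut at 1); merges exactly at the cut height join, which makes
partitions nested along the grid.

At each height, MAG abundance rows are permuted uniformly within bins — the
whole row moves jointly across samples, preserving each MAG's spatial
occupancy pattern — for 20 iterations. After each permutation the CWM of
the focal trait is recomputed and regressed on the focal covariate with a
spatially corrected additive model
$$y_s = \beta x_s + f(\text{lat}_s, \text{lon}_s) + \varepsilon_s,$$
where $f$ is a penalized spline on the sphere (`mgcv`, `bs = "sos"`,
great-circle geometry; basis dimension $\min(n/4, 50)$, penalty selected by
REML). Per height the scan records the mean and standard deviation of
$\hat\beta$ over iterations and pools the per-iteration two-sided Wald
p-values with Stouffer's method using *signed* normal scores
$z_i = \mathrm{sign}(\hat\beta_i)\,\Phi^{-1}(1 - p_i/2)$,
$Z = \sum_i z_i / \sqrt{k}$, so direction-inconsistent iterations cancel.
Heights with pooled $p < \alpha$ (default 0.01) are flagged.

The logic: permuting within bins destroys trait-abundance matching *within*
bins while preserving it *between* bins. An association that survives
permutation at height $h$ therefore resides deeper than $h$; the deepest
flagged height is reported as the signal depth. Coefficient profiles are
normalized by the maximum absolute mean over the grid so different
trait-covariate pairs share a $[-1, 1]$ scale, and median per-rank depths
(the relative height of the smallest cluster containing each genus, family,
class, ...) provide taxonomic depth markers for the same axis.

### A refitting engine for the permutation loop

Within one scan the design (covariate, coordinates, spatial basis) is
fixed; only the response changes. The spatial smoothing parameters are
therefore estimated once, by REML on the observed (unpermuted) CWM, and
held fixed across all heights and iterations; each permuted fit is then the
exact penalized least-squares solve
$\hat\beta = (X^\top X + \sum_j \lambda_j S_j)^{-1} X^\top y$ with the
Bayesian posterior covariance for the Wald standard error. This reproduces
`mgcv` at the same fixed smoothing parameters to machine precision
(unit-tested), and spot checks against full per-iteration REML refits agree
to two significant digits in the pooled p-values, so the shortcut changes
no conclusions while making thousands of refits cheap.

## Clade attribution and enrichment

At a chosen height, every cluster (bin) with at least `minClusterSize`
members (default 5; the removal test is degenerate for singletons) is
evaluated by leave-one-cluster-out: with the same permutation stream, the
per-iteration coefficient is computed with all MAGs and with the cluster's
MAGs removed before the CWM, and the two coefficient *distributions* are
compared by a two-sample Wilcoxon rank-sum test, Holm-adjusted across
clusters. The median relative effect summarizes the contribution:
$$\mathrm{MRE} = \frac{\mathrm{median}_{\text{with}} - \mathrm{median}_{\text{without}}}
                      {\mathrm{median}_{\text{with}}}.$$

A signed-rank variant paired by iteration is available
(`pairedWilcoxon = TRUE`) but is *not* the default: removing any cluster
rescales the coefficient by a small, sign-consistent amount through weight
renormalization, and a paired test over 20 shared iterations flags that
shift regardless of its size — in benchmark runs 30-60% of clusters with no
planted effect were flagged. The two-sample comparison judges the shift
against the full across-iteration spread of the coefficient and recovers
the intended selectivity (only the planted driver clade flagged, with the
largest |MRE|).

Flagged clusters are then profiled taxonomically: for each cluster and each
taxon at a chosen rank, a two-sided Fisher exact test on the 2x2 table
(in-cluster vs not, taxon vs not) over the whole MAG universe, Holm-adjusted
across all cluster-taxon tests, identifies taxa with disproportionately
many MAGs in the cluster.

## Functional layer

To connect attributed clades to gene content, KO copy numbers are
log-transformed after adding half of the minimal non-zero value of the
whole matrix as a pseudocount (natural logs; rank tests and LASSO selection
are base-invariant). Per KO, a two-sided Wilcoxon rank-sum test compares
in-clade vs out-of-clade log copies, Bonferroni-adjusted over all KOs; a KO
is called only when its adjusted $p < 0.01$ *and* the in-minus-out mean log
difference is positive (higher redundancy inside the clade). Sparse
clade-marker selection uses L1-penalized logistic regression of membership
on the standardized log matrix (`glmnet`), with the penalty chosen by
stratified 10-fold cross-validation under the one-standard-error rule —
deliberately conservative — and deterministic fold assignment from the
seed. KO sets from different trait-covariate contrasts are compared by
plain intersection.

Ecological-success comparisons (a MAG-level feature against prevalence or
mean abundance) use shrinkage splines (`bs = "ts"`, basis dimension 5),
optionally one spline per group, fitted by maximum likelihood so that the
two fixed-effect structures are comparable by the BIC-approximate Bayes
factor $\mathrm{BF} = \exp((\mathrm{BIC}_{\text{shared}} -
\mathrm{BIC}_{\text{grouped}})/2)$, with BF > 3 read as support for
group-specific curves.

## The synthetic benchmark

Because the framework's statistical behavior can only be validated against
known truth, the generator builds all five inputs with planted parameters:

* **Tree**: pure-birth, conditioned on the tip count, rescaled to unit
  depth. Because the tree is ultrametric, the average-linkage dendrogram of
  its cophenetic distances reproduces node ages exactly, so planted clades
  sit at exact relative heights. Signal scenarios graft a driver clade pair
  with crown ages just below the target depth, joining just above it.
* **Traits**: the planted trait is genome size, baseline 4 Mb with 0.25 Mb
  tip-level noise; driver clades deviate by +/- 1 Mb (between-genus to
  between-class genome-size differences of this order are typical).
  Completeness and contamination are drawn from [0.7, 1] x [0, 0.1] and raw
  values back-computed so quality normalization recovers the planted values
  exactly. In the depth-recovery scenarios the background clades are
  trait-neutral, so no systematic between-bin signal survives above the
  planted depth; the attribution scenario instead carries genus-level
  background clade structure (half the driver deviation), because
  within-cluster trait heterogeneity is what makes leave-one-cluster-out
  differences of non-driver clusters jitter, as in real communities.
* **Samples**: coordinates scattered around six mountain-range centers; a
  latent glacial-influence factor drives glacier area (up), distance,
  temperature and log chlorophyll-a (down) with independent noise; the
  glacier index is derived, not drawn.
* **Abundances**: per-MAG lognormal baselines with multiplicative
  sample-to-sample noise of 2 natural-log units (roughly two orders of
  magnitude at 95%, as coverage-derived abundances span across widely
  separated streams); driver-clade members shift by +/- 0.2 log-units per
  covariate standard deviation in the paired scenarios (a weak per-genome
  response buried in noise — the regime the permutation framework targets)
  and 1 log-unit in the single-driver attribution scenario (a dominant
  responder). The smallest quarter of values is zeroed for sparsity.
* **KO profiles**: Poisson baselines (means 0.4-1.2), ten enriched KOs at
  baseline mean 2 with fold 2 in a 40-MAG clade (against 160), plus one
  perfectly separating marker KO.

The paired-clade construction (opposite trait deviations, opposite
abundance responses, equal sizes) is what makes the planted depth *sharp*:
below the joining height each driver clade is its own bin and permutation
preserves the association; at any coarser cut the two clades share a bin,
their opposed contributions cancel under within-bin shuffling, and the
signal vanishes. The `null` scenario keeps the planted trait structure but
zeroes the abundance response, making it the matched no-association
control.

Default scale is 200 MAGs x 60 samples — chosen so a full 40-height x
20-iteration scan completes in well under a second with the refitting
engine, while keeping cluster sizes (5-50) in the range where the
attribution statistics are meaningful. What the generator does *not*
emulate: compositionality of real coverage tables, MAG-quality biases
correlated with taxonomy, biome-scale phylogeographic structure, or
correlated KO modules; recovery results on these benchmarks therefore
demonstrate internal consistency of the framework, not robustness to every
property of real surveys.

## Numerical choices and degenerate inputs

* One root seed drives everything; child seeds are derived
  deterministically per stage, height and iteration, so scans, benchmarks
  and CLI runs are byte-reproducible and leave the caller's RNG state
  untouched.
* Dendrogram cuts are inclusive at the cut height (ties merge), which
  preserves nestedness across the grid; agglomeration tie-breaking follows
  `hclust`'s deterministic internal rule.
* p-values of exactly 0 or 1 entering the Stouffer pool are clipped to the
  open interval (with a warning); normal quantiles are computed on the
  upper tail so extremely small p-values do not overflow.
* Constant responses yield a zero coefficient with $p = 1$ rather than an
  error; constant covariates are a hard error (degenerate design).
* A cluster whose removal leaves every coefficient unchanged (e.g. zero
  abundance everywhere) is reported as a no-op: $p = 1$, MRE 0. Samples
  losing all present MAGs after a removal are dropped for that cluster with
  a warning; iterations whose fit fails are dropped, and a height is
  reported missing when more than half its iterations fail.
* Infinite odds ratios in enrichment (taxon confined to a cluster) are
  reported as `Inf`, never silently truncated.

## Known limitations

* **Shallow heights are anti-conservative under a global null.** Near the
  tips, bins are almost all singletons, so the permutations are
  near-identities and the 20 iterations return essentially the same
  p-value as the observed fit; pooling then multiplies that one z-score by
  $\sqrt{20}$. Whenever the observed no-association $|z|$ exceeds
  $2.576/\sqrt{20} \approx 0.58$ — more than half of null datasets — every
  near-identity height is flagged. Flags at shallow heights should
  therefore be read together with the observed-data fit, not as a
  calibrated family-wise test; this is a property of pooling
  permutation-conditional p-values, inherent to the procedure.
* **Isolated deep false flags.** At heights where the signal is destroyed,
  the pooled test is approximately calibrated per height, so over a
  40-point grid a handful of isolated alpha-level flags are expected. The
  deepest *contiguous* run of significant heights starting at the tips is
  the robust depth readout (both readouts are reported by the acceptance
  script); the single deepest flagged height can occasionally overshoot.
* The scan's smoothing parameters are reused across permutations within a
  scan (validated against full refits, above); users wanting fully
  independent fits can call `fitTraitGam()` per permutation at ~50x the
  cost.
* CWM weights are renormalized over present MAGs only, and presence uses a
  strict threshold; both are configuration-level choices that matter near
  the detection limit of low-abundance MAGs.
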