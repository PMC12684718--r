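# phylodepth

Locating the phylogenetic depth at which community-level genomic
trait–environment associations arise, for metagenome-assembled genomes
(MAGs) sampled along environmental gradients.

## What it does, and for whom

Surveys of environmental microbiomes — the motivating system is benthic
biofilms of glacier-fed streams sampled as thousands of MAGs across many
catchments — routinely find that community-weighted means (CWM) of genomic
features (genome size, gene and tRNA counts, GC content, coding density,
gene redundancy index) track environmental covariates such as benthic
chlorophyll-a, streamwater temperature, distance to the glacier snout, or
the glacier index `GI = √A / (√A + d)`. A CWM trend alone does not reveal
*where on the phylogeny* it is generated: by abundance shifts among whole
classes, or by sorting among close relatives within genera.

`phylodepth` is for microbial ecologists and comparative genomicists who
have (a) a MAG feature table with completeness/contamination, (b) a
MAG-by-sample table of recA-normalized coverages, (c) sample metadata with
coordinates and covariates, (d) a rooted phylogeny over the MAGs, and (e)
optionally a MAG-by-KO copy-number table. It provides:

1. **Feature layer** — quality normalization
   `v · (1/completeness) · (1 − contamination)`, redundancy index
   (total/distinct KO copies), presence calls, prevalence, and CWMs
   weighted by recA-normalized abundances of present MAGs.
2. **Depth scan** — for 40 relative heights `h` of the average-linkage
   dendrogram of cophenetic distances, abundances are permuted within the
   phylogenetic bins obtained at `h` (20 iterations); each permuted CWM is
   regressed on the covariate with a spatially corrected GAM (spline on the
   sphere over latitude/longitude, mgcv `bs = "sos"`); per-iteration
   p-values are pooled with signed Stouffer scores. A signal that survives
   permutation at `h` lives deeper than `h`; the deepest significant height
   localizes it.
3. **Clade attribution** — leave-one-cluster-out: coefficients with and
   without each cluster, compared by Wilcoxon tests with Holm adjustment,
   summarized by the median relative effect
   `(median_with − median_without) / median_with`, plus Fisher-exact
   taxonomic enrichment of flagged clusters.
4. **Functional layer** — per-KO copy-number tests (Wilcoxon on
   log-transformed counts with a half-minimum pseudocount, Bonferroni),
   LASSO selection of clade-marker KOs, KO set intersections, and
   grouped-spline "ecological success" models compared by BIC Bayes
   factors.
5. **Synthetic benchmarks** — a generator that emits all five inputs with
   planted ground truth (signal depth, driver clades, KO enrichments), so
   every stage is testable by parameter recovery.

The central container is `MAGExperiment`, an S4 class extending
`SummarizedExperiment` (abundance assay, MAG metadata in `rowData`, sample
metadata in `colData`, plus the tree, KO matrix and presence threshold).
See `vignette` source `vignettes/phylodepth-methods.Rmd` for the model,
the generator design and known limitations.

## Worked example

Generate a benchmark in which a clade pair planted at relative height 0.6
(crown ages just below, joining just above) carries opposite genome-size
deviations (±1 Mb) and opposite abundance responses to chlorophyll-a, then
scan:

```r
library(phylodepth)

cfg   <- analysisConfig(seed = 1)              # 40 heights x 20 iterations
bench <- generateBenchmark(cfg, "deep_signal") # 200 MAGs x 60 samples
prof  <- runDepthScan(bench$experiment, "genome_size", "chlorophyll_a", cfg)
prof
#> ScanProfile: genome_size ~ chlorophyll_a over 40 heights (20 iterations, seed 1)
#>   24/40 heights significant at alpha = 0.01; deepest: 0.6

as.data.frame(prof)[c(8, 16, 24, 25, 32, 40),
                    c("height", "coef_mean", "pooled_p", "n_bins", "significant")]
#>    height  coef_mean pooled_p n_bins significant
#> 8   0.200 110130.299   0.0000     74        TRUE
#> 16  0.400 115794.325   0.0000     26        TRUE
#> 24  0.600 114557.361   0.0000      9        TRUE
#> 25  0.625   5968.603   0.3953      8       FALSE
#> 32  0.800   8920.850   0.2120      3       FALSE
#> 40  1.000   2793.299   0.7786      1       FALSE
```

The coefficient (bp of CWM genome size per µg g⁻¹ chlorophyll-a) holds
near 115,000 at every height up to 0.6 and collapses twenty-fold one grid
step deeper — the permutation destroys the association exactly when the
planted clades first share a bin, so the recovered signal depth is 0.6.
Attribution at that height flags the two 50-member driver clades with the
largest median relative effects:

```r
loco <- leaveOneClusterOut(bench$experiment, "genome_size", "chlorophyll_a",
                           0.6, cfg)
head(loco[, c("cluster_id", "n_members", "wilcoxon_p", "p_adjusted",
              "median_relative_effect", "significant")], 3)
#>   cluster_id n_members wilcoxon_p p_adjusted median_relative_effect significant
#> 7          8        50   1.45e-11   1.16e-10                  0.794        TRUE
#> 8          9        50   1.45e-11   1.16e-10                  0.346        TRUE
#> 3          4        29   3.72e-04   1.86e-03                 -0.119        TRUE
```

Removing the first driver clade erases 79% of the community-level slope.
The same workflow runs from the shell:

```sh
phylodepth simulate --scenario deep_signal --seed 1 --out bench/
phylodepth scan --mags bench/mag_features.tsv --abundance bench/abundance.tsv \
  --samples bench/samples.tsv --tree bench/tree.nwk \
  --trait genome_size --covariate chlorophyll_a --seed 1 --out scan/
```

(`phylodepth` is the wrapper installed at
`system.file("scripts", "phylodepth", package = "phylodepth")`; every
subcommand writes TSV outputs plus a JSON run manifest and is
byte-reproducible under a fixed seed.)

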