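test_that("within-bin permutation preserves per-bin multisets and bin walls", {
  set.seed(11)
  ab <- matrix(rexp(20 * 6), 20, 6,
               dimnames = list(sprintf("m%02d", 1:20), sprintf("s%d", 1:6)))
  bins <- new("BinAssignment", relativeHeight = 0.5,
              bins = setNames(rep(1:5, each = 4L), rownames(ab)), nBins = 5L)
  for (seed in 1:20) {
    out <- permuteWithinBins(ab, bins, seed)
    expect_equal(dim(out), dim(ab))
    for (b in 1:5) {
      rows <- which(binMembership(bins)[rownames(ab)] == b)
      for (s in 1:6) {
        # per bin and per sample the multiset of values is exactly preserved
        expect_equal(sort(unname(out[rows, s])), sort(unname(ab[rows, s])))
      }
      # rows never leave their bin: each permuted row matches a row of the bin
      for (r in rows) {
        expect_true(any(apply(ab[rows, , drop = FALSE], 1,
                              function(v) identical(unname(v), unname(out[r, ])))))
      }
    }
  }
  # all-singleton bins: identity
  single <- new("BinAssignment", relativeHeight = 0,
                bins = setNames(seq_len(20L), rownames(ab)), nBins = 20L)
  expect_identical(permuteWithinBins(ab, single, 3L), ab)
  # determinism
  expect_identical(permuteWithinBins(ab, bins, 42L),
                   permuteWithinBins(ab, bins, 42L))
  # missing MAG in the bin map
  bad <- new("BinAssignment", relativeHeight = 0.5,
             bins = setNames(rep(1L, 5), rownames(ab)[1:5]), nBins = 1L)
  expect_error(permuteWithinBins(ab, bad, 1L),
               class = "phylodepth_alignment_error")
})

test_that("the scan's fast CWM path equals CWM of the explicitly permuted matrix", {
  ex <- makeToyExperiment()
  ctx <- phylodepth:::cwmContext(ex, "genome_size")
  dendro <- buildDendrogram(copheneticMatrix(magTree(ex)))
  for (h in c(0.1, 0.4, 0.8)) {
    ba <- binsAtRelativeHeight(dendro, h)
    b <- binMembership(ba)[ctx$magIds]
    for (seed in c(1L, 9L)) {
      pi <- phylodepth:::binPermutationIndex(b, seed)
      fast <- phylodepth:::cwmFromContext(ctx, perm = pi)
      abPerm <- permuteWithinBins(abundances(ex), ba, seed)
      exPerm <- MAGExperiment(abPerm,
                              as.data.frame(SummarizedExperiment::rowData(ex)),
                              as.data.frame(SummarizedExperiment::colData(ex)),
                              magTree(ex), koCounts(ex), presenceThreshold(ex))
      slow <- communityWeightedMeans(exPerm)[, "genome_size"]
      expect_equal(fast, slow, tolerance = 1e-12)
    }
  }
})

test_that("depth scans are deterministic and singleton bins reproduce the observed fit", {
  ex <- makeToyExperiment()
  cfg <- analysisConfig(seed = 5L, nHeights = 8L, nIterations = 5L)
  p1 <- suppressWarnings(runDepthScan(ex, "genome_size", "chlorophyll_a", cfg))
  p2 <- suppressWarnings(runDepthScan(ex, "genome_size", "chlorophyll_a", cfg))
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_s4_class(p1, "ScanProfile")
  # at an all-singleton cut every permutation is the identity: sd of the
  # coefficient is 0 and the mean equals the unpermuted-data coefficient
  dendro <- buildDendrogram(copheneticMatrix(magTree(ex)))
  ba0 <- binsAtRelativeHeight(dendro, 0)
  expect_equal(nBins(ba0), nrow(ex))
  ctx <- phylodepth:::cwmContext(ex, "genome_size")
  pi0 <- phylodepth:::binPermutationIndex(binMembership(ba0)[ctx$magIds], 1L)
  expect_identical(pi0, seq_len(nrow(ex)))
})

test_that("profile normalization scales by the maximum absolute coefficient", {
  mk <- function(cm) {
    nh <- length(cm)
    new("ScanProfile", trait = "t", covariate = "c",
        heights = seq_len(nh) / nh, coefMean = cm, coefSd = abs(cm) / 10,
        pooledP = rep(0.5, nh), normalizedCoef = rep(NA_real_, nh),
        nBins = rep(1L, nh), nOk = rep(1L, nh), nIterations = 1L,
        seed = 1L, alpha = 0.01)
  }
  expect_equal(normalizeProfile(mk(c(1, 2, 4)))@normalizedCoef,
               c(0.25, 0.5, 1))
  expect_equal(normalizeProfile(mk(c(-4, 2)))@normalizedCoef, c(-1, 0.5))
  expect_equal(abs(normalizeProfile(mk(-3))@normalizedCoef), 1)
  expect_warning(z <- normalizeProfile(mk(c(0, 0))),
                 class = "phylodepth_zero_profile")
  expect_equal(z@normalizedCoef, c(0, 0))
  set.seed(12)
  cm <- rnorm(40)
  expect_equal(max(abs(normalizeProfile(mk(cm))@normalizedCoef)), 1)
  expect_equal(normalizeProfile(mk(cm))@normalizedCoef,
               oracleNormalizeProfile(cm))
})

test_that("leave-one-cluster-out computes MREs per the median formula", {
  cfg <- analysisConfig(seed = 31L)
  bb <- generateBenchmark(cfg, "single_driver_clade", nMags = 80L,
                          nSamples = 20L)
  loco <- suppressWarnings(
    leaveOneClusterOut(bb$experiment, "genome_size", "chlorophyll_a",
                       bb$truth$eval_height, cfg))
  expect_true(all(c("cluster_id", "n_members", "wilcoxon_p", "p_adjusted",
                    "median_relative_effect", "significant") %in% names(loco)))
  expect_equal(loco$median_relative_effect,
               (loco$median_with - loco$median_without) / loco$median_with)
  expect_true(all(loco$n_members >= cfg@minClusterSize))
  expect_true(all(loco$p_adjusted >= loco$wilcoxon_p - 1e-15))
  # medians 2 and 1 give MRE 0.5 by the formula used
  expect_equal(oracleMRE(c(2, 2, 2), c(1, 1, 1)), 0.5)
})

test_that("removing a zero-abundance cluster is a no-op with p = 1", {
  ex <- makeToyExperiment()
  ab <- abundances(ex)
  dendro <- buildDendrogram(copheneticMatrix(magTree(ex)))
  ba <- binsAtRelativeHeight(dendro, 0.25)
  b <- binMembership(ba)[rownames(ex)]
  sizes <- table(b)
  target <- as.integer(names(sizes)[sizes >= 5][1])
  ab[names(b)[b == target], ] <- 0
  ex0 <- MAGExperiment(ab, as.data.frame(SummarizedExperiment::rowData(ex)),
                       as.data.frame(SummarizedExperiment::colData(ex)),
                       magTree(ex), koCounts(ex), presenceThreshold(ex))
  cfg <- analysisConfig(seed = 3L, nIterations = 10L)
  loco <- suppressWarnings(
    leaveOneClusterOut(ex0, "genome_size", "chlorophyll_a", 0.25, cfg))
  row <- loco[loco$cluster_id == target, ]
  expect_equal(row$median_relative_effect, 0)
  expect_equal(row$wilcoxon_p, 1)
  expect_false(row$significant)
})

test_that("degenerate single-cluster leave-one-out is rejected", {
  ex <- makeToyExperiment()
  cfg <- analysisConfig(seed = 3L, minClusterSize = nrow(ex))
  expect_error(
    suppressWarnings(
      leaveOneClusterOut(ex, "genome_size", "chlorophyll_a", 1, cfg)),
    class = "phylodepth_domain_error")
})

test_that("class enrichment agrees with exact hypergeometric enumeration", {
  # background-rate cluster: independence, p = 1
  tax <- data.frame(class = rep(c("X", "Y"), each = 10),
                    row.names = sprintf("m%02d", 1:20))
  loco <- data.frame(cluster_id = 1L, n_members = 10L, wilcoxon_p = 1e-5,
                     p_adjusted = 1e-5, median_relative_effect = 1,
                     median_with = 1, median_without = 0, significant = TRUE)
  loco$members <- list(sprintf("m%02d", c(1:5, 11:15)))  # 5 of each class
  enr <- classEnrichment(loco, tax, rank = "class")
  expect_true(all(enr$fisher_p == 1))

  # 8/2 vs 2/8 table: two-sided exact p matches the enumeration oracle
  loco$members <- list(sprintf("m%02d", c(1:8, 11:12)))
  enr2 <- classEnrichment(loco, tax, rank = "class")
  pX <- enr2$fisher_p[enr2$taxon == "X"]
  expect_equal(pX, oracleFisherTwoSided(matrix(c(8, 2, 2, 8), 2)),
               tolerance = 1e-9)
  expect_equal(pX, 0.0230, tolerance = 1e-3)

  # a class confined to the cluster: tiny p, infinite odds ratio
  tax3 <- data.frame(class = c(rep("Z", 10), rep("W", 90)),
                     row.names = sprintf("m%03d", 1:100))
  loco3 <- loco
  loco3$members <- list(sprintf("m%03d", 1:10))
  enr3 <- classEnrichment(loco3, tax3, rank = "class")
  pZ <- enr3[enr3$taxon == "Z", ]
  expect_lt(pZ$fisher_p, 1e-3)
  expect_true(is.infinite(pZ$odds_ratio))
})
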