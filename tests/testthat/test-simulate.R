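test_that("simulated trees are deterministic, ultrametric, unit depth", {
  t1 <- simulateTree(50, 1L)
  t2 <- simulateTree(50, 1L)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  depths <- ape::node.depth.edgelength(t1)[seq_len(50)]
  expect_true(all(abs(depths - 1) < 1e-9))
  t3 <- simulateTree(200, 2L)
  expect_equal(max(copheneticMatrix(t3)), 2, tolerance = 1e-9)
  expect_error(simulateTree(3, 1L), class = "phylodepth_domain_error")
})

test_that("simulated traits carry the planted clade structure", {
  tr <- simulateTree(60, 3L)
  # no effect, no noise: all tips identical
  flat <- simulateTraits(tr, 0.5, 0, 0, 4L, baseline = 10)
  expect_true(all(flat$value == 10))
  # noise 0: within-clade variance exactly 0 at the planted cut
  s <- simulateTraits(tr, 0.6, 5, 0, 5L)
  expect_true(all(tapply(s$value, s$clade, var, default = 0) %in% c(0, NA) |
                    tapply(s$value, s$clade, length) == 1))
  # quality normalization recovers the planted values exactly
  expect_equal(normalizeFeature(s$value_raw, s$completeness, s$contamination),
               s$value, tolerance = 1e-12)
  expect_true(all(s$completeness >= 0.7 & s$completeness <= 1))
  expect_true(all(s$contamination >= 0 & s$contamination <= 0.1))
})

test_that("trait signal planted deep shows stronger clustering at its depth", {
  # intraclass correlation of traits within clades-at-0.6 exceeds that
  # within clades-at-0.9 when the signal is planted at 0.6
  icc <- function(values, groups) {
    gm <- tapply(values, groups, mean)
    b <- var(gm[as.character(groups)])
    w <- mean(tapply(values, groups, var), na.rm = TRUE)
    b / (b + w)
  }
  wins <- replicate(10, {
    seed <- sample.int(1e6, 1)
    tr <- simulateTree(80, seed)
    dendro <- buildDendrogram(copheneticMatrix(tr))
    s <- simulateTraits(tr, 0.6, 5, 1, seed + 1)
    g06 <- binMembership(binsAtRelativeHeight(dendro, 0.6))[s$mag_id]
    g09 <- binMembership(binsAtRelativeHeight(dendro, 0.9))[s$mag_id]
    icc(s$value, g06) > icc(s$value, g09)
  })
  expect_gt(mean(wins), 0.7)
})

test_that("simulated samples are deterministic with coherent covariates", {
  s1 <- simulateSamples(500, 6L)
  s2 <- simulateSamples(500, 6L)
  expect_identical(s1, s2)
  g <- attr(s1, "latentFactor")
  expect_lt(cor(s1$chlorophyll_a, g), -0.4)   # chla drops with glacial influence
  expect_gt(cor(s1$glacier_index, g), 0.4)
  expect_true(all(s1$glacier_index >= 0 & s1$glacier_index <= 1))
  expect_true(all(abs(s1$latitude) <= 90))
  expect_error(simulateSamples(5, 1L), class = "phylodepth_domain_error")
})

test_that("driver clades respond to the covariate in simulated abundances", {
  tr <- simulateTree(60, 7L)
  samples <- simulateSamples(40, 8L)
  drivers <- list(A = tr$tip.label[1:12])
  slopes <- replicate(15, {
    seed <- sample.int(1e6, 1)
    ab <- simulateAbundances(tr, samples, drivers, abundanceEffect = 1,
                             seed = seed, driverSigns = 1, logNoiseSd = 0.5)
    z <- as.numeric(scale(samples$chlorophyll_a))
    mean(sapply(drivers$A, function(m) {
      y <- log(ab[m, ] + 1e-6)
      coef(lm(y ~ z))[["z"]]
    }))
  })
  expect_gte(mean(slopes > 0), 0.95)
  expect_true(all(simulateAbundances(tr, samples, seed = 1L) >= 0))
  expect_identical(simulateAbundances(tr, samples, seed = 9L),
                   simulateAbundances(tr, samples, seed = 9L))
  expect_error(
    simulateAbundances(tr, samples,
                       list(tr$tip.label[1:5], tr$tip.label[4:8]), 1, 1L),
    class = "phylodepth_domain_error")
})

test_that("KO profile simulation plants recoverable enrichment", {
  ids <- sprintf("mag_%03d", 1:100)
  m <- simulateKoProfiles(100, 50, 5, 2, ids[1:25], 10L,
                          perfectMarker = TRUE)
  expect_identical(m, simulateKoProfiles(100, 50, 5, 2, ids[1:25], 10L,
                                         perfectMarker = TRUE))
  expect_length(attr(m, "enrichedKos"), 5)
  expect_equal(attr(m, "markerKo"), "K99999")
  expect_true(all(m[ids[1:25], "K99999"] >= 1))
  expect_true(all(m[ids[26:100], "K99999"] == 0))
  # fold = 1 plants nothing
  m0 <- simulateKoProfiles(100, 50, 5, 1, ids[1:25], 10L)
  expect_length(attr(m0, "enrichedKos"), 0)
  expect_error(simulateKoProfiles(10, 5, 2, 0, ids[1:2], 1L),
               class = "phylodepth_domain_error")
  expect_error(simulateKoProfiles(10, 5, 9, 2, ids[1:2], 1L),
               class = "phylodepth_domain_error")
})

test_that("benchmark bundles are truth-consistent and align with zero drops", {
  cfg <- analysisConfig(seed = 17L)
  bb <- generateBenchmark(cfg, "deep_signal")
  ex <- bb$experiment
  tree <- magTree(ex)
  # driver clades are monophyletic in the emitted tree
  for (cl in bb$truth$driver_clades) {
    expect_true(ape::is.monophyletic(tree, cl))
  }
  # the smallest dendrogram cluster containing each driver clade sits within
  # one grid step of the planted signal height
  dendro <- buildDendrogram(copheneticMatrix(tree))
  sets <- phylodepth:::mergeTipSets(dendro)
  maxh <- max(dendro$height)
  for (cl in bb$truth$driver_clades) {
    idx <- match(cl, dendro$labels)
    k <- which(vapply(sets, function(s) all(idx %in% s), logical(1)))[1]
    relH <- dendro$height[k] / maxh
    expect_lt(abs(relH - bb$truth$signal_height), 1 / cfg@nHeights + 1e-9)
  }
  # null truth lists no driver clades
  expect_length(generateBenchmark(cfg, "null")$truth$driver_clades, 0)
  # bundle survives alignInputs with zero drops
  dir <- withr::local_tempdir()
  writeInputBundle(ex, dir)
  expect_no_message(
    ex2 <- alignInputs(readMagTable(file.path(dir, "mag_features.tsv")),
                       readAbundanceTable(file.path(dir, "abundance.tsv")),
                       readMagTree(file.path(dir, "tree.nwk")),
                       readSampleTable(file.path(dir, "samples.tsv")),
                       readKoTable(file.path(dir, "ko_counts.tsv"))))
  expect_equal(dim(ex2), dim(ex))
})

test_that("a fixed seed reproduces a byte-identical bundle", {
  cfg <- analysisConfig(seed = 23L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generateBenchmark(cfg, "shallow_signal", dir = d1)
  generateBenchmark(cfg, "shallow_signal", dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
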