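test_that("glacierIndex matches its closed form and limits", {
  expect_equal(glacierIndex(0, 500), 0)
  expect_equal(glacierIndex(1e6, 0), 1)
  expect_equal(glacierIndex(1e6, 1000), 0.5)
  expect_error(glacierIndex(0, 0), class = "phylodepth_domain_error")
  expect_error(glacierIndex(-1, 10), class = "phylodepth_domain_error")
  set.seed(1)
  a <- runif(200, 0, 1e7)
  d <- runif(200, 1, 1e4)
  expect_equal(glacierIndex(a, d), oracleGlacierIndex(a, d), tolerance = 1e-14)
  # monotone: increasing in area, decreasing in distance
  expect_true(all(diff(glacierIndex(seq(1, 1e6, length = 50), 100)) > 0))
  expect_true(all(diff(glacierIndex(1e6, seq(1, 1e4, length = 50))) < 0))
})

test_that("normalizeFeature applies the quality correction exactly", {
  expect_equal(normalizeFeature(5, 1, 0), 5)
  expect_equal(normalizeFeature(100, 0.5, 0.1), 180)
  expect_equal(normalizeFeature(3e6, 0.75, 0.05), 3.8e6)
  expect_error(normalizeFeature(1, 0, 0), class = "phylodepth_domain_error")
  expect_error(normalizeFeature(1, 0.5, 1), class = "phylodepth_domain_error")
  # monotonicity: increasing in value, decreasing in completeness/contamination
  expect_true(normalizeFeature(2, 0.8, 0.1) > normalizeFeature(1, 0.8, 0.1))
  expect_true(normalizeFeature(1, 0.7, 0.1) > normalizeFeature(1, 0.9, 0.1))
  expect_true(normalizeFeature(1, 0.8, 0.05) > normalizeFeature(1, 0.8, 0.1))
})

test_that("redundancyIndex is copies over distinct KOs, 1 iff no duplication", {
  expect_equal(redundancyIndex(c(k1 = 1, k2 = 1)), 1)
  expect_equal(redundancyIndex(c(k1 = 2, k2 = 1)), 1.5)
  expect_equal(redundancyIndex(c(k1 = 3)), 3)
  expect_error(redundancyIndex(c(k1 = 0)), class = "phylodepth_domain_error")
  set.seed(2)
  for (i in 1:25) {
    counts <- rpois(50, 0.8)
    if (all(counts == 0)) next
    expect_equal(redundancyIndex(counts), oracleRedundancyIndex(counts))
    if (all(counts <= 1)) expect_equal(redundancyIndex(counts), 1)
    if (any(counts > 1)) expect_gt(redundancyIndex(counts), 1)
  }
})

test_that("normalizeCoverage divides by recA and rejects non-positive recA", {
  expect_equal(normalizeCoverage(10, 10), 1)
  expect_equal(normalizeCoverage(5, 20), 0.25)
  expect_error(normalizeCoverage(3, 0), class = "phylodepth_domain_error")
})

test_that("prevalence counts samples strictly above the threshold", {
  ab <- matrix(c(0.5, 0.05, 0.2, 0.2), 2, byrow = TRUE,
               dimnames = list(c("mag1", "mag2"), c("s1", "s2")))
  md <- data.frame(completeness = c(1, 1), contamination = c(0, 0),
                   genome_size = c(1e6, 2e6), row.names = c("mag1", "mag2"))
  sd <- data.frame(latitude = c(0, 1), longitude = c(0, 1),
                   row.names = c("s1", "s2"))
  tr <- ape::read.tree(text = "(mag1:1,mag2:1);")
  ex <- MAGExperiment(ab, md, sd, tr, presenceThreshold = 0.1)
  expect_equal(prevalence(ex), c(mag1 = 1L, mag2 = 2L))
  # all-zero matrix: zero prevalence everywhere
  ex0 <- MAGExperiment(ab * 0, md, sd, tr, presenceThreshold = 0.1)
  expect_equal(unname(prevalence(ex0)), c(0L, 0L))
  # ties at the threshold count as absent (strict comparison)
  exT <- MAGExperiment(ab, md, sd, tr, presenceThreshold = 0.2)
  expect_equal(prevalence(exT), c(mag1 = 1L, mag2 = 0L))
  # threshold 0: present wherever positive
  exZ <- MAGExperiment(ab, md, sd, tr, presenceThreshold = 0)
  expect_equal(unname(prevalence(exZ)), c(2L, 2L))
})

test_that("community-weighted means reproduce hand examples", {
  tr <- ape::read.tree(text = "((m1:1,m2:1):1,m3:2);")
  md <- data.frame(completeness = rep(1, 3), contamination = rep(0, 3),
                   genome_size = c(4, 8, 7), row.names = c("m1", "m2", "m3"))
  sd <- data.frame(latitude = 1:3, longitude = 1:3,
                   row.names = c("s1", "s2", "s3"))
  # s1: only m3 present (trait 7); s2: equal weights on traits 4, 8;
  # s3: weights 0.75/0.25 on traits 4, 8
  ab <- matrix(c(0, 0.5, 0.75,
                 0, 0.5, 0.25,
                 2, 0, 0), 3, byrow = TRUE,
               dimnames = list(c("m1", "m2", "m3"), c("s1", "s2", "s3")))
  ex <- MAGExperiment(ab, md, sd, tr, presenceThreshold = 0.05)
  cwm <- communityWeightedMeans(ex)
  expect_equal(unname(cwm[, "genome_size"]), c(7, 6, 5))
})

test_that("CWM matches the double-loop oracle and its invariances", {
  set.seed(3)
  for (rep in 1:5) {
    ab <- matrix(rexp(50 * 20, 2), 50, 20,
                 dimnames = list(sprintf("m%02d", 1:50), sprintf("s%02d", 1:20)))
    traits <- matrix(rnorm(50 * 3), 50, 3,
                     dimnames = list(rownames(ab), c("f1", "f2", "f3")))
    traits[sample(150, 10)] <- NA
    md <- data.frame(completeness = rep(1, 50), contamination = rep(0, 50),
                     row.names = rownames(ab))
    sd <- data.frame(latitude = rnorm(20), longitude = rnorm(20),
                     row.names = colnames(ab))
    tr <- ape::rtree(50, tip.label = rownames(ab))
    ex <- MAGExperiment(ab, md, sd, tr, presenceThreshold = 0.1)
    got <- suppressWarnings(communityWeightedMeans(ex, traits))
    expect_equal(got, oracleCWM(ab, traits, 0.1), tolerance = 1e-12)

    # scale equivariance: scaling a sample's weights leaves its CWM unchanged
    ab2 <- ab
    ab2[, 1] <- ab2[, 1] * 37.5
    ex2 <- MAGExperiment(ab2, md, sd, tr, presenceThreshold = 0.1)
    got2 <- suppressWarnings(communityWeightedMeans(ex2, traits))
    # presence set may differ since thresholding is on the scaled values;
    # compare against the oracle instead of the unscaled CWM for sample 1
    expect_equal(got2, oracleCWM(ab2, traits, 0.1), tolerance = 1e-12)

    # boundedness by contributing trait values
    for (f in 1:3) {
      present <- ab > 0.1 & !is.na(traits[, f])
      for (s in 1:20) {
        if (!any(present[, s])) next
        vals <- traits[present[, s], f]
        expect_gte(got[s, f], min(vals) - 1e-12)
        expect_lte(got[s, f], max(vals) + 1e-12)
      }
    }
  }
})

test_that("normalizedTraits corrects extensive features only and computes RI", {
  ex <- makeToyExperiment()
  rd <- SummarizedExperiment::rowData(ex)
  tr <- normalizedTraits(ex)
  raw <- normalizedTraits(ex, raw = TRUE)
  expect_equal(tr[, "genome_size"],
               normalizeFeature(raw[, "genome_size"], rd$completeness,
                                rd$contamination))
  expect_equal(tr[, "gc_content"], raw[, "gc_content"])
  expect_equal(tr[, "coding_density"], raw[, "coding_density"])
  expect_equal(unname(tr[, "redundancy_index"]),
               unname(redundancyIndex(koCounts(ex))))
  expect_true(all(tr[, "redundancy_index"] >= 1, na.rm = TRUE))
})
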