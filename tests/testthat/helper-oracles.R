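# Independent brute-force oracles used to validate the closed-form
# implementations. These deliberately use the most naive formulation
# available (loops, explicit recomputation) and share no code with R/.

oracleGlacierIndex <- function(a, d) {
  out <- numeric(length(a))
  for (i in seq_along(a)) out[i] <- sqrt(a[i]) / (sqrt(a[i]) + d[i])
  out
}

oracleNormalizeFeature <- function(v, comp, cont) {
  out <- numeric(length(v))
  for (i in seq_along(v)) out[i] <- v[i] * (1 / comp[i]) * (1 - cont[i])
  out
}

oracleRedundancyIndex <- function(counts) {
  total <- 0
  uniq <- 0
  for (c in counts) {
    total <- total + c
    if (c >= 1) uniq <- uniq + 1
  }
  total / uniq
}

# naive per-sample, per-feature double loop CWM with presence filtering
oracleCWM <- function(abundance, traits, threshold) {
  out <- matrix(NA_real_, ncol(abundance), ncol(traits))
  for (s in seq_len(ncol(abundance))) {
    for (f in seq_len(ncol(traits))) {
      num <- 0
      den <- 0
      for (i in seq_len(nrow(abundance))) {
        w <- abundance[i, s]
        v <- traits[i, f]
        if (w > threshold && !is.na(v)) {
          num <- num + w * v
          den <- den + w
        }
      }
      if (den > 0) out[s, f] <- num / den
    }
  }
  dimnames(out) <- list(colnames(abundance), colnames(traits))
  out
}

# step-down Holm by explicit sorting and cummax
oracleHolm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    running <- max(running, (m - k + 1) * p[o[k]])
    adj[o[k]] <- min(1, running)
  }
  adj
}

oracleBonferroni <- function(p) pmin(1, p * length(p))

oracleStouffer <- function(p, signs) {
  z <- numeric(length(p))
  for (i in seq_along(p)) z[i] <- signs[i] * qnorm(1 - p[i] / 2)
  Z <- sum(z) / sqrt(length(z))
  2 * pnorm(-abs(Z))
}

oracleMRE <- function(withCoefs, withoutCoefs) {
  (median(withCoefs) - median(withoutCoefs)) / median(withCoefs)
}

oracleNormalizeProfile <- function(coefs) {
  coefs / max(abs(coefs), na.rm = TRUE)
}

# O(n^3) average linkage: recompute all cluster-pair mean distances at every
# step, merging the closest pair (first-found on ties).
oracleAverageLinkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf
    bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        s <- 0
        for (a in clusters[[i]]) for (b in clusters[[j]]) s <- s + d[a, b]
        m <- s / (length(clusters[[i]]) * length(clusters[[j]]))
        if (m < best) {
          best <- m
          bi <- i
          bj <- j
        }
      }
    }
    heights[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# two-sided Fisher exact p by enumerating the hypergeometric support
oracleFisherTwoSided <- function(tab) {
  x <- tab[1, 1]
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pObs <- dhyper(x, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# small random ultrametric-ish test tree with branch lengths
randomTestTree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

# small aligned experiment used across scan/LOCO unit tests
makeToyExperiment <- function(seed = 7L, nMags = 40L, nSamples = 12L) {
  cfg <- analysisConfig(seed = seed)
  generateBenchmark(cfg, "null", nMags = nMags, nSamples = nSamples)$experiment
}

toyFixturePath <- function(file) {
  system.file("extdata", "toy", file, package = "phylodepth")
}
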