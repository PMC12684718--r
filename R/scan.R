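#' @include utils.R AllClasses.R phylo.R features.R gam-engine.R stats.R
NULL

# Deterministic within-bin permutation as a row-index vector pi such that the
# permuted matrix is A[pi, ]. Rows are exchanged only among members of the
# same bin; whole abundance vectors move jointly across all samples, so each
# MAG's spatial occupancy pattern is preserved.
binPermutationIndex <- function(bins, seed) {
  n <- length(bins)
  pi <- seq_len(n)
  withSeed(seed, {
    for (b in sort(unique(bins))) {
      members <- which(bins == b)
      if (length(members) > 1) {
        pi[members] <- members[sample.int(length(members))]
      }
    }
  })
  pi
}

#' Permute MAG abundance rows within phylogenetic bins
#'
#' For each bin independently, the MAG rows (entire abundance vectors across
#' all samples) are permuted uniformly at random among the bin's members;
#' rows outside a bin's membership are untouched. Deterministic given the
#' seed. This is the null model of the depth scan: it destroys any
#' trait-abundance matching *within* bins while preserving the per-sample
#' multiset of abundances inside every bin.
#'
#' @param abundance numeric MAG x sample matrix with MAG rownames.
#' @param bins a [BinAssignment-class] covering every MAG in the matrix.
#' @param seed integer seed.
#' @return permuted matrix with the original rownames.
#' @export
permuteWithinBins <- function(abundance, bins, seed) {
  b <- binMembership(bins)
  if (!all(rownames(abundance) %in% names(b))) {
    pd_stop("permuteWithinBins: MAG(s) missing from the bin assignment",
            "phylodepth_alignment_error")
  }
  b <- b[rownames(abundance)]
  pi <- binPermutationIndex(b, seed)
  out <- abundance[pi, , drop = FALSE]
  rownames(out) <- rownames(abundance)
  out
}

# Presence-filtered CWM machinery shared by the scan and LOCO. Permuting the
# abundance rows within bins by pi is equivalent, for CWM purposes, to
# carrying the trait of MAG pi(i) at row i, i.e. using v[inverse(pi)] against
# the unpermuted weights (exact identity, unit-tested).
cwmContext <- function(ex, trait, traits = normalizedTraits(ex)) {
  if (!trait %in% colnames(traits)) {
    pd_stop(sprintf("unknown trait '%s'", trait), "phylodepth_domain_error")
  }
  a <- abundances(ex)
  w <- a * (a > presenceThreshold(ex))
  v <- traits[rownames(ex), trait]
  ok <- !is.na(v)
  list(w = w[ok, , drop = FALSE], v = v[ok], magIds = rownames(ex)[ok],
       colW = colSums(w[ok, , drop = FALSE]))
}

cwmFromContext <- function(ctx, perm = NULL, keepRows = NULL) {
  v <- ctx$v
  if (!is.null(perm)) {
    inv <- integer(length(perm))
    inv[perm] <- seq_along(perm)
    v <- v[inv]
  }
  if (is.null(keepRows)) {
    drop(crossprod(ctx$w, v)) / ctx$colW
  } else {
    w <- ctx$w[keepRows, , drop = FALSE]
    den <- colSums(w)
    ifelse(den > 0, drop(crossprod(w, v[keepRows])) / den, NA_real_)
  }
}

scanSampleData <- function(ex, covariate) {
  cd <- SummarizedExperiment::colData(ex)
  need <- c(covariate, "latitude", "longitude")
  miss <- setdiff(need, names(cd))
  if (length(miss) > 0) {
    pd_stop(sprintf("sample metadata lacks column(s): %s",
                    paste(miss, collapse = ", ")), "phylodepth_domain_error")
  }
  data.frame(x = as.numeric(cd[[covariate]]),
             latitude = as.numeric(cd$latitude),
             longitude = as.numeric(cd$longitude),
             row.names = colnames(ex))
}

#' Abundance-permutation depth scan for one trait-covariate pair
#'
#' The core of the framework. For each relative phylogenetic height `h` on
#' the grid, tips are binned by cutting the average-linkage dendrogram of
#' cophenetic distances at `h`; abundances are then permuted within bins
#' (`nIterations` times), the community-weighted mean of the trait is
#' recomputed, and a spatially corrected GAM tests for a linear effect of the
#' covariate. Per height the scan records the mean and standard deviation of
#' the linear coefficient over iterations and the Stouffer-pooled signed
#' p-value; heights with pooled p below `alpha` are flagged significant.
#' A height whose trait-environment association survives within-bin
#' permutation carries its signal *between* bins, i.e. deeper than `h`; the
#' deepest significant height localizes the phylogenetic depth of the
#' signal ([deepestSignificantHeight()]).
#'
#' The spatial smoothing parameters are estimated once per scan on the
#' observed (unpermuted) CWM response and held fixed across permutations;
#' each permuted fit is then an exact penalized least-squares solve.
#'
#' @param ex a [MAGExperiment-class].
#' @param trait genomic feature name (column of [normalizedTraits()]).
#' @param covariate sample metadata column name.
#' @param config an [AnalysisConfig-class].
#' @return a [ScanProfile-class].
#' @export
runDepthScan <- function(ex, trait, covariate, config = analysisConfig()) {
  ctx <- cwmContext(ex, trait)
  sdat <- scanSampleData(ex, covariate)
  valid <- ctx$colW > 0 & stats::complete.cases(sdat)
  if (sum(valid) < 10) {
    pd_stop("runDepthScan: fewer than 10 usable samples", "phylodepth_domain_error")
  }
  if (any(!valid)) {
    pd_warn(sprintf("runDepthScan: dropping %d sample(s) with zero present weight or missing metadata",
                    sum(!valid)), "phylodepth_sample_drop")
  }
  y0 <- cwmFromContext(ctx)[valid]
  engine <- newGamEngine(y0, sdat$x[valid], sdat$latitude[valid],
                         sdat$longitude[valid])
  dendro <- buildDendrogram(copheneticMatrix(magTree(ex)))
  grid <- heightGrid(config@nHeights)
  nh <- length(grid)
  coefMean <- coefSd <- pooled <- rep(NA_real_, nh)
  nOk <- integer(nh)
  nbins <- integer(nh)
  binOrder <- match(ctx$magIds, dendro$labels)
  for (kI in seq_len(nh)) {
    ba <- binsAtRelativeHeight(dendro, grid[kI])
    nbins[kI] <- ba@nBins
    b <- binMembership(ba)[ctx$magIds]
    coefs <- ps <- rep(NA_real_, config@nIterations)
    for (it in seq_len(config@nIterations)) {
      pi <- binPermutationIndex(b, deriveSeed(config@seed, kI, it))
      y <- cwmFromContext(ctx, perm = pi)[valid]
      r <- engineFit(engine, y)
      coefs[it] <- r[1]
      ps[it] <- r[3]
    }
    ok <- is.finite(coefs) & is.finite(ps)
    nOk[kI] <- sum(ok)
    if (nOk[kI] < config@nIterations) {
      pd_warn(sprintf("runDepthScan: %d iteration(s) failed at height %.3f",
                      config@nIterations - nOk[kI], grid[kI]),
              "phylodepth_iteration_drop")
    }
    if (nOk[kI] <= config@nIterations / 2) next  # height dropped
    coefMean[kI] <- mean(coefs[ok])
    coefSd[kI] <- stats::sd(coefs[ok])
    pooled[kI] <- suppressWarnings(
      as.numeric(stoufferCombine(ps[ok], sign(coefs[ok]))))
  }
  profile <- new("ScanProfile", trait = trait, covariate = covariate,
                 heights = grid, coefMean = coefMean, coefSd = coefSd,
                 pooledP = pooled, normalizedCoef = rep(NA_real_, nh),
                 nBins = nbins, nOk = nOk, nIterations = config@nIterations,
                 seed = config@seed, alpha = config@alpha)
  normalizeProfile(profile)
}

#' Normalize a scan profile's coefficients
#'
#' Divides the per-height coefficient means (and their standard deviations)
#' by the maximum absolute coefficient mean over the profile, so that
#' profiles of different trait-covariate pairs share a common \[-1, 1\]
#' scale.
#'
#' @param profile a [ScanProfile-class].
#' @return the profile with `normalizedCoef` (and rescaled sd attribute
#'   folded into the data.frame view) populated.
#' @export
normalizeProfile <- function(profile) {
  cm <- profile@coefMean
  if (all(is.na(cm))) {
    pd_stop("normalizeProfile: no finite coefficient means", "phylodepth_domain_error")
  }
  m <- max(abs(cm), na.rm = TRUE)
  if (m == 0) {
    pd_warn("normalizeProfile: all coefficients zero; normalized profile set to 0",
            "phylodepth_zero_profile")
    profile@normalizedCoef <- ifelse(is.na(cm), NA_real_, 0)
  } else {
    profile@normalizedCoef <- cm / m
  }
  profile
}

#' Leave-one-cluster-out clade attribution
#'
#' Quantifies each phylogenetic cluster's contribution to the
#' community-level trait-environment association at a given height. Clusters
#' are the bins at `height`; for every cluster with at least
#' `minClusterSize` members, the per-iteration GAM coefficient is computed
#' with all MAGs ("with") and with the cluster's MAGs removed before the CWM
#' ("without"), using the same permutation seeds, and the two coefficient
#' distributions are compared by a two-sample Wilcoxon rank-sum test (a
#' signed-rank variant paired by iteration is available via the config; it
#' is far more sensitive, including to the small systematic shift that
#' removing any cluster induces through weight renormalization). The median
#' relative effect summarizes the shift:
#' `MRE = (median_with - median_without) / median_with`. P-values are
#' Holm-adjusted across clusters; a cluster is flagged significant when its
#' adjusted p falls below `alpha`.
#'
#' @param ex a [MAGExperiment-class].
#' @param trait,covariate names as in [runDepthScan()].
#' @param height relative phylogenetic height in \[0, 1\] at which clusters
#'   are formed.
#' @param config an [AnalysisConfig-class].
#' @return data.frame with one row per evaluated cluster: `cluster_id`,
#'   `n_members`, `wilcoxon_p`, `p_adjusted`, `median_relative_effect`,
#'   `median_with`, `median_without`, `significant`, and a list-column
#'   `members`.
#' @export
leaveOneClusterOut <- function(ex, trait, covariate, height,
                               config = analysisConfig()) {
  if (height < 0 || height > 1) {
    pd_stop("leaveOneClusterOut: height must lie in [0, 1]",
            "phylodepth_domain_error")
  }
  ctx <- cwmContext(ex, trait)
  sdat <- scanSampleData(ex, covariate)
  valid <- ctx$colW > 0 & stats::complete.cases(sdat)
  y0 <- cwmFromContext(ctx)[valid]
  engine <- newGamEngine(y0, sdat$x[valid], sdat$latitude[valid],
                         sdat$longitude[valid])
  dendro <- buildDendrogram(copheneticMatrix(magTree(ex)))
  ba <- binsAtRelativeHeight(dendro, height)
  b <- binMembership(ba)[ctx$magIds]
  sizes <- table(b)
  eligible <- as.integer(names(sizes)[sizes >= config@minClusterSize])
  if (length(eligible) == 0) {
    pd_stop("leaveOneClusterOut: no cluster reaches minClusterSize",
            "phylodepth_domain_error")
  }
  if (length(eligible) == 1 && sizes[as.character(eligible)] == length(b)) {
    pd_stop("leaveOneClusterOut: single cluster containing every MAG is degenerate",
            "phylodepth_domain_error")
  }
  kI <- as.integer(round(height * config@nHeights))
  perms <- lapply(seq_len(config@nIterations), function(it) {
    binPermutationIndex(b, deriveSeed(config@seed, kI, it))
  })
  coefWith <- vapply(perms, function(pi) {
    engineFit(engine, cwmFromContext(ctx, perm = pi)[valid])[1]
  }, numeric(1))
  validIdx <- which(valid)
  rows <- lapply(eligible, function(cl) {
    keep <- which(b != cl)
    if (length(keep) == 0) return(NULL)
    coefWo <- vapply(perms, function(pi) {
      y <- cwmFromContext(ctx, perm = pi, keepRows = keep)
      yv <- y[validIdx]
      if (anyNA(yv)) {
        sub <- which(!is.na(yv))
        if (length(sub) < 10) return(NA_real_)
        engineFit(engine, yv[sub], rows = sub)[1]
      } else {
        engineFit(engine, yv)[1]
      }
    }, numeric(1))
    ok <- is.finite(coefWith) & is.finite(coefWo)
    if (sum(ok) < 3) return(NULL)
    w <- coefWith[ok]
    wo <- coefWo[ok]
    # a removal that leaves every coefficient unchanged (up to float noise,
    # e.g. a zero-abundance cluster) is a no-op: p = 1, zero effect
    if (all(abs(w - wo) <= 1e-9 * pmax(abs(w), 1))) {
      p <- 1
      wo <- w
    } else if (config@pairedWilcoxon) {
      p <- suppressWarnings(stats::wilcox.test(w, wo, paired = TRUE)$p.value)
    } else {
      p <- suppressWarnings(stats::wilcox.test(w, wo)$p.value)
    }
    mw <- stats::median(w)
    mwo <- stats::median(wo)
    data.frame(cluster_id = cl, n_members = as.integer(sizes[as.character(cl)]),
               wilcoxon_p = p,
               median_with = mw, median_without = mwo,
               median_relative_effect = if (mw != 0) (mw - mwo) / mw else NA_real_,
               members = I(list(ctx$magIds[b == cl])))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    pd_stop("leaveOneClusterOut: no evaluable cluster", "phylodepth_domain_error")
  }
  adjust <- if (config@multipleTesting == "holm") holmAdjust else bonferroniAdjust
  out$p_adjusted <- adjust(out$wilcoxon_p)
  out$significant <- out$p_adjusted < config@alpha
  attr(out, "height") <- height
  out[order(-abs(out$median_relative_effect)), ]
}

#' Taxonomic enrichment of significant clusters
#'
#' For each flagged cluster and each taxon at the chosen rank, a two-sided
#' Fisher exact test on the 2x2 table (in-cluster vs not, taxon vs not) over
#' the whole MAG universe identifies taxa with disproportionately many MAGs
#' in the cluster. P-values are Holm-adjusted across all cluster-taxon
#' tests; infinite odds ratios (taxon confined to the cluster) are reported
#' as `Inf`.
#'
#' @param loco result of [leaveOneClusterOut()].
#' @param taxonomy data.frame of rank columns with MAG ids as rownames (e.g.
#'   [taxonomyTable()]).
#' @param rank rank at which to test (default `"class"`).
#' @param onlySignificant restrict to flagged clusters (default TRUE).
#' @param alpha significance level applied to adjusted p-values.
#' @return data.frame: `cluster_id`, `taxon`, `in_cluster`, `cluster_size`,
#'   `taxon_total`, `odds_ratio`, `fisher_p`, `p_adjusted`, `enriched`.
#' @export
classEnrichment <- function(loco, taxonomy, rank = "class",
                            onlySignificant = TRUE, alpha = 0.05) {
  if (!rank %in% names(taxonomy)) {
    pd_stop(sprintf("classEnrichment: rank '%s' not in taxonomy", rank),
            "phylodepth_domain_error")
  }
  use <- if (onlySignificant) loco[loco$significant, , drop = FALSE] else loco
  if (nrow(use) == 0) {
    return(data.frame(cluster_id = integer(0), taxon = character(0),
                      in_cluster = integer(0), cluster_size = integer(0),
                      taxon_total = integer(0), odds_ratio = numeric(0),
                      fisher_p = numeric(0), p_adjusted = numeric(0),
                      enriched = logical(0)))
  }
  universe <- rownames(taxonomy)
  tax <- as.character(taxonomy[[rank]])
  rows <- list()
  for (i in seq_len(nrow(use))) {
    members <- use$members[[i]]
    if (length(members) == 0) {
      pd_warn("classEnrichment: empty cluster skipped", "phylodepth_empty_cluster")
      next
    }
    inCl <- universe %in% members
    for (tx in sort(unique(tax[!is.na(tax)]))) {
      isTx <- !is.na(tax) & tax == tx
      tab <- matrix(c(sum(inCl & isTx), sum(inCl & !isTx),
                      sum(!inCl & isTx), sum(!inCl & !isTx)), 2, 2)
      ft <- stats::fisher.test(tab, alternative = "two.sided")
      rows[[length(rows) + 1]] <- data.frame(
        cluster_id = use$cluster_id[i], taxon = tx,
        in_cluster = tab[1, 1], cluster_size = sum(inCl),
        taxon_total = sum(isTx),
        odds_ratio = unname(ft$estimate), fisher_p = ft$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- holmAdjust(out$fisher_p)
  out$enriched <- out$p_adjusted < alpha & out$odds_ratio > 1
  out[order(out$p_adjusted), ]
}
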