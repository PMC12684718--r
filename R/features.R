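#' @include utils.R AllClasses.R AllGenerics.R
NULL

#' Glacier index
#'
#' Integrates glacier size and proximity into a single influence measure in
#' \[0, 1\]: `GI = sqrt(A) / (sqrt(A) + d)` with `A` the glacier surface area
#' (m^2) and `d` the distance from the sampling reach to the glacier snout
#' (m). GI is 1 at the snout of any glacier and 0 for a vanished glacier.
#'
#' @param glacierArea glacier surface area in m^2 (>= 0), vectorized.
#' @param distanceToGlacier distance to the glacier snout in m (>= 0).
#' @return numeric vector of glacier indices in \[0, 1\].
#' @examples
#' glacierIndex(1e6, 1000)  # 0.5
#' @export
glacierIndex <- function(glacierArea, distanceToGlacier) {
  if (any(glacierArea < 0, na.rm = TRUE) ||
      any(distanceToGlacier < 0, na.rm = TRUE)) {
    pd_stop("glacierIndex: arguments must be non-negative", "phylodepth_domain_error")
  }
  if (any(glacierArea == 0 & distanceToGlacier == 0, na.rm = TRUE)) {
    pd_stop("glacierIndex: undefined when both area and distance are zero",
            "phylodepth_domain_error")
  }
  s <- sqrt(glacierArea)
  s / (s + distanceToGlacier)
}

#' Quality-normalize a genomic feature value
#'
#' Corrects a per-genome extensive feature (e.g. genome size, gene count) for
#' assembly incompleteness and contamination:
#' `value_normalized = value * (1 / completeness) * (1 - contamination)`.
#' Identity when completeness is 1 and contamination 0.
#'
#' @param value raw feature value (vectorized).
#' @param completeness estimated completeness, fraction in (0, 1\].
#' @param contamination estimated contamination, fraction in \[0, 1).
#' @return normalized feature value(s).
#' @examples
#' normalizeFeature(100, 0.5, 0.1)  # 180
#' @export
normalizeFeature <- function(value, completeness, contamination) {
  if (any(completeness <= 0, na.rm = TRUE) || any(completeness > 1, na.rm = TRUE)) {
    pd_stop("normalizeFeature: completeness must lie in (0, 1]",
            "phylodepth_domain_error")
  }
  if (any(contamination < 0, na.rm = TRUE) || any(contamination >= 1, na.rm = TRUE)) {
    pd_stop("normalizeFeature: contamination must lie in [0, 1)",
            "phylodepth_domain_error")
  }
  value * (1 / completeness) * (1 - contamination)
}

#' Gene redundancy index
#'
#' Ratio of the total number of KO gene copies to the number of distinct KOs
#' in a genome. Equals 1 exactly when no KO is duplicated; larger values
#' indicate functional redundancy.
#'
#' @param koCounts named non-negative integer vector (KO id -> copy count) or
#'   a MAG x KO count matrix (one index per row).
#' @return redundancy index (>= 1), or a vector of indices for matrix input
#'   (NA for all-zero rows).
#' @examples
#' redundancyIndex(c(K1 = 2, K2 = 1))  # 1.5
#' @export
redundancyIndex <- function(koCounts) {
  if (is.matrix(koCounts)) {
    tot <- rowSums(koCounts)
    uniq <- rowSums(koCounts >= 1)
    out <- ifelse(uniq > 0, tot / uniq, NA_real_)
    names(out) <- rownames(koCounts)
    return(out)
  }
  if (length(koCounts) == 0 || all(koCounts == 0)) {
    pd_stop("redundancyIndex: undefined for an empty/all-zero KO map",
            "phylodepth_domain_error")
  }
  if (any(koCounts < 0)) {
    pd_stop("redundancyIndex: counts must be non-negative", "phylodepth_domain_error")
  }
  sum(koCounts) / sum(koCounts >= 1)
}

#' recA coverage normalization
#'
#' Divides a MAG's trimmed-mean coverage by the coverage of the single-copy
#' recA gene (K03553) in the same sample, yielding genome-equivalent relative
#' abundance.
#'
#' @param magCoverage MAG coverage(s), >= 0.
#' @param recaCoverage recA coverage of the sample, > 0.
#' @param sample optional sample id used in error messages.
#' @return recA-normalized coverage(s).
#' @export
normalizeCoverage <- function(magCoverage, recaCoverage, sample = NULL) {
  if (length(recaCoverage) != 1 || !is.finite(recaCoverage) || recaCoverage <= 0) {
    pd_stop(sprintf("normalizeCoverage: recA coverage must be positive%s",
                    if (is.null(sample)) "" else sprintf(" (sample %s)", sample)),
            "phylodepth_domain_error")
  }
  if (any(magCoverage < 0, na.rm = TRUE)) {
    pd_stop("normalizeCoverage: coverages must be non-negative",
            "phylodepth_domain_error")
  }
  magCoverage / recaCoverage
}

#' @describeIn prevalence Boolean MAG x sample presence mask: a MAG is
#'   present where its recA-normalized coverage strictly exceeds the presence
#'   threshold (ties at the threshold count as absent).
#' @export
setMethod("presenceMask", "MAGExperiment", function(x, ...) {
  abundances(x) > presenceThreshold(x)
})

#' Presence and prevalence of MAGs across samples
#'
#' Prevalence is the number of samples in which a MAG is present, presence
#' being defined as recA-normalized coverage strictly above the experiment's
#' presence threshold (default 0.1, i.e. one tenth of the community genome
#' equivalents spanned by recA).
#'
#' @param x a [MAGExperiment-class].
#' @param ... unused.
#' @return `prevalence()`: named integer vector (MAG -> number of samples);
#'   `presenceMask()`: logical MAG x sample matrix.
#' @export
setMethod("prevalence", "MAGExperiment", function(x, ...) {
  mask <- presenceMask(x)
  out <- as.integer(rowSums(mask))
  names(out) <- rownames(x)
  out
})

#' Quality-normalized MAG trait matrix
#'
#' Builds the MAG x feature matrix of genomic traits (genome size, gene
#' count, tRNA count, GC content, coding density, gene redundancy index).
#' Extensive features (those that scale with the assembled fraction of the
#' genome: `genome_size`, `gene_count`, `trna_count`) are corrected for
#' completeness and contamination via [normalizeFeature()]; intensive
#' features (ratios: GC content, coding density, redundancy index) are used
#' as-is. The redundancy index is computed from the KO copy-number matrix
#' when available, otherwise taken from a `redundancy_index` column of
#' `rowData`.
#'
#' @param x a [MAGExperiment-class].
#' @param correct feature names to quality-correct.
#' @param raw logical; return the uncorrected matrix instead.
#' @param ... unused.
#' @return numeric MAG x feature matrix.
#' @export
setMethod("normalizedTraits", "MAGExperiment",
  function(x, correct = c("genome_size", "gene_count", "trna_count"),
           raw = FALSE, ...) {
    rd <- SummarizedExperiment::rowData(x)
    feats <- intersect(MAG_FEATURES, names(rd))
    m <- vapply(feats, function(f) as.numeric(rd[[f]]), numeric(nrow(x)))
    if (!is.matrix(m)) m <- matrix(m, nrow = nrow(x))
    dimnames(m) <- list(rownames(x), feats)
    if (ncol(koCounts(x)) > 0) {
      m <- cbind(m, redundancy_index = redundancyIndex(koCounts(x)))
    } else if ("redundancy_index" %in% names(rd)) {
      m <- cbind(m, redundancy_index = as.numeric(rd$redundancy_index))
    }
    if (raw) return(m)
    for (f in intersect(correct, colnames(m))) {
      m[, f] <- normalizeFeature(m[, f], rd$completeness, rd$contamination)
    }
    m
  })

#' Community-weighted means of genomic traits
#'
#' For each sample and feature, the abundance-weighted mean of the
#' quality-normalized feature over the MAGs present in that sample:
#' `CWM_sf = sum_i w_is v_if / sum_i w_is`, where the weights `w_is` are the
#' recA-normalized coverages of present MAGs (so CWM is invariant to
#' sequencing depth) and `v_if` the normalized feature values. MAGs with a
#' missing feature value are dropped from both sums for that feature only.
#' Samples whose present MAGs carry zero total weight yield NA with a
#' warning.
#'
#' @param x a [MAGExperiment-class].
#' @param traits optional MAG x feature matrix (defaults to
#'   [normalizedTraits()]).
#' @param ... unused.
#' @return numeric sample x feature matrix.
#' @export
setMethod("communityWeightedMeans", "MAGExperiment",
  function(x, traits = normalizedTraits(x), ...) {
    a <- abundances(x)
    w <- a * (a > presenceThreshold(x))
    traits <- as.matrix(traits)[rownames(x), , drop = FALSE]
    out <- matrix(NA_real_, ncol(x), ncol(traits),
                  dimnames = list(colnames(x), colnames(traits)))
    for (f in seq_len(ncol(traits))) {
      v <- traits[, f]
      ok <- !is.na(v)
      num <- crossprod(w[ok, , drop = FALSE], v[ok])
      den <- colSums(w[ok, , drop = FALSE])
      out[, f] <- ifelse(den > 0, num / den, NA_real_)
    }
    if (anyNA(out)) {
      pd_warn(sprintf("communityWeightedMeans: %d sample x feature cell(s) undefined (zero present weight)",
                      sum(is.na(out))), "phylodepth_zero_weight")
    }
    out
  })
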