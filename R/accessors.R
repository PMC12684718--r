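#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for MAGExperiment
#'
#' `magTree()` returns the rooted phylogeny, `koCounts()` the MAG-by-KO
#' copy-number matrix, `presenceThreshold()` the coverage threshold above
#' which a MAG counts as present, `abundances()` the recA-normalized
#' abundance assay, and `taxonomyTable()` the per-MAG taxonomy columns.
#'
#' @param x a [MAGExperiment-class].
#' @name MAGExperiment-accessors
#' @aliases magTree koCounts presenceThreshold
NULL

#' @rdname MAGExperiment-accessors
#' @export
setMethod("magTree", "MAGExperiment", function(x) x@tree)

#' @rdname MAGExperiment-accessors
#' @export
setMethod("koCounts", "MAGExperiment", function(x) x@koCounts)

#' @rdname MAGExperiment-accessors
#' @export
setMethod("presenceThreshold", "MAGExperiment", function(x) x@presenceThreshold)

#' @rdname MAGExperiment-accessors
#' @export
abundances <- function(x) SummarizedExperiment::assay(x, "abundance")

#' @rdname MAGExperiment-accessors
#' @param ranks taxonomy ranks to return (defaults to domain..genus, where
#'   present in `rowData`).
#' @export
setMethod("taxonomyTable", "MAGExperiment", function(x, ranks = TAXONOMY_RANKS) {
  rd <- SummarizedExperiment::rowData(x)
  keep <- intersect(ranks, names(rd))
  out <- as.data.frame(rd[, keep, drop = FALSE])
  rownames(out) <- rownames(x)
  out
})

setMethod("show", "MAGExperiment", function(object) {
  callNextMethod()
  cat(sprintf("tree: %d tips, rooted %s\n", length(object@tree$tip.label),
              if (ape::is.ultrametric(object@tree)) "(ultrametric)" else ""))
  cat(sprintf("koCounts: %d KOs; presenceThreshold: %g\n",
              ncol(object@koCounts), object@presenceThreshold))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:",
      sprintf("%d heights x %d iterations, alpha = %g, seed = %d",
              object@nHeights, object@nIterations, object@alpha, object@seed),
      "\n")
  cat(sprintf("  minClusterSize = %d, presenceThreshold = %g, %s adjustment, %s Wilcoxon\n",
              object@minClusterSize, object@presenceThreshold,
              object@multipleTesting,
              if (object@pairedWilcoxon) "paired" else "unpaired"))
})

setMethod("show", "BinAssignment", function(object) {
  cat(sprintf("BinAssignment: %d tips in %d bins at relative height %.4g\n",
              length(object@bins), object@nBins, object@relativeHeight))
})

setMethod("show", "ScanProfile", function(object) {
  sig <- sum(object@pooledP < object@alpha, na.rm = TRUE)
  cat(sprintf("ScanProfile: %s ~ %s over %d heights (%d iterations, seed %d)\n",
              object@trait, object@covariate, length(object@heights),
              object@nIterations, object@seed))
  cat(sprintf("  %d/%d heights significant at alpha = %g; deepest: %s\n",
              sig, length(object@heights), object@alpha,
              if (sig > 0) format(deepestSignificantHeight(object)) else "none"))
})

setMethod("show", "GamFit", function(object) {
  cat(sprintf("GamFit: coef = %.6g (se %.3g, p = %.3g), BIC = %.6g, n = %d\n",
              object@coefficient, object@stdError, object@pValue,
              object@icScore, object@nObs))
})

#' Number of bins in a BinAssignment
#' @param x a [BinAssignment-class].
#' @export
nBins <- function(x) x@nBins

#' Bin membership vector of a BinAssignment
#' @param x a [BinAssignment-class].
#' @return named integer vector: tip id -> bin id.
#' @export
binMembership <- function(x) x@bins

#' Convert a ScanProfile to a data.frame
#'
#' One row per relative height with the coefficient mean/sd over permutation
#' iterations, the pooled p-value, the normalized coefficient, the number of
#' bins and the number of successful iterations.
#'
#' @param x a [ScanProfile-class].
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns height, coef_mean, coef_sd, pooled_p,
#'   normalized_coef, n_bins, n_ok_iterations, significant.
#' @exportS3Method base::as.data.frame
as.data.frame.ScanProfile <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    height = x@heights, coef_mean = x@coefMean, coef_sd = x@coefSd,
    pooled_p = x@pooledP, normalized_coef = x@normalizedCoef,
    n_bins = x@nBins, n_ok_iterations = x@nOk,
    significant = !is.na(x@pooledP) & x@pooledP < x@alpha
  )
}

#' Deepest significant height of a scan profile
#'
#' The largest relative height whose pooled p-value falls below the scan's
#' significance level; the framework reports this as the phylogenetic depth
#' at which the trait-environment signal resides.
#'
#' @param profile a [ScanProfile-class].
#' @param alpha significance level (defaults to the scan's own).
#' @return a single height, or `NA` when no height is significant.
#' @export
deepestSignificantHeight <- function(profile, alpha = profile@alpha) {
  sig <- which(!is.na(profile@pooledP) & profile@pooledP < alpha)
  if (length(sig) == 0) return(NA_real_)
  max(profile@heights[sig])
}
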