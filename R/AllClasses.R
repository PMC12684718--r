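#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata DataFrame
NULL

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Container for an aligned MAG-by-sample study
#'
#' `MAGExperiment` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds everything one study contributes: the recA-normalized MAG-by-sample
#' abundance matrix (assay `"abundance"`), per-MAG quality metrics, genomic
#' features and taxonomy (`rowData`), per-sample environmental metadata
#' (`colData`), the rooted phylogeny over the MAGs, the MAG-by-KO copy-number
#' matrix, and the presence threshold used to call a MAG present in a sample.
#'
#' Objects are normally built by [alignInputs()] (from the five input tables)
#' or by [generateBenchmark()] (synthetic data with known truth).
#'
#' @slot tree a rooted `ape::phylo` whose tip labels equal `rownames(x)`.
#' @slot koCounts integer matrix (MAG x KO) of gene copy counts; may have zero
#'   columns when no annotation table was supplied.
#' @slot presenceThreshold positive numeric; a MAG is present in a sample when
#'   its recA-normalized coverage strictly exceeds this value.
#'
#' @export
setClass("MAGExperiment",
  contains = "SummarizedExperiment",
  slots = c(tree = "ANY", koCounts = "matrix", presenceThreshold = "numeric")
)

setValidity("MAGExperiment", function(object) {
  msg <- character(0)
  if (!inherits(object@tree, "phylo")) {
    msg <- c(msg, "tree must be an ape 'phylo' object")
  } else {
    if (!setequal(object@tree$tip.label, rownames(object))) {
      msg <- c(msg, "tree tip labels must match MAG ids (rownames)")
    }
    if (!is.null(object@tree$edge.length) && any(object@tree$edge.length < 0)) {
      msg <- c(msg, "tree has negative branch lengths")
    }
  }
  a <- SummarizedExperiment::assay(object, "abundance")
  if (any(!is.finite(a)) || any(a < 0)) {
    msg <- c(msg, "abundances must be finite and non-negative")
  }
  if (nrow(object@koCounts) > 0 &&
      !identical(rownames(object@koCounts), rownames(object))) {
    msg <- c(msg, "koCounts rownames must equal MAG ids (rownames)")
  }
  if (length(object@presenceThreshold) != 1 ||
      !is.finite(object@presenceThreshold) || object@presenceThreshold < 0) {
    msg <- c(msg, "presenceThreshold must be a single non-negative number")
  }
  cd <- SummarizedExperiment::colData(object)
  if ("latitude" %in% names(cd) &&
      any(abs(stats::na.omit(cd$latitude)) > 90)) {
    msg <- c(msg, "latitude outside [-90, 90]")
  }
  if ("longitude" %in% names(cd) &&
      any(stats::na.omit(cd$longitude) > 180 | stats::na.omit(cd$longitude) <= -180)) {
    msg <- c(msg, "longitude outside (-180, 180]")
  }
  if (length(msg) > 0) msg else TRUE
})

#' Construct a MAGExperiment
#'
#' @param abundance numeric MAG x sample matrix of recA-normalized coverages
#'   with MAG ids as rownames and sample ids as colnames.
#' @param magData data.frame/DataFrame of per-MAG metadata (completeness,
#'   contamination, genomic features, taxonomy ranks), rows aligned to
#'   `rownames(abundance)`.
#' @param sampleData data.frame/DataFrame of per-sample metadata, rows aligned
#'   to `colnames(abundance)`.
#' @param tree rooted `phylo`; tips must equal the MAG ids.
#' @param koCounts optional MAG x KO copy-count matrix.
#' @param presenceThreshold presence threshold on recA-normalized coverage
#'   (default 0.1; see [prevalence()]).
#' @return A [MAGExperiment-class] object.
#' @export
MAGExperiment <- function(abundance, magData, sampleData, tree,
                          koCounts = NULL, presenceThreshold = 0.1) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    pd_stop("abundance matrix needs MAG rownames and sample colnames",
            "phylodepth_integrity_error")
  }
  if (is.null(koCounts)) {
    koCounts <- matrix(0L, nrow = nrow(abundance), ncol = 0,
                       dimnames = list(rownames(abundance), NULL))
  } else {
    koCounts <- as.matrix(koCounts)[rownames(abundance), , drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = S4Vectors::DataFrame(magData, row.names = rownames(abundance)),
    colData = S4Vectors::DataFrame(sampleData, row.names = colnames(abundance))
  )
  new("MAGExperiment", se, tree = tree, koCounts = koCounts,
      presenceThreshold = presenceThreshold)
}

#' Analysis configuration for the depth-scan framework
#'
#' Bundles the tunable parameters of the permutation framework. Defaults
#' follow the framework's reference settings: a 40-point relative-height grid,
#' 20 permutation iterations per height, significance level 0.01, presence
#' threshold 0.1 on recA-normalized coverage, and Holm adjustment for
#' cluster-level multiple testing.
#'
#' @slot nHeights number of relative phylogenetic heights scanned (grid
#'   `k/nHeights`, k = 1..nHeights).
#' @slot nIterations permutation iterations per height.
#' @slot alpha significance level for pooled p-values and adjusted tests.
#' @slot seed root RNG seed; all stochastic stages derive child seeds from it.
#' @slot minClusterSize smallest cluster evaluated by [leaveOneClusterOut()].
#' @slot presenceThreshold presence threshold for community-weighted means.
#' @slot multipleTesting `"holm"` or `"bonferroni"`.
#' @slot pairedWilcoxon use the signed-rank (paired-by-iteration) Wilcoxon
#'   variant in leave-one-cluster-out instead of the default two-sample
#'   rank-sum comparison of the coefficient distributions (default FALSE;
#'   the paired variant is hypersensitive to the systematic renormalization
#'   shift that removing any cluster induces — see the methods vignette).
#' @export
setClass("AnalysisConfig", slots = c(
  nHeights = "integer", nIterations = "integer", alpha = "numeric",
  seed = "integer", minClusterSize = "integer", presenceThreshold = "numeric",
  multipleTesting = "character", pairedWilcoxon = "logical"
))

setValidity("AnalysisConfig", function(object) {
  msg <- character(0)
  if (object@nHeights < 1L) msg <- c(msg, "nHeights must be >= 1")
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1) {
    msg <- c(msg, "alpha must lie strictly between 0 and 1")
  }
  if (object@minClusterSize < 1L) msg <- c(msg, "minClusterSize must be >= 1")
  if (object@presenceThreshold < 0) {
    msg <- c(msg, "presenceThreshold must be non-negative")
  }
  if (!object@multipleTesting %in% c("holm", "bonferroni")) {
    msg <- c(msg, "multipleTesting must be 'holm' or 'bonferroni'")
  }
  if (length(msg) > 0) msg else TRUE
})

#' @rdname AnalysisConfig-class
#' @param nHeights,nIterations,alpha,seed,minClusterSize,presenceThreshold,multipleTesting,pairedWilcoxon
#'   see slot documentation.
#' @return An `AnalysisConfig` object.
#' @export
analysisConfig <- function(nHeights = 40L, nIterations = 20L, alpha = 0.01,
                           seed = 1L, minClusterSize = 5L,
                           presenceThreshold = 0.1,
                           multipleTesting = c("holm", "bonferroni"),
                           pairedWilcoxon = FALSE) {
  new("AnalysisConfig",
      nHeights = as.integer(nHeights), nIterations = as.integer(nIterations),
      alpha = as.numeric(alpha), seed = as.integer(seed),
      minClusterSize = as.integer(minClusterSize),
      presenceThreshold = as.numeric(presenceThreshold),
      multipleTesting = match.arg(multipleTesting),
      pairedWilcoxon = isTRUE(pairedWilcoxon))
}

#' Partition of tree tips into phylogenetic bins at a relative height
#'
#' @slot relativeHeight cut height as a fraction of the maximum merge height
#'   of the average-linkage dendrogram.
#' @slot bins named integer vector mapping each tip id to a bin id.
#' @slot nBins number of distinct bins.
#' @export
setClass("BinAssignment", slots = c(
  relativeHeight = "numeric", bins = "integer", nBins = "integer"
))

setValidity("BinAssignment", function(object) {
  msg <- character(0)
  if (object@relativeHeight < 0 || object@relativeHeight > 1) {
    msg <- c(msg, "relativeHeight must lie in [0, 1]")
  }
  if (is.null(names(object@bins)) || anyNA(object@bins)) {
    msg <- c(msg, "bins must be a fully named, NA-free integer vector")
  }
  if (object@nBins != length(unique(object@bins))) {
    msg <- c(msg, "nBins must equal the number of distinct bin ids")
  }
  if (length(msg) > 0) msg else TRUE
})

#' Depth-scan profile for one trait-covariate pair
#'
#' Per relative height: mean and standard deviation of the focal linear GAM
#' coefficient over permutation iterations, the Stouffer-pooled (signed)
#' p-value, and the coefficient normalized by the maximum absolute mean over
#' the profile.
#'
#' @slot trait,covariate names of the genomic feature and the environmental
#'   covariate.
#' @slot heights the relative-height grid.
#' @slot coefMean,coefSd,pooledP,normalizedCoef per-height summaries.
#' @slot nBins number of phylogenetic bins at each height.
#' @slot nOk number of successful iterations at each height.
#' @slot nIterations,seed,alpha scan settings.
#' @export
setClass("ScanProfile", slots = c(
  trait = "character", covariate = "character", heights = "numeric",
  coefMean = "numeric", coefSd = "numeric", pooledP = "numeric",
  normalizedCoef = "numeric", nBins = "integer", nOk = "integer",
  nIterations = "integer", seed = "integer", alpha = "numeric"
))

setValidity("ScanProfile", function(object) {
  n <- length(object@heights)
  lens <- c(length(object@coefMean), length(object@coefSd),
            length(object@pooledP), length(object@normalizedCoef),
            length(object@nBins), length(object@nOk))
  if (any(lens != n)) return("all per-height slots must have equal length")
  if (any(stats::na.omit(object@coefSd) < 0)) return("coefSd must be >= 0")
  TRUE
})

#' Summary of one fitted (generalized) additive model
#'
#' Captures the focal linear coefficient (when the model has one), its Wald
#' standard error and normal-reference p-value, the log-likelihood, the
#' BIC-type information score used for Bayes-factor comparison, and the
#' number of observations.
#'
#' @slot coefficient slope of the focal linear term (NA for pure-spline fits).
#' @slot coefficientStd slope after standardizing response and covariate to
#'   unit variance (comparable across features).
#' @slot stdError Wald standard error of `coefficient`.
#' @slot pValue two-sided p under a normal reference.
#' @slot logLik,icScore,nObs fit summaries (`icScore` is the BIC).
#' @slot model the underlying `mgcv::gam` fit (may be NULL).
#' @export
setClass("GamFit", slots = c(
  coefficient = "numeric", coefficientStd = "numeric", stdError = "numeric",
  pValue = "numeric", logLik = "numeric", icScore = "numeric",
  nObs = "integer", model = "ANY"
))

setValidity("GamFit", function(object) {
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1)) {
    return("pValue must lie in [0, 1]")
  }
  if (!is.na(object@stdError) && object@stdError <= 0) {
    return("stdError must be positive")
  }
  TRUE
})
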