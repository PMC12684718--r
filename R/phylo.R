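#' @include utils.R AllClasses.R
NULL

#' Cophenetic distance matrix of a tree
#'
#' Entry (i, j) is the total branch length along the path between tips i and
#' j.
#'
#' @param tree a `phylo` with >= 2 tips and non-negative branch lengths.
#' @return symmetric numeric matrix with zero diagonal, rows/columns ordered
#'   as `tree$tip.label`.
#' @export
copheneticMatrix <- function(tree) {
  if (!inherits(tree, "phylo") || length(tree$tip.label) < 2) {
    pd_stop("copheneticMatrix: need a tree with at least 2 tips",
            "phylodepth_domain_error")
  }
  if (any(tree$edge.length < 0)) {
    pd_stop("copheneticMatrix: negative branch lengths", "phylodepth_domain_error")
  }
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Average-linkage dendrogram of cophenetic distances
#'
#' Agglomerative clustering of the tips with average linkage (UPGMA on the
#' cophenetic matrix). For an ultrametric input tree this reproduces the tree
#' itself, with merge heights equal to the cophenetic distances between the
#' merged clades.
#'
#' @param distances symmetric distance matrix from [copheneticMatrix()], or a
#'   `dist` object.
#' @return an `hclust` object (merge heights non-decreasing).
#' @export
buildDendrogram <- function(distances) {
  if (is.matrix(distances)) {
    if (any(!is.finite(distances))) {
      pd_stop("buildDendrogram: non-finite distances", "phylodepth_domain_error")
    }
    distances <- stats::as.dist(distances)
  }
  if (any(!is.finite(distances))) {
    pd_stop("buildDendrogram: non-finite distances", "phylodepth_domain_error")
  }
  stats::hclust(distances, method = "average")
}

#' Tip bins at a relative phylogenetic height
#'
#' Cuts the average-linkage dendrogram at `h` times its maximum merge height.
#' Tips whose joining height is less than or equal to the cut share a bin
#' (ties at the cut merge), so `h = 0` gives all singletons and `h = 1` one
#' bin containing every tip. Relative height is defined against the maximum
#' merge height of the dendrogram: it is the scale on which the unit interval
#' spans root to tips for the agglomeration actually used.
#'
#' @param dendrogram an `hclust` from [buildDendrogram()].
#' @param h relative height in \[0, 1\].
#' @return a [BinAssignment-class].
#' @export
binsAtRelativeHeight <- function(dendrogram, h) {
  if (!is.numeric(h) || length(h) != 1 || is.na(h) || h < 0 || h > 1) {
    pd_stop("binsAtRelativeHeight: h must lie in [0, 1]", "phylodepth_domain_error")
  }
  maxh <- max(dendrogram$height)
  # small relative tolerance so merges exactly at the cut height join
  cut <- h * maxh * (1 + 1e-10)
  memb <- stats::cutree(dendrogram, h = cut)
  new("BinAssignment", relativeHeight = h,
      bins = stats::setNames(as.integer(memb), names(memb)),
      nBins = length(unique(memb)))
}

#' Relative-height grid
#'
#' Evenly spaced relative phylogenetic heights `k / nHeights` for
#' `k = 1..nHeights`: the grid excludes 0 (the trivial all-singleton cut) and
#' includes 1 (a single bin).
#'
#' @param nHeights number of heights (>= 1).
#' @return numeric vector of length `nHeights`.
#' @export
heightGrid <- function(nHeights) {
  if (!is.numeric(nHeights) || length(nHeights) != 1 || nHeights < 1) {
    pd_stop("heightGrid: nHeights must be >= 1", "phylodepth_domain_error")
  }
  seq_len(as.integer(nHeights)) / as.integer(nHeights)
}

# tips of every internal merge of an hclust, as a list of integer vectors
mergeTipSets <- function(dendrogram) {
  m <- dendrogram$merge
  out <- vector("list", nrow(m))
  for (k in seq_len(nrow(m))) {
    pick <- function(v) if (v < 0) -v else out[[v]]
    out[[k]] <- c(pick(m[k, 1]), pick(m[k, 2]))
  }
  out
}

#' Median phylogenetic depth of a taxonomic rank
#'
#' For every taxon at the given rank represented by at least two tips, finds
#' the smallest dendrogram cluster containing all of the taxon's tips and
#' records its merge height as a fraction of the maximum merge height; the
#' median over taxa summarizes how deep that rank sits in the dendrogram
#' (the depth markers drawn on scan-profile plots).
#'
#' @param tree a `phylo`, or an `hclust` from [buildDendrogram()].
#' @param taxonomy named character vector (tip id -> taxon name at the rank),
#'   or a data.frame of rank columns with tip ids as rownames.
#' @param rank rank column to use when `taxonomy` is a data.frame.
#' @return list with `median` (relative height) and `perTaxon` (named vector
#'   of relative heights).
#' @export
medianRankHeight <- function(tree, taxonomy, rank = NULL) {
  dendrogram <- if (inherits(tree, "hclust")) tree else
    buildDendrogram(copheneticMatrix(tree))
  if (is.data.frame(taxonomy)) {
    if (is.null(rank) || !rank %in% names(taxonomy)) {
      pd_stop("medianRankHeight: 'rank' must name a taxonomy column",
              "phylodepth_domain_error")
    }
    taxonomy <- stats::setNames(as.character(taxonomy[[rank]]),
                                rownames(taxonomy))
  }
  taxonomy <- taxonomy[dendrogram$labels]
  counts <- table(taxonomy[!is.na(taxonomy) & taxonomy != "unassigned"])
  taxa <- names(counts)[counts >= 2]
  if (length(taxa) == 0) {
    pd_stop("medianRankHeight: no taxon at this rank has >= 2 tips",
            "phylodepth_domain_error")
  }
  sets <- mergeTipSets(dendrogram)
  maxh <- max(dendrogram$height)
  per <- vapply(taxa, function(tx) {
    tipIdx <- which(!is.na(taxonomy) & taxonomy == tx)
    for (k in seq_along(sets)) {
      if (all(tipIdx %in% sets[[k]])) return(dendrogram$height[k] / maxh)
    }
    NA_real_
  }, numeric(1))
  list(median = stats::median(per, na.rm = TRUE), perTaxon = per)
}

#' Median depths of all standard ranks
#'
#' Convenience wrapper over [medianRankHeight()] for the domain..genus ranks
#' present in a [MAGExperiment-class]'s taxonomy.
#'
#' @param ex a [MAGExperiment-class].
#' @param ranks ranks to evaluate.
#' @return data.frame with columns `rank`, `median_height`, `n_taxa`.
#' @export
rankDepthTable <- function(ex, ranks = TAXONOMY_RANKS) {
  tax <- taxonomyTable(ex)
  dendro <- buildDendrogram(copheneticMatrix(magTree(ex)))
  ranks <- intersect(ranks, names(tax))
  rows <- lapply(ranks, function(r) {
    res <- tryCatch(medianRankHeight(dendro, tax, r), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(rank = r, median_height = res$median,
               n_taxa = sum(!is.na(res$perTaxon)))
  })
  do.call(rbind, rows)
}
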