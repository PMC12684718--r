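#' @include utils.R stats.R
NULL

#' Log-transform a KO copy-number matrix
#'
#' Adds half of the minimal non-zero value of the whole matrix as a
#' pseudocount (so zeroes are representable) and takes natural logs.
#'
#' @param koMatrix non-negative MAG x KO count matrix with at least one
#'   non-zero entry.
#' @return real matrix `log(count + pseudocount)`, with the pseudocount as
#'   attribute `"pseudocount"`.
#' @export
koLogTransform <- function(koMatrix) {
  koMatrix <- as.matrix(koMatrix)
  if (any(koMatrix < 0, na.rm = TRUE)) {
    pd_stop("koLogTransform: counts must be non-negative", "phylodepth_domain_error")
  }
  nz <- koMatrix[koMatrix > 0]
  if (length(nz) == 0) {
    pd_stop("koLogTransform: all-zero matrix", "phylodepth_domain_error")
  }
  pc <- min(nz) / 2
  out <- log(koMatrix + pc)
  attr(out, "pseudocount") <- pc
  out
}

#' Per-KO copy-number redundancy test
#'
#' Tests, for every KO, whether the number of gene copies is higher in the
#' in-clade MAGs than in all other MAGs: a two-sided Wilcoxon rank-sum test
#' on the log-transformed copy numbers, Bonferroni-adjusted over all tested
#' KOs. A KO is significant when its adjusted p falls below `alpha` *and*
#' the in-minus-out mean log difference is positive (higher redundancy in
#' the clade).
#'
#' @param koMatrix MAG x KO count matrix.
#' @param membership logical vector (or vector of MAG ids) marking in-clade
#'   MAGs; both groups need >= 3 MAGs.
#' @param alpha significance level on adjusted p-values (default 0.01).
#' @return data.frame: `ko_id`, `mean_log_difference`, `p_raw`, `p_adjusted`,
#'   `significant`, ordered by adjusted p.
#' @export
koRedundancyTest <- function(koMatrix, membership, alpha = 0.01) {
  koMatrix <- as.matrix(koMatrix)
  if (!is.logical(membership)) {
    membership <- rownames(koMatrix) %in% membership
  }
  if (length(membership) != nrow(koMatrix)) {
    pd_stop("koRedundancyTest: membership length must match MAG rows",
            "phylodepth_alignment_error")
  }
  if (sum(membership) < 3 || sum(!membership) < 3) {
    pd_stop("koRedundancyTest: both groups need >= 3 MAGs", "phylodepth_domain_error")
  }
  lm_ <- koLogTransform(koMatrix)
  inM <- lm_[membership, , drop = FALSE]
  outM <- lm_[!membership, , drop = FALSE]
  res <- vapply(seq_len(ncol(lm_)), function(j) {
    a <- inM[, j]
    b <- outM[, j]
    d <- mean(a) - mean(b)
    if (max(lm_[, j]) == min(lm_[, j])) return(c(0, 1))  # constant column
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    c(d, p)
  }, numeric(2))
  out <- data.frame(ko_id = colnames(koMatrix),
                    mean_log_difference = res[1, ],
                    p_raw = res[2, ],
                    p_adjusted = bonferroniAdjust(res[2, ]))
  out$significant <- out$p_adjusted < alpha & out$mean_log_difference > 0
  out[order(out$p_adjusted, -out$mean_log_difference), ]
}

# deterministic stratified fold assignment for cross-validation
stratifiedFolds <- function(y, nfolds, seed) {
  fold <- integer(length(y))
  withSeed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
  })
  fold
}

#' LASSO selection of clade-marker KOs
#'
#' L1-penalized logistic regression of clade membership on the
#' log-transformed, per-KO standardized copy-number matrix. The penalty is
#' chosen by stratified 10-fold cross-validation with the one-standard-error
#' rule (conservative selection); KOs with non-zero coefficients at that
#' penalty are returned with their signs. Deterministic given the seed.
#'
#' @param koMatrix MAG x KO count matrix (>= 2 KOs).
#' @param membership logical vector or vector of member MAG ids; both
#'   classes need >= 10 MAGs.
#' @param seed integer seed for the CV fold assignment.
#' @param nfolds number of CV folds (default 10).
#' @return data.frame `ko_id`, `coefficient`, `separating` (TRUE when the KO
#'   alone splits the two classes perfectly), ordered by |coefficient|.
#' @export
lassoCladeMarkers <- function(koMatrix, membership, seed = 1L, nfolds = 10L) {
  koMatrix <- as.matrix(koMatrix)
  if (!is.logical(membership)) {
    membership <- rownames(koMatrix) %in% membership
  }
  if (sum(membership) < 10 || sum(!membership) < 10) {
    pd_stop("lassoCladeMarkers: both classes need >= 10 MAGs",
            "phylodepth_domain_error")
  }
  if (ncol(koMatrix) < 2) {
    pd_stop("lassoCladeMarkers: need >= 2 KOs", "phylodepth_domain_error")
  }
  lx <- koLogTransform(koMatrix)
  sds <- apply(lx, 2, stats::sd)
  keep <- which(sds > 0)  # zero-variance KOs can never be selected
  x <- scale(lx[, keep, drop = FALSE])
  y <- as.integer(membership)
  foldid <- stratifiedFolds(y, nfolds, seed)
  cv <- withSeed(seed, glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                                         foldid = foldid, standardize = FALSE))
  co <- as.matrix(stats::coef(cv, s = "lambda.1se"))[-1, 1]
  sel <- which(co != 0)
  if (length(sel) == 0) {
    return(data.frame(ko_id = character(0), coefficient = numeric(0),
                      separating = logical(0)))
  }
  ids <- colnames(x)[sel]
  separating <- vapply(ids, function(ko) {
    a <- lx[membership, ko]
    b <- lx[!membership, ko]
    min(a) > max(b) || max(a) < min(b)
  }, logical(1))
  out <- data.frame(ko_id = ids, coefficient = unname(co[sel]),
                    separating = unname(separating))
  out[order(-abs(out$coefficient)), ]
}

#' Intersection of named KO sets
#'
#' KO ids present in every set, sorted lexicographically.
#'
#' @param sets list of >= 2 character vectors of KO ids.
#' @return sorted character vector.
#' @export
koSetIntersection <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) {
    pd_stop("koSetIntersection: need at least two sets", "phylodepth_domain_error")
  }
  sort(Reduce(intersect, lapply(sets, unique)))
}
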