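#' @include utils.R AllClasses.R
NULL

checkPValues <- function(p, what) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    pd_stop(sprintf("%s: p-values must lie in [0, 1]", what),
            "phylodepth_domain_error")
  }
  invisible(TRUE)
}

#' Holm step-down adjustment
#'
#' Family-wise error controlling step-down adjustment with monotonicity
#' enforcement and capping at 1; input order preserved.
#'
#' @param pValues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order.
#' @export
holmAdjust <- function(pValues) {
  checkPValues(pValues, "holmAdjust")
  stats::p.adjust(pValues, method = "holm")
}

#' Bonferroni adjustment
#'
#' Single-step adjustment `p * m`, capped at 1.
#'
#' @param pValues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order.
#' @export
bonferroniAdjust <- function(pValues) {
  checkPValues(pValues, "bonferroniAdjust")
  stats::p.adjust(pValues, method = "bonferroni")
}

#' Stouffer combination of signed two-sided p-values
#'
#' Converts each two-sided p-value and the sign of its coefficient to a
#' signed standard-normal score `z_i = sign_i * qnorm(1 - p_i / 2)`, pools
#' `Z = sum(z_i) / sqrt(k)`, and returns the two-sided p of `Z`. Signing the
#' scores makes direction-inconsistent iterations cancel rather than
#' reinforce.
#'
#' @param pValues k two-sided p-values in (0, 1); values of exactly 0 or 1
#'   are clipped to the open interval with a warning.
#' @param signs coefficient signs (+1/-1), recycled if length 1.
#' @return combined two-sided p-value, with the pooled z-score as attribute
#'   `"z"`.
#' @examples
#' stoufferCombine(c(0.05, 0.05), c(1, 1))   # 0.00557
#' stoufferCombine(c(0.05, 0.05), c(1, -1))  # 1 (cancellation)
#' @export
stoufferCombine <- function(pValues, signs = rep(1, length(pValues))) {
  if (length(pValues) < 1) {
    pd_stop("stoufferCombine: need at least one p-value", "phylodepth_domain_error")
  }
  if (length(signs) == 1) signs <- rep(signs, length(pValues))
  if (length(signs) != length(pValues)) {
    pd_stop("stoufferCombine: signs must match p-values in length",
            "phylodepth_domain_error")
  }
  checkPValues(pValues, "stoufferCombine")
  clip <- pValues <= 0 | pValues >= 1
  if (any(clip)) {
    pd_warn("stoufferCombine: p-values of exactly 0/1 clipped to the open interval",
            "phylodepth_p_clip")
    pValues <- pmin(pmax(pValues, 1e-300), 1 - 1e-16)
  }
  # upper-tail quantile: numerically exact for very small p (where 1 - p/2
  # would round to 1)
  z <- sign(signs) * stats::qnorm(pValues / 2, lower.tail = FALSE)
  Z <- sum(z) / sqrt(length(z))
  out <- 2 * stats::pnorm(-abs(Z))
  attr(out, "z") <- Z
  out
}

#' BIC-approximate Bayes factor between two additive models
#'
#' `BF = exp((BIC_shared - BIC_grouped) / 2)`: the evidence in favor of the
#' grouped model under the BIC approximation to the marginal likelihood.
#' Values above 3 are conventionally read as support for the grouped model.
#'
#' @param fitShared,fitGrouped [GamFit-class] objects fitted to the same
#'   observations.
#' @return Bayes factor (> 0) with attribute `"supportsGrouped"`.
#' @export
bicBayesFactor <- function(fitShared, fitGrouped) {
  if (fitShared@nObs != fitGrouped@nObs) {
    pd_stop("bicBayesFactor: models were fitted to different numbers of observations",
            "phylodepth_comparison_error")
  }
  bf <- exp((fitShared@icScore - fitGrouped@icScore) / 2)
  attr(bf, "supportsGrouped") <- bf > 3
  bf
}

# shared extraction of the focal linear term from an mgcv fit
gamFitFromModel <- function(fit, term, sdCov = NA_real_, sdResp = NA_real_,
                            keepModel = TRUE) {
  est <- NA_real_
  se <- NA_real_
  p <- NA_real_
  std <- NA_real_
  if (!is.na(term) && term %in% names(stats::coef(fit))) {
    est <- unname(stats::coef(fit)[term])
    se <- sqrt(stats::vcov(fit)[term, term])
    z <- est / se
    if (is.finite(z)) {
      p <- 2 * stats::pnorm(-abs(z))
    } else {
      # degenerate fit (e.g. constant response): no evidence against zero
      se <- NA_real_
      p <- 1
    }
    if (is.finite(sdCov) && is.finite(sdResp) && sdResp > 0) {
      std <- est * sdCov / sdResp
    }
  }
  new("GamFit", coefficient = est, coefficientStd = std, stdError = se,
      pValue = p, logLik = as.numeric(stats::logLik(fit)),
      icScore = stats::BIC(fit), nObs = as.integer(stats::nobs(fit)),
      model = if (keepModel) fit else NULL)
}

#' Spatially corrected additive model for one trait-covariate pair
#'
#' Fits `response ~ intercept + beta * covariate + f(latitude, longitude)`
#' where `f` is a penalized spline-on-the-sphere smooth (great-circle
#' geometry, basis `bs = "sos"`), and extracts the focal linear coefficient
#' `beta` with its Wald standard error and two-sided normal-reference
#' p-value. The smoothing penalty is selected by restricted marginal
#' likelihood by default.
#'
#' @param response numeric response per sample (e.g. a CWM feature).
#' @param covariate numeric environmental covariate per sample.
#' @param latitude,longitude sample coordinates in degrees.
#' @param k spatial basis dimension; `NULL` (automatic) starts at
#'   `min(n / 4, 50)` basis functions, penalty-selected.
#' @param method mgcv smoothing-parameter criterion (`"REML"` default, or
#'   `"GCV.Cp"`).
#' @param sp optional fixed smoothing parameter(s), bypassing selection.
#' @param keepModel keep the mgcv object in the result (set FALSE in tight
#'   loops).
#' @return a [GamFit-class].
#' @export
fitTraitGam <- function(response, covariate, latitude, longitude, k = NULL,
                        method = "REML", sp = NULL, keepModel = TRUE) {
  dat <- data.frame(y = response, x = covariate,
                    latitude = latitude, longitude = longitude)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 10) {
    pd_stop(sprintf("fitTraitGam: only %d complete cases (need >= 10)", n),
            "phylodepth_domain_error")
  }
  if (stats::var(dat$x) == 0) {
    pd_stop("fitTraitGam: covariate is constant (degenerate design)",
            "phylodepth_domain_error")
  }
  if (stats::sd(dat$y) == 0) {
    # constant response: the zero model, with no evidence against beta = 0
    return(new("GamFit", coefficient = 0, coefficientStd = 0,
               stdError = NA_real_, pValue = 1, logLik = NA_real_,
               icScore = NA_real_, nObs = as.integer(n), model = NULL))
  }
  if (is.null(k)) k <- max(5L, min(50L, floor(n / 4)))
  if (k + 3 > n) {
    kNew <- max(5L, n - 5L)
    pd_warn(sprintf("fitTraitGam: basis dimension reduced from %d to %d for n = %d",
                    k, kNew, n), "phylodepth_basis_reduction")
    k <- kNew
  }
  fit <- mgcv::gam(y ~ x + s(latitude, longitude, bs = "sos", k = k),
                   data = dat, method = method, sp = sp)
  gamFitFromModel(fit, "x", sdCov = stats::sd(dat$x), sdResp = stats::sd(dat$y),
                  keepModel = keepModel)
}

#' Ecological-success additive model, optionally with group-specific splines
#'
#' Fits a MAG-level genomic feature against an ecological-success covariate
#' (prevalence or mean relative abundance) with a shrinkage spline
#' (`bs = "ts"`, basis dimension 5), either one spline for all MAGs or one
#' spline per group (a `by`-variable spline plus a group intercept). The
#' maximum-likelihood criterion is used so that BIC-based comparison of the
#' two fixed-effect structures via [bicBayesFactor()] is valid.
#'
#' @param response MAG-level feature vector.
#' @param covariate success covariate (prevalence or mean abundance).
#' @param group logical or factor group membership (e.g. focal class vs
#'   rest).
#' @param grouped fit one spline per group?
#' @param k spline basis dimension (default 5).
#' @return a [GamFit-class] (its `coefficient` slot is NA: there is no focal
#'   linear term; the fit carries `icScore` for model comparison).
#' @export
fitSuccessGam <- function(response, covariate, group, grouped = FALSE, k = 5) {
  dat <- data.frame(y = response, x = covariate, g = factor(group))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 20) {
    pd_stop(sprintf("fitSuccessGam: only %d complete cases (need >= 20)", n),
            "phylodepth_domain_error")
  }
  if (grouped) {
    sizes <- table(dat$g)
    if (any(sizes == 0) || nlevels(dat$g) < 2) {
      pd_stop("fitSuccessGam: both groups must be non-empty when grouped",
              "phylodepth_domain_error")
    }
    if (any(sizes < 3)) {
      pd_stop(sprintf("fitSuccessGam: smallest group has %d member(s) (need >= 3)",
                      min(sizes)), "phylodepth_domain_error")
    }
    if (any(sizes < k)) {
      pd_warn(sprintf("fitSuccessGam: group of size %d below basis dimension %d; basis reduced",
                      min(sizes), k), "phylodepth_basis_reduction")
      k <- max(3L, min(sizes) - 1L)
    }
    fit <- mgcv::gam(y ~ g + s(x, k = k, bs = "ts", by = g), data = dat,
                     method = "ML")
  } else {
    fit <- mgcv::gam(y ~ s(x, k = k, bs = "ts"), data = dat, method = "ML")
  }
  gamFitFromModel(fit, NA_character_)
}
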