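#' @include AllClasses.R
NULL

#' @export
setGeneric("magTree", function(x) standardGeneric("magTree"))

#' @export
setGeneric("koCounts", function(x) standardGeneric("koCounts"))

#' @export
setGeneric("presenceThreshold", function(x) standardGeneric("presenceThreshold"))

#' @export
setGeneric("presenceMask", function(x, ...) standardGeneric("presenceMask"))

#' @export
setGeneric("prevalence", function(x, ...) standardGeneric("prevalence"))

#' @export
setGeneric("normalizedTraits", function(x, ...) standardGeneric("normalizedTraits"))

#' @export
setGeneric("communityWeightedMeans",
           function(x, ...) standardGeneric("communityWeightedMeans"))

#' @export
setGeneric("taxonomyTable", function(x, ...) standardGeneric("taxonomyTable"))
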