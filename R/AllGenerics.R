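#' @include AllClasses.R
NULL

#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @export
setGeneric("structures", function(x) standardGeneric("structures"))

#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
setGeneric("nSkipped", function(x) standardGeneric("nSkipped"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @export
setGeneric("induction", function(x, ...) standardGeneric("induction"))

#' @export
setGeneric("isActive", function(x) standardGeneric("isActive"))

#' @export
setGeneric("profileIds", function(x) standardGeneric("profileIds"))

#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @export
setGeneric("clusterNames", function(x) standardGeneric("clusterNames"))

#' @export
setGeneric("subprofiles", function(x) standardGeneric("subprofiles"))

#' @export
setGeneric("subprofileValues", function(x) standardGeneric("subprofileValues"))

#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))

#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @export
setGeneric("fragmentContributions", function(x) standardGeneric("fragmentContributions"))

#' @export
setGeneric("mitoValues", function(x) standardGeneric("mitoValues"))
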