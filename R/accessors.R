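#' @include AllGenerics.R
NULL

#' Accessors for CompoundSet
#'
#' @param x A \linkS4class{CompoundSet}.
#' @return \code{compoundIds}, \code{structures}, \code{classLabels} return
#'   character vectors (one element per record); \code{nSkipped} the number
#'   of unparseable input rows; \code{provenance} a description of origin.
#'
#' @aliases compoundIds structures classLabels nSkipped provenance
#' @name CompoundSet-accessors
NULL

#' @rdname CompoundSet-accessors
#' @export
setMethod("compoundIds", "CompoundSet", function(x) x@records$compound_id)

#' @rdname CompoundSet-accessors
#' @export
setMethod("structures", "CompoundSet", function(x) {
  structure(x@records$structure, names = x@records$compound_id)
})

#' @rdname CompoundSet-accessors
#' @export
setMethod("classLabels", "CompoundSet", function(x) {
  structure(x@records$class_label, names = x@records$compound_id)
})

#' @rdname CompoundSet-accessors
#' @export
setMethod("nSkipped", "CompoundSet", function(x) x@nSkipped)

#' @rdname CompoundSet-accessors
#' @export
setMethod("provenance", "CompoundSet", function(x) x@provenance)

#' @rdname CompoundSet-accessors
#' @export
setMethod("length", "CompoundSet", function(x) nrow(x@records))

#' @rdname CompoundSet-accessors
#' @param i Index (numeric, logical or compound id character).
#' @param j,drop,... Ignored; present for generic compatibility.
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@records$compound_id)
  initialize(x, records = x@records[i, , drop = FALSE])
})

setMethod("show", "CompoundSet", function(object) {
  cat(sprintf(
    "CompoundSet with %d compounds (%d input rows skipped)\n",
    length(object), object@nSkipped
  ))
  tab <- table(object@records$class_label)
  cat("labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat("provenance:", object@provenance, "\n")
})

#' Accessors for MorphProfileSet
#'
#' @param x A \linkS4class{MorphProfileSet}.
#' @param ... Ignored.
#' @return \code{zMatrix} returns the features x profiles z-score matrix;
#'   \code{induction} the per-profile induction percentages; \code{isActive}
#'   the activity flags; \code{profileIds} the profile (column) ids;
#'   \code{featureIds} the feature (row) ids.
#'
#' @aliases zMatrix profileIds isActive featureIds
#' @name MorphProfileSet-accessors
NULL

#' @rdname MorphProfileSet-accessors
#' @export
setMethod("zMatrix", "MorphProfileSet", function(x) assay(x, "z"))

#' @rdname MorphProfileSet-accessors
#' @export
setMethod("induction", "MorphProfileSet", function(x, ...) {
  structure(colData(x)$induction, names = colnames(x))
})

#' @rdname MorphProfileSet-accessors
#' @export
setMethod("isActive", "MorphProfileSet", function(x) {
  structure(colData(x)$active, names = colnames(x))
})

#' @rdname MorphProfileSet-accessors
#' @export
setMethod("profileIds", "MorphProfileSet", function(x) colnames(x))

#' @rdname MorphProfileSet-accessors
#' @export
setMethod("featureIds", "MorphProfileSet", function(x) rownames(x))

#' @rdname MorphProfileSet-accessors
#' @export
setMethod("featureIds", "PlateData", function(x) rownames(x))

setMethod("show", "MorphProfileSet", function(object) {
  callNextMethod()
  act <- sum(colData(object)$active)
  cat(sprintf(
    "profiles: %d (%d active); usable features: %d of %d\n",
    ncol(object), act, sum(!rowData(object)$excluded), nrow(object)
  ))
})

#' Accessors for Subprofile and ClusterModel
#'
#' @param x A \linkS4class{Subprofile} or \linkS4class{ClusterModel}.
#' @return \code{clusterNames} returns the cluster name(s);
#'   \code{featureIds} the selected feature ids; \code{subprofileValues} the
#'   named median z values; \code{subprofiles} the list of
#'   \linkS4class{Subprofile} objects in a model.
#'
#' @aliases clusterNames subprofiles subprofileValues
#' @name cluster-accessors
NULL

#' @rdname cluster-accessors
#' @export
setMethod("clusterNames", "Subprofile", function(x) x@clusterName)

#' @rdname cluster-accessors
#' @export
setMethod("featureIds", "Subprofile", function(x) x@featureIds)

#' @rdname cluster-accessors
#' @export
setMethod("subprofileValues", "Subprofile", function(x) x@values)

#' @rdname cluster-accessors
#' @export
setMethod("clusterNames", "ClusterModel", function(x) {
  vapply(x@subprofiles, function(s) s@clusterName, character(1))
})

#' @rdname cluster-accessors
#' @export
setMethod("subprofiles", "ClusterModel", function(x) {
  structure(x@subprofiles, names = clusterNames(x))
})

#' @rdname cluster-accessors
#' @export
setMethod("length", "ClusterModel", function(x) length(x@subprofiles))

setMethod("show", "Subprofile", function(object) {
  cat(sprintf(
    "Subprofile '%s': %d features from %d members (consistency %.2f, min |median z| %.2f)\n",
    object@clusterName, length(object@featureIds), length(object@memberIds),
    object@consistency, object@minAbsMedian
  ))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel with %d clusters:\n", length(object)))
  for (s in object@subprofiles) {
    cat(sprintf(
      "  %-12s %4d features, %d members\n",
      s@clusterName, length(s@featureIds), length(s@memberIds)
    ))
  }
})

#' Accessors for Embedding
#'
#' @param x An \linkS4class{Embedding}.
#' @return \code{embeddingCoords} returns the coordinate matrix;
#'   \code{explainedVariance} the per-component explained variance in
#'   percent (PCA only).
#'
#' @aliases embeddingCoords explainedVariance
#' @name Embedding-accessors
NULL

#' @rdname Embedding-accessors
#' @export
setMethod("embeddingCoords", "Embedding", function(x) x@coordinates)

#' @rdname Embedding-accessors
#' @export
setMethod("explainedVariance", "Embedding", function(x) x@explainedVariance)

setMethod("show", "Embedding", function(object) {
  cat(sprintf(
    "%s embedding: %d rows x %d dims\n",
    toupper(object@method), nrow(object@coordinates), ncol(object@coordinates)
  ))
  if (length(object@explainedVariance)) {
    cat(
      "explained variance (%):",
      paste(sprintf("%.1f", object@explainedVariance), collapse = ", "), "\n"
    )
  }
})

#' Accessor for MitoParams
#'
#' @param x A \linkS4class{MitoParams}.
#' @return Named numeric vector with basal, atp_linked, proton_leak,
#'   maximal, spare_capacity and non_mitochondrial respiration.
#'
#' @aliases mitoValues
#' @export
setMethod("mitoValues", "MitoParams", function(x) {
  vapply(slotNames(x), function(s) slot(x, s), numeric(1))
})

setMethod("show", "MitoParams", function(object) {
  v <- mitoValues(object)
  cat("MitoStress respiration parameters (OCR units):\n")
  for (nm in names(v)) cat(sprintf("  %-18s %8.3f\n", nm, v[[nm]]))
})

#' Fragment contributions of a trained NP-likeness table
#'
#' @param x A \linkS4class{FragmentScoreTable}.
#' @return Named numeric vector of per-fragment log-odds contributions.
#' @aliases fragmentContributions
#' @export
setMethod("fragmentContributions", "FragmentScoreTable", function(x) x@contributions)

setMethod("show", "FragmentScoreTable", function(object) {
  cat(sprintf(
    "FragmentScoreTable: %d fragments (radius %d), trained on %d NP vs %d synthetic molecules\n",
    length(object@contributions), object@radius, object@nNp, object@nSyn
  ))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat(sprintf(
    "AnalysisConfig: |z| >= %.2f counts as altered; active at induction >= %.1f%%; similar at BioSim >= %.1f%%; robust scale %.4f\n",
    object@thetaZ, object@activityThreshold, object@similarityThreshold,
    object@robustScale
  ))
})

setMethod("show", "OCRTrace", function(object) {
  cat(sprintf(
    "OCRTrace: %d timepoints over %.1f min, %d injections (%s)%s\n",
    length(object@time), diff(range(object@time)), nrow(object@injections),
    paste(object@injections$label, collapse = ", "),
    if (length(object@ecar)) ", with ECAR" else ""
  ))
})
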