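#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @import SummarizedExperiment
NULL

#' CompoundSet: a labeled, canonicalized compound collection
#'
#' Holds one row per molecule with a unique identifier, a canonical SMILES
#' structure and a class label (e.g., \code{"PNP"}, \code{"MIA"},
#' \code{"drug"}). Structures are canonicalized at construction; the largest
#' covalent fragment is kept (counterions are stripped) and stereochemistry is
#' retained, mirroring common screening-collection preprocessing.
#'
#' @slot records A \link[S4Vectors]{DataFrame} with columns
#'   \code{compound_id}, \code{structure} (canonical SMILES),
#'   \code{class_label} and \code{name}.
#' @slot provenance Character scalar describing where the set came from
#'   (file path or generator seed).
#' @slot nSkipped Number of input rows dropped because they failed to parse.
#' @slot skippedMessages One diagnostic string per skipped row.
#'
#' @aliases CompoundSet-class
#' @exportClass CompoundSet
setClass(
  "CompoundSet",
  slots = c(
    records = "DataFrame",
    provenance = "character",
    nSkipped = "integer",
    skippedMessages = "character"
  )
)

setValidity("CompoundSet", function(object) {
  req <- c("compound_id", "structure", "class_label", "name")
  msgs <- character()
  if (!all(req %in% colnames(object@records))) {
    msgs <- c(msgs, paste(
      "records must have columns:", paste(req, collapse = ", ")
    ))
  } else {
    ids <- object@records$compound_id
    if (anyDuplicated(ids)) {
      msgs <- c(msgs, paste(
        "duplicate compound ids:",
        paste(unique(ids[duplicated(ids)]), collapse = ", ")
      ))
    }
    if (any(!nzchar(object@records$structure))) {
      msgs <- c(msgs, "empty structure strings are not allowed")
    }
  }
  if (length(object@provenance) != 1) {
    msgs <- c(msgs, "provenance must be a single string")
  }
  if (length(msgs)) msgs else TRUE
})

#' PlateData: a plate-level morphological feature table
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with one assay
#' \code{"features"} (features x wells) and well metadata in \code{colData}:
#' \code{plate_id}, \code{well_id}, \code{compound_id},
#' \code{concentration_um} and \code{is_control}. The on-disk representation
#' (see \code{\link{readFeatureTable}}) is transposed: one CSV row per well.
#'
#' @aliases PlateData-class
#' @exportClass PlateData
setClass("PlateData", contains = "SummarizedExperiment")

setValidity("PlateData", function(object) {
  msgs <- character()
  if (!"features" %in% assayNames(object)) {
    return("PlateData requires an assay named 'features'")
  }
  a <- assay(object, "features")
  if (!is.numeric(a)) msgs <- c(msgs, "feature assay must be numeric")
  meta <- c("plate_id", "well_id", "compound_id", "concentration_um", "is_control")
  miss <- setdiff(meta, colnames(colData(object)))
  if (length(miss)) {
    msgs <- c(msgs, paste("missing well metadata columns:", paste(miss, collapse = ", ")))
  } else {
    cd <- colData(object)
    trt <- !cd$is_control
    noId <- trt & (is.na(cd$compound_id) | !nzchar(cd$compound_id))
    if (any(noId)) {
      msgs <- c(msgs, "every well must be a control or carry a compound_id")
    }
    conc <- cd$concentration_um[trt]
    if (any(!is.na(conc) & conc <= 0)) {
      msgs <- c(msgs, "treatment concentrations must be positive")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' MorphProfileSet: per-treatment z-score profiles
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with assay \code{"z"}
#' (features x profiles). Each column is one (compound, concentration)
#' treatment, standardized against the DMSO controls of its source plate.
#' \code{colData} carries \code{compound_id}, \code{concentration_um},
#' \code{induction} (percent of significantly altered features) and
#' \code{active}. \code{rowData} flags features that were \code{excluded}
#' from the induction denominator (constant control column) and features
#' whose zero control MAD was \code{mad_substituted}.
#'
#' @aliases MorphProfileSet-class
#' @exportClass MorphProfileSet
setClass("MorphProfileSet", contains = "SummarizedExperiment")

setValidity("MorphProfileSet", function(object) {
  msgs <- character()
  if (!"z" %in% assayNames(object)) {
    return("MorphProfileSet requires an assay named 'z'")
  }
  need <- c("compound_id", "concentration_um", "induction", "active")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss)) {
    msgs <- c(msgs, paste("missing profile metadata:", paste(miss, collapse = ", ")))
  } else {
    ind <- colData(object)$induction
    if (any(ind < 0 | ind > 100, na.rm = TRUE)) {
      msgs <- c(msgs, "induction must lie in [0, 100]")
    }
  }
  rneed <- c("excluded", "mad_substituted")
  if (!all(rneed %in% colnames(rowData(object)))) {
    msgs <- c(msgs, "rowData must flag 'excluded' and 'mad_substituted' features")
  }
  if (length(msgs)) msgs else TRUE
})

#' AnalysisConfig: thresholds of the profile analytics
#'
#' Central container for the tunable cutoffs: \code{thetaZ} (a feature counts
#' as significantly altered when |z| >= thetaZ; default 3), the activity
#' threshold on induction (percent; compounds are active at >= 5),
#' the biosimilarity threshold (percent; profiles are similar at >= 75) and
#' the robust scale constant (1.4826, making the MAD a consistent estimator
#' of a Gaussian standard deviation).
#'
#' @slot thetaZ Numeric z-score cutoff for a significantly altered feature.
#' @slot activityThreshold Percent induction at and above which a profile is
#'   flagged active.
#' @slot similarityThreshold Percent biosimilarity at and above which two
#'   profiles are called similar.
#' @slot robustScale Multiplier applied to the control MAD.
#'
#' @aliases AnalysisConfig-class
#' @exportClass AnalysisConfig
setClass(
  "AnalysisConfig",
  slots = c(
    thetaZ = "numeric",
    activityThreshold = "numeric",
    similarityThreshold = "numeric",
    robustScale = "numeric"
  )
)

setValidity("AnalysisConfig", function(object) {
  msgs <- character()
  one_pos <- function(x, nm, hi = Inf) {
    if (length(x) != 1 || !is.finite(x) || x <= 0 || x > hi) {
      paste0(nm, " must be a single positive value", if (is.finite(hi)) paste0(" <= ", hi))
    } else {
      character()
    }
  }
  msgs <- c(
    msgs,
    one_pos(object@thetaZ, "thetaZ"),
    one_pos(object@activityThreshold, "activityThreshold", 100),
    one_pos(object@similarityThreshold, "similarityThreshold", 100),
    one_pos(object@robustScale, "robustScale")
  )
  if (length(msgs)) msgs else TRUE
})

#' Subprofile: a cluster's reduced feature signature
#'
#' Built from a set of biosimilar reference profiles: the features retained
#' are those changed in the same direction across (at least a
#' \code{consistency} fraction of) the members, with a per-feature median
#' magnitude of at least \code{minAbsMedian}; \code{values} stores the
#' per-feature median z across members.
#'
#' @slot clusterName Cluster name (e.g., \code{"MitoStress"}).
#' @slot featureIds Selected feature identifiers.
#' @slot values Named numeric median z per selected feature.
#' @slot memberIds Profile ids the subprofile was extracted from.
#' @slot consistency Fraction of members required to share the median sign.
#' @slot minAbsMedian Minimum absolute median z for a feature to be kept.
#'
#' @aliases Subprofile-class
#' @exportClass Subprofile
setClass(
  "Subprofile",
  slots = c(
    clusterName = "character",
    featureIds = "character",
    values = "numeric",
    memberIds = "character",
    consistency = "numeric",
    minAbsMedian = "numeric"
  )
)

setValidity("Subprofile", function(object) {
  msgs <- character()
  if (length(object@featureIds) == 0) msgs <- c(msgs, "featureIds must be non-empty")
  if (length(object@values) != length(object@featureIds)) {
    msgs <- c(msgs, "values and featureIds must have equal length")
  }
  if (!all(is.finite(object@values))) msgs <- c(msgs, "values must be finite")
  if (!identical(names(object@values), object@featureIds)) {
    msgs <- c(msgs, "values must be named by featureIds")
  }
  if (length(object@consistency) != 1 ||
      object@consistency <= 0 || object@consistency > 1) {
    msgs <- c(msgs, "consistency must be in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' ClusterModel: the named bioactivity clusters
#'
#' An ordered list of \linkS4class{Subprofile} objects with unique cluster
#' names; the reference space against which test profiles are scored. The
#' original analysis used 13 such clusters (MitoStress, L/CH, PYR, BET,
#' HDAC, HSP90, uncoupler, ...); the model here is fully user- or
#' generator-supplied.
#'
#' @slot subprofiles List of \linkS4class{Subprofile}.
#'
#' @aliases ClusterModel-class
#' @exportClass ClusterModel
setClass("ClusterModel", slots = c(subprofiles = "list"))

setValidity("ClusterModel", function(object) {
  msgs <- character()
  if (length(object@subprofiles) == 0) {
    msgs <- c(msgs, "a ClusterModel needs at least one subprofile")
  }
  if (!all(vapply(object@subprofiles, is, logical(1), "Subprofile"))) {
    msgs <- c(msgs, "all elements must be Subprofile objects")
  } else {
    nms <- vapply(object@subprofiles, function(s) s@clusterName, character(1))
    if (anyDuplicated(nms)) msgs <- c(msgs, "cluster names must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' OCRTrace: a segmented metabolic flux trace
#'
#' Time-ordered oxygen consumption rate (OCR, pmol O2/min) and optionally
#' extracellular acidification rate (ECAR, mpH/min) measurements, segmented
#' by injection events (e.g., compound, oligomycin, FCCP,
#' rotenone+antimycin). Replicate wells are expected to be aggregated (mean
#' per timepoint) before construction; see \code{\link{readOCRTrace}}.
#'
#' @slot time Strictly increasing measurement times in minutes.
#' @slot ocr OCR value per timepoint.
#' @slot ecar ECAR value per timepoint, or length-zero if absent.
#' @slot injections \code{data.frame} with columns \code{label} and
#'   \code{time_min}, ordered by time, all within the measurement range.
#'
#' @aliases OCRTrace-class
#' @exportClass OCRTrace
setClass(
  "OCRTrace",
  slots = c(
    time = "numeric",
    ocr = "numeric",
    ecar = "numeric",
    injections = "data.frame"
  )
)

setValidity("OCRTrace", function(object) {
  msgs <- character()
  t <- object@time
  if (length(t) < 2 || any(diff(t) <= 0)) {
    msgs <- c(msgs, "time must be strictly increasing with >= 2 points")
  }
  if (length(object@ocr) != length(t)) msgs <- c(msgs, "ocr length must match time")
  if (length(object@ecar) && length(object@ecar) != length(t)) {
    msgs <- c(msgs, "ecar length must match time (or be empty)")
  }
  inj <- object@injections
  if (!all(c("label", "time_min") %in% colnames(inj))) {
    msgs <- c(msgs, "injections need columns label, time_min")
  } else if (nrow(inj)) {
    if (is.unsorted(inj$time_min, strictly = TRUE)) {
      msgs <- c(msgs, "injection times must be strictly increasing")
    }
    if (any(inj$time_min <= min(t)) || any(inj$time_min >= max(t))) {
      msgs <- c(msgs, "injection times must fall inside the measurement range")
    }
    phase <- findInterval(t, inj$time_min, left.open = TRUE)
    counts <- tabulate(phase + 1L, nbins = nrow(inj) + 1L)
    if (any(counts < 2)) {
      msgs <- c(msgs, sprintf(
        "phases with fewer than 2 measurements: %s",
        paste(which(counts < 2) - 1L, collapse = ", ")
      ))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' MitoParams: standard MitoStress respiration parameters
#'
#' Derived quantities of the sequential-injection mitochondrial stress test,
#' all in OCR units: non-mitochondrial respiration (final-phase mean), basal
#' respiration, proton leak, ATP-linked respiration, maximal respiration
#' (best post-FCCP measurement) and spare respiratory capacity. By
#' construction \code{atp_linked + proton_leak == basal} and
#' \code{spare_capacity == maximal - basal}.
#'
#' @slot basal,atp_linked,proton_leak,maximal,spare_capacity,non_mitochondrial
#'   Numeric scalars in OCR units.
#'
#' @aliases MitoParams-class
#' @exportClass MitoParams
setClass(
  "MitoParams",
  slots = c(
    basal = "numeric",
    atp_linked = "numeric",
    proton_leak = "numeric",
    maximal = "numeric",
    spare_capacity = "numeric",
    non_mitochondrial = "numeric"
  )
)

setValidity("MitoParams", function(object) {
  v <- vapply(slotNames(object), function(s) slot(object, s), numeric(1))
  if (!all(is.finite(v))) return("all respiration parameters must be finite")
  TRUE
})

#' FragmentScoreTable: NP-likeness fragment contributions
#'
#' Log-odds contribution per circular-fragment identifier, trained from a
#' natural-product set against a synthetic set (see
#' \code{\link{trainNPLikeness}}).
#'
#' @slot contributions Named numeric log-odds per fragment identifier.
#' @slot radius Fragment radius used.
#' @slot nNp,nSyn Training set sizes (molecules).
#' @slot epsilonNp,epsilonSyn Additive smoothing used on each side.
#'
#' @aliases FragmentScoreTable-class
#' @exportClass FragmentScoreTable
setClass(
  "FragmentScoreTable",
  slots = c(
    contributions = "numeric",
    radius = "integer",
    nNp = "integer",
    nSyn = "integer",
    epsilonNp = "numeric",
    epsilonSyn = "numeric"
  )
)

setValidity("FragmentScoreTable", function(object) {
  msgs <- character()
  if (is.null(names(object@contributions)) && length(object@contributions)) {
    msgs <- c(msgs, "contributions must be named by fragment identifier")
  }
  if (!all(is.finite(object@contributions))) {
    msgs <- c(msgs, "contributions must be finite")
  }
  if (object@nNp < 1 || object@nSyn < 1) {
    msgs <- c(msgs, "training set sizes must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' Embedding: a low-dimensional embedding of compounds or profiles
#'
#' @slot coordinates Numeric matrix (rows = input rows, columns =
#'   embedding dimensions), with rownames carrying the input ids.
#' @slot method \code{"pca"} or \code{"umap"}.
#' @slot explainedVariance Percent explained variance per component
#'   (PCA only; length zero for UMAP).
#' @slot params Method parameters (neighbor count, seed, normalization, ...).
#'
#' @aliases Embedding-class
#' @exportClass Embedding
setClass(
  "Embedding",
  slots = c(
    coordinates = "matrix",
    method = "character",
    explainedVariance = "numeric",
    params = "list"
  )
)

setValidity("Embedding", function(object) {
  msgs <- character()
  if (!object@method %in% c("pca", "umap")) {
    msgs <- c(msgs, "method must be 'pca' or 'umap'")
  }
  ev <- object@explainedVariance
  if (length(ev)) {
    if (any(ev < 0 | ev > 100) || is.unsorted(rev(ev)) || sum(ev) > 100 + 1e-8) {
      msgs <- c(msgs, "explained variances must be non-increasing, in [0,100], summing <= 100")
    }
  }
  if (length(msgs)) msgs else TRUE
})
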