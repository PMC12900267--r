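#' @include compound-io.R
NULL

#' Analysis thresholds for profile analytics
#'
#' @param thetaZ Absolute z-score at and above which a feature counts as
#'   significantly altered (default 3).
#' @param activityThreshold Induction percent at and above which a profile
#'   is active (default 5).
#' @param similarityThreshold Biosimilarity percent at and above which two
#'   profiles are similar (default 75).
#' @param robustScale MAD-to-sigma consistency constant (default 1.4826).
#' @return An \linkS4class{AnalysisConfig}.
#' @export
analysisConfig <- function(thetaZ = 3, activityThreshold = 5,
                           similarityThreshold = 75, robustScale = 1.4826) {
  new(
    "AnalysisConfig",
    thetaZ = thetaZ, activityThreshold = activityThreshold,
    similarityThreshold = similarityThreshold, robustScale = robustScale
  )
}

# Raw (unscaled) median absolute deviation.
.rawMad <- function(x) stats::median(abs(x - stats::median(x)))

#' Z-score profiles of a plate against its DMSO controls
#'
#' Per feature, the center is the median over control wells and the scale is
#' \code{robustScale * MAD} of the control wells. Replicate wells of the
#' same (compound, concentration) treatment are aggregated by the median
#' before scaling, so one profile is produced per treatment. Features whose
#' control values are all identical are flagged \code{excluded} (their z is
#' undefined, NA) and removed from the induction denominator; features with
#' zero MAD but non-constant controls get the smallest positive control MAD
#' on the plate substituted and are flagged \code{mad_substituted}.
#' Profiles are ordered by (compound id, concentration), so well order does
#' not matter.
#'
#' @param plate A \linkS4class{PlateData} with at least 4 control wells.
#' @param config An \linkS4class{AnalysisConfig}.
#' @return A \linkS4class{MorphProfileSet}; induction and activity flags are
#'   precomputed in its \code{colData}.
#' @export
zscoreProfiles <- function(plate, config = analysisConfig()) {
  stopifnot(is(plate, "PlateData"), is(config, "AnalysisConfig"))
  feat <- assay(plate, "features")
  cd <- colData(plate)
  ctrl <- feat[, cd$is_control, drop = FALSE]
  if (ncol(ctrl) < 4) {
    stop("need at least 4 control wells, found ", ncol(ctrl))
  }
  center <- apply(ctrl, 1, stats::median)
  madRaw <- apply(ctrl, 1, .rawMad)
  constant <- apply(ctrl, 1, function(x) diff(range(x)) == 0)
  posMads <- madRaw[madRaw > 0]
  substitute <- madRaw == 0 & !constant
  if (any(substitute) && !length(posMads)) {
    stop("every control feature has zero MAD; cannot substitute a scale")
  }
  scale <- config@robustScale * madRaw
  scale[substitute] <- config@robustScale * min(posMads)
  scale[constant] <- NA_real_
  trtIdx <- which(!cd$is_control)
  if (!length(trtIdx)) stop("plate has no treatment wells")
  key <- paste(cd$compound_id[trtIdx], cd$concentration_um[trtIdx], sep = "@")
  groups <- split(trtIdx, key)
  ord <- order(
    vapply(groups, function(i) cd$compound_id[i[1]], character(1)),
    vapply(groups, function(i) cd$concentration_um[i[1]], numeric(1))
  )
  groups <- groups[ord]
  z <- vapply(groups, function(i) {
    med <- apply(feat[, i, drop = FALSE], 1, stats::median)
    (med - center) / scale
  }, numeric(nrow(feat)))
  if (is.null(dim(z))) z <- matrix(z, nrow = nrow(feat))
  rownames(z) <- rownames(feat)
  colnames(z) <- names(groups)
  ind <- apply(z, 2, function(v) {
    .inductionFromZ(v, config@thetaZ, excluded = constant)
  })
  prof <- SummarizedExperiment(
    assays = list(z = z),
    rowData = DataFrame(
      excluded = constant, mad_substituted = substitute,
      row.names = rownames(feat)
    ),
    colData = DataFrame(
      compound_id = vapply(groups, function(i) cd$compound_id[i[1]], character(1)),
      concentration_um = vapply(groups, function(i) cd$concentration_um[i[1]], numeric(1)),
      induction = ind,
      active = ind >= config@activityThreshold,
      row.names = colnames(z)
    ),
    metadata = list(config = config, n_control_wells = ncol(ctrl))
  )
  new("MorphProfileSet", prof)
}

.inductionFromZ <- function(z, thetaZ, excluded = NULL) {
  if (!is.null(excluded)) z <- z[!excluded]
  z <- z[!is.na(z)]
  if (!length(z)) return(NA_real_)
  100 * sum(abs(z) >= thetaZ) / length(z)
}

#' Induction of a z-score vector
#'
#' Percentage of non-excluded features whose |z| meets the significance
#' cutoff; the general bioactivity measure of morphological profiling.
#' Profiles are considered active at induction >= 5 percent (default
#' threshold).
#'
#' @param x Numeric z-score vector (NA entries are treated as excluded
#'   features and removed from the denominator).
#' @param config An \linkS4class{AnalysisConfig}.
#' @param ... Ignored.
#' @return A list with \code{induction} (percent) and \code{active}.
#' @export
setMethod("induction", "numeric", function(x, config = analysisConfig(), ...) {
  ind <- .inductionFromZ(x, config@thetaZ)
  list(induction = ind, active = !is.na(ind) && ind >= config@activityThreshold)
})

#' Biosimilarity of two profiles
#'
#' 100 times the Pearson correlation of the two z-score vectors over their
#' shared non-missing features; the +/-100 percent scale of morphological
#' profile comparison. Two profiles count as similar at >= 75 percent
#' (default threshold).
#'
#' @param p,q Numeric z-score vectors of equal length.
#' @param config An \linkS4class{AnalysisConfig}.
#' @return A list with \code{biosim} (percent) and \code{similar}.
#' @export
biosimilarity <- function(p, q, config = analysisConfig()) {
  if (length(p) != length(q)) stop("profiles differ in feature count")
  keep <- !is.na(p) & !is.na(q)
  p <- p[keep]
  q <- q[keep]
  if (length(p) < 3) stop("fewer than 3 shared features")
  if (stats::sd(p) == 0 || stats::sd(q) == 0) {
    stop("undefined correlation: constant profile")
  }
  b <- 100 * stats::cor(p, q)
  list(biosim = b, similar = b >= config@similarityThreshold)
}

#' Pairwise biosimilarity matrix
#'
#' @param profiles A \linkS4class{MorphProfileSet} or numeric matrix
#'   (features x profiles).
#' @param config An \linkS4class{AnalysisConfig}.
#' @return Symmetric numeric matrix of biosimilarities in [-100, 100] with
#'   exactly 100 on the diagonal.
#' @export
biosimMatrix <- function(profiles, config = analysisConfig()) {
  z <- if (is(profiles, "MorphProfileSet")) zMatrix(profiles) else as.matrix(profiles)
  n <- ncol(z)
  if (n < 2) stop("need at least two profiles")
  m <- diag(100, n)
  dimnames(m) <- list(colnames(z), colnames(z))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- biosimilarity(z[, i], z[, j], config)$biosim
    }
  }
  m
}

#' Export profiles as a flat CSV
#'
#' One row per (compound, concentration) with columns \code{profile_id},
#' \code{compound_id}, \code{concentration_um}, \code{induction},
#' \code{active}, then the z-scores.
#'
#' @param profiles A \linkS4class{MorphProfileSet}.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
writeProfiles <- function(profiles, path) {
  stopifnot(is(profiles, "MorphProfileSet"))
  z <- t(zMatrix(profiles))
  cd <- as.data.frame(colData(profiles))
  out <- cbind(
    data.frame(
      profile_id = rownames(z),
      compound_id = cd$compound_id,
      concentration_um = cd$concentration_um,
      induction = sprintf("%.17g", cd$induction),
      active = cd$active,
      stringsAsFactors = FALSE
    ),
    as.data.frame(
      matrix(sprintf("%.17g", z), nrow(z), ncol(z), dimnames = dimnames(z)),
      stringsAsFactors = FALSE
    )
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
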