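#' @include profiles.R
NULL

#' Extract a cluster subprofile from biosimilar member profiles
#'
#' A subprofile keeps the features that change in the same direction across
#' the member profiles: a feature is selected when (a) at least a
#' \code{consistency} fraction of members shares the sign of the per-feature
#' median and (b) the absolute median is at least \code{minAbsMedian}. The
#' stored values are the per-feature medians. Members are expected to be
#' pairwise biosimilar at the similarity threshold; if they are not, a
#' warning is emitted (not an error). Member order does not matter.
#'
#' @param members A \linkS4class{MorphProfileSet} or numeric matrix
#'   (features x members) with at least 2 columns.
#' @param name Cluster name.
#' @param consistency Required sign-agreement fraction in (0, 1]
#'   (default 1: strictly the same direction in every member).
#' @param minAbsMedian Minimum |median z| for a feature (default 1).
#' @param config An \linkS4class{AnalysisConfig} (for the biosimilarity
#'   warning threshold).
#' @return A \linkS4class{Subprofile}.
#' @export
extractSubprofile <- function(members, name, consistency = 1,
                              minAbsMedian = 1, config = analysisConfig()) {
  z <- if (is(members, "MorphProfileSet")) zMatrix(members) else as.matrix(members)
  if (ncol(z) < 2) stop("need at least 2 member profiles")
  if (is.null(rownames(z))) rownames(z) <- sprintf("f_%04d", seq_len(nrow(z)))
  if (is.null(colnames(z))) colnames(z) <- sprintf("member_%d", seq_len(ncol(z)))
  pair <- tryCatch(biosimMatrix(z, config), error = function(e) NULL)
  if (!is.null(pair)) {
    low <- pair[upper.tri(pair)] < config@similarityThreshold
    if (any(low)) {
      warning(
        sum(low), " member pair(s) fall below the ",
        config@similarityThreshold, "% biosimilarity threshold"
      )
    }
  }
  med <- apply(z, 1, stats::median, na.rm = TRUE)
  signShare <- vapply(seq_len(nrow(z)), function(i) {
    v <- z[i, ]
    v <- v[!is.na(v)]
    if (!length(v) || med[i] == 0) return(0)
    sum(sign(v) == sign(med[i])) / ncol(z)
  }, numeric(1))
  keep <- is.finite(med) & signShare >= consistency & abs(med) >= minAbsMedian
  if (!any(keep)) {
    stop(
      "no consistent features selected; consider lowering consistency (",
      consistency, ") or minAbsMedian (", minAbsMedian, ")"
    )
  }
  new(
    "Subprofile",
    clusterName = name,
    featureIds = rownames(z)[keep],
    values = structure(unname(med[keep]), names = rownames(z)[keep]),
    memberIds = colnames(z),
    consistency = consistency,
    minAbsMedian = minAbsMedian
  )
}

#' Construct a ClusterModel
#'
#' @param subprofiles List of \linkS4class{Subprofile} objects (order
#'   defines the tie-breaking priority in \code{\link{assignClusters}}).
#' @return A \linkS4class{ClusterModel}.
#' @export
clusterModel <- function(subprofiles) {
  new("ClusterModel", subprofiles = unname(subprofiles))
}

#' Biosimilarity of a profile to a cluster subprofile
#'
#' 100 times the Pearson correlation between the profile restricted to the
#' subprofile's features and the subprofile's median values.
#'
#' @param profile Named numeric z-score vector covering the subprofile's
#'   features, or a single-column \linkS4class{MorphProfileSet}.
#' @param sub A \linkS4class{Subprofile}.
#' @return Biosimilarity percent in [-100, 100].
#' @export
clusterBiosim <- function(profile, sub) {
  stopifnot(is(sub, "Subprofile"))
  if (is(profile, "MorphProfileSet")) {
    stopifnot(ncol(profile) == 1)
    profile <- zMatrix(profile)[, 1]
  }
  v <- profile[sub@featureIds]
  keep <- !is.na(v)
  if (sum(keep) < 3) stop("subprofile too small for correlation (< 3 shared features)")
  v <- v[keep]
  ref <- sub@values[keep]
  if (stats::sd(v) == 0 || stats::sd(ref) == 0) {
    stop("undefined correlation: constant restriction")
  }
  100 * stats::cor(v, ref)
}

#' Assign profiles to bioactivity clusters
#'
#' Scores every profile against every cluster subprofile and assigns the
#' argmax cluster when its biosimilarity reaches the similarity threshold,
#' otherwise none (NA). Cells whose correlation is undefined (too few
#' shared features, constant restriction) are recorded as NA, never as 0.
#' Ties are broken in favor of the first-declared cluster and logged via
#' \code{message}.
#'
#' @param profiles A \linkS4class{MorphProfileSet} or numeric matrix
#'   (features x profiles, feature ids as rownames).
#' @param model A \linkS4class{ClusterModel}.
#' @param config An \linkS4class{AnalysisConfig}.
#' @return A \code{data.frame} with one row per profile: \code{profile_id},
#'   one biosimilarity column per cluster, \code{best_cluster} (NA when no
#'   cluster reaches the threshold) and \code{best_biosim}.
#' @export
assignClusters <- function(profiles, model, config = analysisConfig()) {
  stopifnot(is(model, "ClusterModel"))
  z <- if (is(profiles, "MorphProfileSet")) zMatrix(profiles) else as.matrix(profiles)
  if (is.null(rownames(z))) stop("profiles need feature ids as rownames")
  cls <- clusterNames(model)
  heat <- matrix(
    NA_real_, ncol(z), length(cls),
    dimnames = list(colnames(z), cls)
  )
  for (j in seq_along(cls)) {
    sub <- model@subprofiles[[j]]
    for (i in seq_len(ncol(z))) {
      heat[i, j] <- tryCatch(
        clusterBiosim(z[, i], sub),
        error = function(e) NA_real_
      )
    }
  }
  best <- character(ncol(z))
  bestVal <- rep(NA_real_, ncol(z))
  for (i in seq_len(ncol(z))) {
    v <- heat[i, ]
    if (all(is.na(v))) {
      best[i] <- NA_character_
      next
    }
    top <- max(v, na.rm = TRUE)
    hits <- which(!is.na(v) & v == top)
    if (length(hits) > 1) {
      message(
        "tie for profile '", colnames(z)[i], "' between clusters ",
        paste(cls[hits], collapse = ", "), "; keeping the first-declared"
      )
    }
    if (top >= config@similarityThreshold) {
      best[i] <- cls[hits[1]]
      bestVal[i] <- top
    } else {
      best[i] <- NA_character_
      bestVal[i] <- top
    }
  }
  out <- data.frame(
    profile_id = colnames(z),
    as.data.frame(heat),
    best_cluster = best,
    best_biosim = bestVal,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Joint UMAP of test and reference profiles
#'
#' Embeds raw z-score vectors (no normalization, matching the profile
#' convention) of test profiles together with optional reference profiles.
#' The returned embedding carries an \code{induction} column intended as the
#' symbol-size aesthetic when plotting.
#'
#' @param profiles A \linkS4class{MorphProfileSet} of test profiles.
#' @param references Optional \linkS4class{MorphProfileSet} of reference
#'   profiles with the same features.
#' @param nNeighbors Neighborhood size (default 10).
#' @param seed Random seed.
#' @return A \code{data.frame} with \code{profile_id}, \code{umap1},
#'   \code{umap2}, \code{role} (test/reference) and \code{induction}.
#' @export
profileUMAP <- function(profiles, references = NULL, nNeighbors = 10L, seed = 42L) {
  z <- t(zMatrix(profiles))
  role <- rep("test", nrow(z))
  ind <- unname(induction(profiles))
  if (!is.null(references)) {
    zr <- t(zMatrix(references))
    if (!identical(colnames(z), colnames(zr))) {
      stop("test and reference profiles disagree on features")
    }
    z <- rbind(z, zr)
    role <- c(role, rep("reference", nrow(zr)))
    ind <- c(ind, unname(induction(references)))
  }
  keep <- apply(z, 2, function(x) !anyNA(x))
  emb <- umapEmbed(
    z[, keep, drop = FALSE],
    nNeighbors = nNeighbors, seed = seed, normalize = FALSE
  )
  co <- embeddingCoords(emb)
  data.frame(
    profile_id = rownames(z),
    umap1 = co[, 1], umap2 = co[, 2],
    role = role, induction = ind,
    stringsAsFactors = FALSE
  )
}

#' Serialize / read a ClusterModel as JSON
#'
#' The on-disk schema is versioned: a top-level \code{schema_version} and
#' one record per cluster with \code{name}, \code{feature_ids},
#' \code{values}, \code{member_ids}, \code{consistency},
#' \code{min_abs_median}.
#'
#' @param model A \linkS4class{ClusterModel}.
#' @param path JSON file path.
#' @return \code{writeClusterModel} invisibly returns the path;
#'   \code{readClusterModel} returns the \linkS4class{ClusterModel}.
#' @export
writeClusterModel <- function(model, path) {
  stopifnot(is(model, "ClusterModel"))
  payload <- list(
    schema_version = 1L,
    clusters = lapply(model@subprofiles, function(s) {
      list(
        name = s@clusterName,
        feature_ids = s@featureIds,
        values = unname(s@values),
        member_ids = s@memberIds,
        consistency = s@consistency,
        min_abs_median = s@minAbsMedian
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeClusterModel
#' @export
readClusterModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(payload$schema_version) || payload$schema_version != 1L) {
    stop("unsupported cluster model schema version")
  }
  subs <- lapply(payload$clusters, function(cl) {
    fids <- vapply(cl$feature_ids, as.character, character(1))
    new(
      "Subprofile",
      clusterName = cl$name,
      featureIds = fids,
      values = structure(vapply(cl$values, as.numeric, numeric(1)), names = fids),
      memberIds = vapply(cl$member_ids, as.character, character(1)),
      consistency = as.numeric(cl$consistency),
      minAbsMedian = as.numeric(cl$min_abs_median)
    )
  })
  clusterModel(subs)
}
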