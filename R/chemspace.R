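#' @include fingerprints.R
NULL

#' PCA embedding of a descriptor table
#'
#' Standardizes every column (zero mean, unit variance), drops constant
#' columns with a warning, and decomposes the result. The sign of each
#' component is fixed so that its largest-magnitude loading is positive,
#' which makes the embedding deterministic.
#'
#' @param table Numeric \code{data.frame} or matrix; rows = compounds (ids as
#'   rownames), columns = descriptors. No missing values allowed.
#' @param k Number of components (default 2).
#' @return An \linkS4class{Embedding} with per-component explained variance
#'   in percent.
#' @export
pcaEmbed <- function(table, k = 2L) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("descriptor table must be numeric")
  if (anyNA(m)) stop("descriptor table must not contain missing values")
  if (nrow(m) < k + 1) stop("need at least k+1 rows")
  sds <- apply(m, 2, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning("dropping constant column(s): ", paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  if (ncol(m) == 0) stop("no non-constant columns left")
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (k > rank) stop("k = ", k, " exceeds the rank (", rank, ") of the table")
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  new(
    "Embedding",
    coordinates = coords, method = "pca",
    explainedVariance = ev[seq_len(k)],
    params = list(k = k, dropped = colnames(table)[const])
  )
}

#' UMAP embedding
#'
#' Two-dimensional uniform manifold approximation and projection. With
#' \code{normalize = TRUE} columns are standardized first (the convention
#' for descriptor tables); with \code{normalize = FALSE} the rows are
#' embedded as-is (the convention for morphological z-score profiles, which
#' are already on a common scale). Same seed and input give identical
#' coordinates.
#'
#' @param table Numeric \code{data.frame} or matrix, rows = items.
#' @param nNeighbors Neighborhood size (default 10).
#' @param seed Random seed (default 42).
#' @param normalize Standardize columns before embedding (default TRUE).
#' @param minDist Minimum embedding distance (default 0.1).
#' @return An \linkS4class{Embedding}.
#' @export
umapEmbed <- function(table, nNeighbors = 10L, seed = 42L,
                      normalize = TRUE, minDist = 0.1) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("input table must be numeric")
  if (nrow(m) <= nNeighbors) {
    stop(
      "UMAP needs more rows (", nrow(m), ") than neighbors (", nNeighbors,
      "); lower nNeighbors or provide more rows"
    )
  }
  if (normalize) {
    sds <- apply(m, 2, stats::sd)
    keep <- sds > 0
    m <- scale(m[, keep, drop = FALSE])
  }
  set.seed(seed)
  coords <- uwot::umap(
    m,
    n_neighbors = nNeighbors, min_dist = minDist, metric = "euclidean",
    n_threads = 1, n_sgd_threads = 0
  )
  rownames(coords) <- rownames(table)
  colnames(coords) <- c("umap1", "umap2")
  new(
    "Embedding",
    coordinates = coords, method = "umap", explainedVariance = numeric(),
    params = list(
      n_neighbors = nNeighbors, seed = seed,
      normalize = normalize, min_dist = minDist
    )
  )
}

#' The packaged 3a-aryloctahydroindole (AOHI) substructure pattern
#'
#' A fused bicyclic octahydroindole (saturated 6-5 ring fusion with the
#' nitrogen in the five-membered ring) carrying an aryl substituent at the
#' ring-fusion quaternary carbon -- the scaffold of the alkaloid mesembrine.
#' The six-membered ring is required to be non-aromatic but may carry sp2
#' carbons (e.g., a ketone). The pattern is deliberately exposed so it can
#' be reviewed or replaced.
#'
#' @return A SMARTS string.
#' @export
aohiSmarts <- function() {
  "[NX3;R]1[#6X4][#6X4][#6X4]2(-[c])[#6;!c][#6;!c][#6;!c][#6;!c][#6X4]12"
}

#' Substructure enrichment across compound classes
#'
#' Counts, per class label, how many compounds contain the given
#' substructure, and reports the matching fraction. Matching is performed on
#' the canonical structures.
#'
#' @param compounds A \linkS4class{CompoundSet} with class labels.
#' @param smarts SMARTS pattern (default: the packaged AOHI pattern).
#' @return A \code{data.frame} with columns \code{class_label},
#'   \code{n_total}, \code{n_matching}, \code{fraction}, one row per class.
#' @examples
#' \dontrun{
#' enrichment(genToyCompoundClasses(1), aohiSmarts())
#' }
#' @export
enrichment <- function(compounds, smarts = aohiSmarts()) {
  stopifnot(is(compounds, "CompoundSet"))
  hit <- .smartsMatch(structures(compounds), smarts)
  labs <- classLabels(compounds)
  out <- do.call(rbind, lapply(sort(unique(labs)), function(lb) {
    sel <- labs == lb
    data.frame(
      class_label = lb,
      n_total = sum(sel),
      n_matching = sum(hit[sel]),
      fraction = sum(hit[sel]) / sum(sel),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Match a substructure against compounds
#'
#' @param compounds A \linkS4class{CompoundSet} or character vector of SMILES.
#' @param smarts SMARTS pattern.
#' @return Named logical vector, TRUE where the pattern matches.
#' @export
matchesSubstructure <- function(compounds, smarts) {
  smi <- .smilesOf(compounds)
  out <- .smartsMatch(smi, smarts)
  names(out) <- names(smi)
  out
}
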