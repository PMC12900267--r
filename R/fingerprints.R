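#' @include nplikeness.R
NULL

#' Hashed circular fingerprints
#'
#' Folds the Morgan environment identifiers (radii 0..\code{radius}) of each
#' molecule into an \code{nbits}-wide bit set by taking the identifier
#' modulo \code{nbits}.
#'
#' @param compounds A \linkS4class{CompoundSet} or character vector of SMILES.
#' @param radius Circular environment radius (default 2).
#' @param nbits Fingerprint width (default 2048).
#' @return A list of sorted integer vectors (the set bits, 0-based) per
#'   molecule.
#' @export
morganBitSets <- function(compounds, radius = 2L, nbits = 2048L) {
  smi <- .smilesOf(compounds)
  frags <- .morganCounts(smi, radius)
  out <- lapply(frags, function(fc) {
    # identifiers are 32-bit hashes serialized as strings; exact as doubles
    sort(unique(as.numeric(names(fc)) %% nbits))
  })
  names(out) <- names(smi)
  out
}

#' Pairwise Tanimoto similarity matrix
#'
#' Tanimoto coefficient |A & B| / |A | B| on hashed circular fingerprints
#' (radius 2 by default). The matrix is symmetric with a unit diagonal.
#'
#' @inheritParams morganBitSets
#' @return Square numeric matrix in [0, 1] with compound ids as dimnames.
#' @export
tanimotoMatrix <- function(compounds, radius = 2L, nbits = 2048L) {
  bits <- morganBitSets(compounds, radius = radius, nbits = nbits)
  n <- length(bits)
  if (n < 2) stop("need at least two compounds for a similarity matrix")
  ids <- names(bits)
  if (is.null(ids)) ids <- sprintf("cpd_%04d", seq_len(n))
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- length(intersect(bits[[i]], bits[[j]]))
      uni <- length(bits[[i]]) + length(bits[[j]]) - inter
      m[i, j] <- m[j, i] <- if (uni == 0) 1 else inter / uni
    }
  }
  m
}
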