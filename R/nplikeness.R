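#' @include descriptors.R
NULL

# Circular (Morgan) environment identifiers per molecule, radii 0..radius,
# as a named integer count vector per molecule.
.morganCounts <- function(smiles, radius = 2L) {
  res <- .molData(smiles, what = "morgan", radius = as.integer(radius))
  lapply(res, function(r) {
    ids <- vapply(r$morgan$ids, as.character, character(1))
    counts <- vapply(r$morgan$counts, as.integer, integer(1))
    structure(counts, names = ids)
  })
}

#' Train an NP-likeness fragment contribution table
#'
#' Contrasts circular-fragment frequencies between a natural-product
#' reference set and a synthetic reference set. For each fragment f the
#' contribution is
#' \deqn{c_f = \log\frac{p_{NP}(f) + \epsilon_{NP}}{p_{syn}(f) + \epsilon_{syn}}}
#' where \eqn{p(f)} is the fraction of molecules in the set containing f and
#' the smoothing defaults to 1/(set size) per side. With per-side smoothing
#' tied to its own set, swapping the two sets exactly negates every
#' contribution.
#'
#' @param npSet,synSet \linkS4class{CompoundSet}s of natural-product-like and
#'   synthetic reference molecules. They should be disjoint by canonical
#'   structure; overlap triggers a warning, not an error.
#' @param radius Circular fragment radius (default 2; all environments of
#'   radius 0..radius are used).
#' @param epsilon Optional single smoothing constant applied to both sides
#'   (overrides the per-set default).
#' @return A \linkS4class{FragmentScoreTable}.
#' @seealso \code{\link{npLikeness}}
#' @export
trainNPLikeness <- function(npSet, synSet, radius = 2L, epsilon = NULL) {
  stopifnot(is(npSet, "CompoundSet"), is(synSet, "CompoundSet"))
  if (length(npSet) == 0 || length(synSet) == 0) {
    stop("both training sets must be non-empty")
  }
  overlap <- intersect(structures(npSet), structures(synSet))
  if (length(overlap)) {
    warning(length(overlap), " structure(s) occur in both training sets")
  }
  npFrags <- .morganCounts(structures(npSet), radius)
  synFrags <- .morganCounts(structures(synSet), radius)
  nNp <- length(npFrags)
  nSyn <- length(synFrags)
  epsNp <- if (is.null(epsilon)) 1 / nNp else epsilon
  epsSyn <- if (is.null(epsilon)) 1 / nSyn else epsilon
  molFreq <- function(frags, n) {
    tab <- table(unlist(lapply(frags, names)))
    structure(as.numeric(tab) / n, names = names(tab))
  }
  fNp <- molFreq(npFrags, nNp)
  fSyn <- molFreq(synFrags, nSyn)
  all <- union(names(fNp), names(fSyn))
  pNp <- structure(numeric(length(all)), names = all)
  pSyn <- pNp
  pNp[names(fNp)] <- fNp
  pSyn[names(fSyn)] <- fSyn
  contrib <- log((pNp + epsNp) / (pSyn + epsSyn))
  new(
    "FragmentScoreTable",
    contributions = contrib, radius = as.integer(radius),
    nNp = as.integer(nNp), nSyn = as.integer(nSyn),
    epsilonNp = epsNp, epsilonSyn = epsSyn
  )
}

#' Score molecules for NP-likeness
#'
#' The score of a molecule is the mean trained fragment contribution over
#' all of its circular-fragment occurrences (multiplicity-weighted), clipped
#' to [-5, 5]. Fragments unseen in training contribute
#' \eqn{\log(\epsilon_{NP}/\epsilon_{syn})}. Positive scores indicate
#' natural-product character, negative scores synthetic character.
#'
#' @param compounds A \linkS4class{CompoundSet} or character vector of SMILES.
#' @param table A trained \linkS4class{FragmentScoreTable}.
#' @return Named numeric vector of clipped scores.
#' @export
npLikeness <- function(compounds, table) {
  stopifnot(is(table, "FragmentScoreTable"))
  smi <- .smilesOf(compounds)
  frags <- .morganCounts(smi, table@radius)
  unseen <- log(table@epsilonNp / table@epsilonSyn)
  out <- vapply(frags, function(fc) {
    if (!length(fc)) {
      warning("molecule yields no circular fragments; score set to 0")
      return(0)
    }
    contrib <- table@contributions[names(fc)]
    contrib[is.na(contrib)] <- unseen
    score <- sum(contrib * fc) / sum(fc)
    min(5, max(-5, score))
  }, numeric(1))
  names(out) <- names(smi)
  out
}
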