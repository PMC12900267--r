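#' @include compound-io.R
NULL

.smilesOf <- function(x) {
  if (is(x, "CompoundSet")) structures(x) else structure(as.character(x), names = NULL)
}

#' The default molecular descriptor panel
#'
#' Seventeen descriptors standard in natural-product versus drug chemical
#' space comparisons: molecular weight, cLogP (atomic-contribution method),
#' tPSA, hydrogen-bond donor/acceptor counts, rotatable bonds, ring count,
#' aromatic ring count, heavy atom count, fraction of sp3 carbons,
#' stereocenter count (assigned plus unassigned tetrahedral centers),
#' heteroatom count, formal charge, ring-system count, largest ring size,
#' nitrogen count and oxygen count.
#'
#' @return Character vector of the 17 descriptor names.
#' @export
defaultDescriptors <- function() {
  c(
    "mw", "clogp", "tpsa", "hbd_count", "hba_count", "rotatable_bonds",
    "ring_count", "aromatic_ring_count", "heavy_atom_count", "fraction_csp3",
    "stereocenter_count", "heteroatom_count", "formal_charge",
    "ring_system_count", "largest_ring_size", "nitrogen_count", "oxygen_count"
  )
}

#' Compute a per-compound descriptor table
#'
#' @param compounds A \linkS4class{CompoundSet} or character vector of SMILES.
#' @param names Descriptor names to compute; must be drawn from
#'   \code{\link{defaultDescriptors}()}.
#' @return A \code{data.frame} (rownames = compound ids) with one numeric
#'   column per requested descriptor. Compounds for which any descriptor
#'   failed are excluded and listed in the \code{"failures"} attribute.
#' @examples
#' \dontrun{
#' descriptorTable(compoundSet("c1ccccc1"), c("heavy_atom_count", "ring_count"))
#' }
#' @export
descriptorTable <- function(compounds, names = defaultDescriptors()) {
  unknown <- setdiff(names, defaultDescriptors())
  if (length(unknown)) {
    stop(
      "unknown descriptor name(s): ", paste(unknown, collapse = ", "),
      "\nsupported: ", paste(defaultDescriptors(), collapse = ", ")
    )
  }
  smi <- .smilesOf(compounds)
  ids <- if (is.null(names(smi))) sprintf("cpd_%04d", seq_along(smi)) else names(smi)
  res <- .molData(smi, what = "descriptors")
  vals <- matrix(
    unlist(lapply(res, function(r) unlist(r$descriptors)[names])),
    nrow = length(res), ncol = length(names), byrow = TRUE,
    dimnames = list(ids, names)
  )
  okRow <- apply(is.finite(vals), 1, all)
  out <- as.data.frame(vals[okRow, , drop = FALSE])
  attr(out, "failures") <- ids[!okRow]
  out
}

# Published desirability (ADS) parameters and property weights of the
# quantitative estimate of drug-likeness (Bickerton et al. parameterization;
# identical constants ship with every mainstream implementation).
.QED_ADS <- list(
  MW     = c(A = 2.817065973, B = 392.5754953, C = 290.7489764, D = 2.419764353,
             E = 49.22325677, F = 65.37051707, DMAX = 104.9805561),
  ALOGP  = c(A = 3.172690585, B = 137.8624751, C = 2.534937431, D = 4.581497897,
             E = 0.822739154, F = 0.576295591, DMAX = 131.3186604),
  HBA    = c(A = 2.948620388, B = 160.4605972, C = 3.615294657, D = 4.435986202,
             E = 0.290141953, F = 1.300669958, DMAX = 148.7763046),
  HBD    = c(A = 1.618662227, B = 1010.051101, C = 0.985094388, D = 1e-09,
             E = 0.713820843, F = 0.920922555, DMAX = 258.1632616),
  PSA    = c(A = 1.876861559, B = 125.2232657, C = 62.90773554, D = 87.83366614,
             E = 12.01999824, F = 28.51324732, DMAX = 104.5686167),
  ROTB   = c(A = 0.01, B = 272.4121427, C = 2.55837997, D = 1.565547684,
             E = 1.271567166, F = 2.758063707, DMAX = 105.4420403),
  AROM   = c(A = 3.21778897, B = 957.7374108, C = 2.274627939, D = 1e-09,
             E = 1.317690384, F = 0.375760881, DMAX = 312.337261),
  ALERTS = c(A = 0.01, B = 1199.094025, C = -0.09002883, D = 1e-09,
             E = 0.185904477, F = 0.875193782, DMAX = 417.725314)
)

.QED_WEIGHTS <- c(
  MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95
)

# Asymmetric double sigmoid desirability, scaled to (0, 1] by its maximum.
.ads <- function(x, p) {
  e1 <- 1 + exp(-(x - p[["C"]] + p[["D"]] / 2) / p[["E"]])
  e2 <- 1 + exp(-(x - p[["C"]] - p[["D"]] / 2) / p[["F"]])
  (p[["A"]] + p[["B"]] / e1 * (1 - 1 / e2)) / p[["DMAX"]]
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted geometric mean of eight property desirabilities (molecular
#' weight, cLogP, H-bond acceptors and donors, polar surface area, rotatable
#' bonds, aromatic rings, structural alerts), each mapped through the
#' published asymmetric-double-sigmoid desirability functions. Values lie in
#' (0, 1], higher meaning more drug-like.
#'
#' @param compounds A \linkS4class{CompoundSet} or character vector of SMILES.
#' @return Named numeric vector of QED values.
#' @examples
#' \dontrun{
#' qed("CC(=O)Nc1ccc(O)cc1")  # paracetamol
#' }
#' @export
qed <- function(compounds) {
  smi <- .smilesOf(compounds)
  res <- .molData(smi, what = "qed")
  out <- vapply(res, function(r) {
    props <- unlist(r$qed)[names(.QED_WEIGHTS)]
    d <- mapply(function(x, nm) .ads(x, .QED_ADS[[nm]]), props, names(.QED_WEIGHTS))
    exp(sum(.QED_WEIGHTS * log(d)) / sum(.QED_WEIGHTS))
  }, numeric(1))
  names(out) <- names(smi)
  out
}

# Per-atom spatial-score terms. h: hybridization weight, s: stereocenter
# weight, r: non-aromatic ring weight, n: heavy-neighbor count. The atom
# contributes h*s*r*n^2.
.spsTerms <- function(atoms) {
  h <- vapply(atoms, function(a) {
    switch(a$hyb, sp = 1, sp2 = 2, sp3 = 3, 4)
  }, numeric(1))
  s <- vapply(atoms, function(a) if (isTRUE(a$stereocenter)) 2 else 1, numeric(1))
  r <- vapply(atoms, function(a) {
    if (isTRUE(a$in_ring) && !isTRUE(a$aromatic)) 2 else 1
  }, numeric(1))
  n <- vapply(atoms, function(a) a$degree, numeric(1))
  data.frame(h = h, s = s, r = r, n = n)
}

#' Spatial score (SPS) and normalized spatial score (nSPS)
#'
#' A molecular complexity descriptor integrating hybridization, stereogenic
#' centers, non-aromatic ring membership and branching: each heavy atom
#' contributes h*s*r*n^2 where h is 1/2/3 for sp/sp2/sp3 (4 otherwise), s is
#' 2 for stereocenters (else 1), r is 2 for atoms in a non-aromatic ring
#' (else 1) and n is the heavy-atom neighbor count. \code{nsps} divides by
#' the heavy atom count, yielding a size-independent complexity density;
#' biologically privileged compound classes typically fall in the nSPS
#' 20--40 range.
#'
#' @param compounds A \linkS4class{CompoundSet} or character vector of SMILES.
#' @return Named numeric vector of scores.
#' @examples
#' \dontrun{
#' sps(c("CC", "c1ccccc1", "C1CCCCC1"))   # 6, 48, 144
#' nsps(c("CC", "c1ccccc1", "C1CCCCC1"))  # 3, 8, 24
#' }
#' @export
sps <- function(compounds) {
  smi <- .smilesOf(compounds)
  res <- .molData(smi, what = "atoms")
  out <- vapply(res, function(r) {
    if (!length(r$atoms)) stop("molecule with no heavy atoms")
    tt <- .spsTerms(r$atoms)
    sum(tt$h * tt$s * tt$r * tt$n^2)
  }, numeric(1))
  names(out) <- names(smi)
  out
}

#' @rdname sps
#' @export
nsps <- function(compounds) {
  smi <- .smilesOf(compounds)
  res <- .molData(smi, what = "atoms")
  out <- vapply(res, function(r) {
    if (!length(r$atoms)) stop("molecule with no heavy atoms")
    tt <- .spsTerms(r$atoms)
    sum(tt$h * tt$s * tt$r * tt$n^2) / length(r$atoms)
  }, numeric(1))
  names(out) <- names(smi)
  out
}

#' Shape descriptor from principal moments of inertia
#'
#' \code{shapeFromMoments} converts sorted principal moments
#' (I1 <= I2 <= I3) into the normalized PMI ratios NPR1 = I1/I3 and
#' NPR2 = I2/I3 and classifies the shape by the nearest vertex of the
#' rod--disc--sphere triangle (rod at (0,1), disc at (0.5,0.5), sphere at
#' (1,1)). \code{shapeDescriptors} embeds each molecule in 3D (10 seeded
#' conformers, force-field optimized, lowest energy kept, hydrogens
#' included), computes the inertia tensor from atomic masses and
#' coordinates, and applies the same classification.
#'
#' @param compounds A \linkS4class{CompoundSet} or character vector of SMILES.
#' @param seed Integer seed for conformer generation.
#' @return A \code{data.frame} with columns \code{npr1}, \code{npr2},
#'   \code{shape_class} (factor: rod, disc, sphere). Always satisfies
#'   0 <= NPR1 <= NPR2 <= 1 and NPR1 + NPR2 >= 1.
#' @export
shapeDescriptors <- function(compounds, seed = 42L) {
  smi <- .smilesOf(compounds)
  ids <- if (is.null(names(smi))) sprintf("cpd_%04d", seq_along(smi)) else names(smi)
  res <- .callBackend("conformer", list(
    smiles = as.list(unname(smi)), seed = as.integer(seed), n_confs = 10L
  ))$results
  rows <- vector("list", length(res))
  for (i in seq_along(res)) {
    r <- res[[i]]
    if (!isTRUE(r$ok)) {
      stop("3D embedding failed for compound '", ids[i], "': ", r$error)
    }
    xyz <- do.call(rbind, lapply(r$coords, unlist))
    m <- unlist(r$masses)
    rows[[i]] <- shapeFromMoments(.principalMoments(xyz, m))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  out
}

# Principal moments of inertia (ascending) from coordinates and masses.
.principalMoments <- function(xyz, masses) {
  ctr <- colSums(xyz * masses) / sum(masses)
  d <- sweep(xyz, 2, ctr)
  x <- d[, 1]; y <- d[, 2]; z <- d[, 3]
  tensor <- matrix(c(
    sum(masses * (y^2 + z^2)), -sum(masses * x * y), -sum(masses * x * z),
    -sum(masses * x * y), sum(masses * (x^2 + z^2)), -sum(masses * y * z),
    -sum(masses * x * z), -sum(masses * y * z), sum(masses * (x^2 + y^2))
  ), 3, 3)
  sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values)
}

#' @rdname shapeDescriptors
#' @param moments Numeric length-3 vector of principal moments (any order);
#'   used directly instead of embedding a structure.
#' @export
shapeFromMoments <- function(moments) {
  stopifnot(length(moments) == 3, all(is.finite(moments)), all(moments >= 0))
  m <- sort(moments)
  if (m[3] <= 0) stop("largest principal moment must be positive")
  npr1 <- m[1] / m[3]
  npr2 <- m[2] / m[3]
  verts <- rbind(rod = c(0, 1), disc = c(0.5, 0.5), sphere = c(1, 1))
  d2 <- (verts[, 1] - npr1)^2 + (verts[, 2] - npr2)^2
  data.frame(
    npr1 = npr1, npr2 = npr2,
    shape_class = factor(rownames(verts)[which.min(d2)],
                         levels = c("rod", "disc", "sphere"))
  )
}
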