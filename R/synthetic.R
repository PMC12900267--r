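#' @include compound-io.R bioenergetics.R
NULL

#' Specification of a synthetic morphological plate
#'
#' Describes the generative model of \code{\link{genPlate}}: control wells
#' are feature-wise Normal(mu_f, sigma_f) with per-feature scales drawn
#' log-uniformly over one decade (so robust scaling is actually exercised);
#' treatment wells add an effect along one of k sign-pattern cluster
#' templates, scaled by a Hill dose response. The \code{amplitude} of a
#' compound is the expected per-effect-feature shift in units of that
#' feature's scale at full saturation, i.e. the planted z-score magnitude is
#' approximately \code{amplitude * hill(conc)}. Templates occupy disjoint
#' feature subsets and are therefore mutually orthogonal.
#'
#' @param nFeatures Number of features F (default 579, the standard cell
#'   painting feature count).
#' @param nControls Number of DMSO control wells (default 32, minimum 8).
#' @param k Number of planted clusters (default 4).
#' @param sPerCluster Effect-carrying features per cluster (default 58,
#'   about 10 percent of F).
#' @param nPerCluster Active compounds per cluster (default 10).
#' @param nInactive Compounds with zero amplitude (default 5).
#' @param amplitude Saturating per-feature effect size in scale units
#'   (default 10).
#' @param concentrations Tested concentrations in uM (default 2, 10, 30, 50).
#' @param c50 Hill half-max concentration in uM (default 10).
#' @param hillSlope Hill slope (default 1).
#' @param nReplicates Replicate wells per (compound, concentration)
#'   (default 4, emulating quadruplicate measurements).
#' @param seed Integer seed; the whole plate is a deterministic function of
#'   the spec.
#' @return A validated spec (class \code{SyntheticPlateSpec}).
#' @export
syntheticPlateSpec <- function(nFeatures = 579L, nControls = 32L, k = 4L,
                               sPerCluster = 58L, nPerCluster = 10L,
                               nInactive = 5L, amplitude = 10,
                               concentrations = c(2, 10, 30, 50),
                               c50 = 10, hillSlope = 1,
                               nReplicates = 4L, seed = 1L) {
  spec <- list(
    nFeatures = as.integer(nFeatures), nControls = as.integer(nControls),
    k = as.integer(k), sPerCluster = as.integer(sPerCluster),
    nPerCluster = as.integer(nPerCluster), nInactive = as.integer(nInactive),
    amplitude = amplitude, concentrations = as.numeric(concentrations),
    c50 = c50, hillSlope = hillSlope,
    nReplicates = as.integer(nReplicates), seed = as.integer(seed)
  )
  if (spec$nControls < 8) stop("need at least 8 control wells")
  if (spec$k * spec$sPerCluster > spec$nFeatures) {
    stop("k * sPerCluster exceeds the number of features")
  }
  if (spec$amplitude < 0) stop("amplitude must be >= 0")
  if (any(spec$concentrations <= 0)) stop("concentrations must be positive")
  class(spec) <- "SyntheticPlateSpec"
  spec
}

#' @export
print.SyntheticPlateSpec <- function(x, ...) {
  cat(sprintf(
    "SyntheticPlateSpec: F=%d, %d controls, k=%d clusters x %d features, %d+%d compounds, amplitude %g, conc {%s} uM, seed %d\n",
    x$nFeatures, x$nControls, x$k, x$sPerCluster,
    x$k * x$nPerCluster, x$nInactive, x$amplitude,
    paste(x$concentrations, collapse = ", "), x$seed
  ))
  invisible(x)
}

.hill <- function(conc, c50, slope) {
  conc^slope / (c50^slope + conc^slope)
}

#' Generate a synthetic plate with known ground truth
#'
#' Deterministic given the spec (same seed twice yields identical tables).
#' Controls are drawn from the per-feature baseline distribution; each
#' active compound shifts its cluster's effect features by
#' \code{amplitude * hill(conc) * sign} scale units plus noise.
#'
#' @param spec A \code{\link{syntheticPlateSpec}}.
#' @return A list with \code{plate} (a \linkS4class{PlateData}) and
#'   \code{truth}: \code{cluster_labels} (named character, NA for inactive
#'   compounds), \code{effect_features} (list of feature-id vectors per
#'   cluster), \code{templates} (unit-norm signed template matrix, features
#'   x clusters) and \code{expected_mean} (wells x features matrix of
#'   noise-free well means).
#' @export
genPlate <- function(spec) {
  stopifnot(inherits(spec, "SyntheticPlateSpec"))
  set.seed(spec$seed)
  F <- spec$nFeatures
  featIds <- sprintf("f_%04d", seq_len(F))
  mu <- stats::runif(F, 50, 150)
  sigma <- 10^stats::runif(F, -0.5, 0.5)  # one decade of scale heterogeneity
  # disjoint signed templates, stored unit-norm
  pool <- sample.int(F, spec$k * spec$sPerCluster)
  templates <- matrix(0, F, spec$k,
                      dimnames = list(featIds, sprintf("cluster_%d", seq_len(spec$k))))
  effectFeatures <- vector("list", spec$k)
  names(effectFeatures) <- colnames(templates)
  for (kk in seq_len(spec$k)) {
    idx <- pool[((kk - 1) * spec$sPerCluster + 1):(kk * spec$sPerCluster)]
    signs <- sample(c(-1, 1), spec$sPerCluster, replace = TRUE)
    templates[idx, kk] <- signs / sqrt(spec$sPerCluster)
    effectFeatures[[kk]] <- featIds[idx]
  }
  compounds <- data.frame(
    compound_id = c(
      sprintf("cpd_%02d", seq_len(spec$k * spec$nPerCluster)),
      if (spec$nInactive) sprintf("inert_%02d", seq_len(spec$nInactive))
    ),
    cluster = c(
      rep(seq_len(spec$k), each = spec$nPerCluster),
      rep(NA_integer_, spec$nInactive)
    ),
    amplitude = c(
      rep(spec$amplitude, spec$k * spec$nPerCluster),
      rep(0, spec$nInactive)
    ),
    stringsAsFactors = FALSE
  )
  wells <- list()
  meta <- list()
  wellNo <- 0L
  addWell <- function(values, compound, conc, control) {
    wellNo <<- wellNo + 1L
    wells[[wellNo]] <<- values
    meta[[wellNo]] <<- data.frame(
      plate_id = "SIMPLATE",
      well_id = sprintf("w%04d", wellNo),
      compound_id = compound,
      concentration_um = conc,
      is_control = control,
      stringsAsFactors = FALSE
    )
  }
  expected <- list()
  for (i in seq_len(spec$nControls)) {
    addWell(mu + stats::rnorm(F, 0, sigma), NA_character_, NA_real_, TRUE)
    expected[[length(expected) + 1L]] <- mu
  }
  for (ci in seq_len(nrow(compounds))) {
    for (conc in spec$concentrations) {
      kk <- compounds$cluster[ci]
      shift <- if (is.na(kk)) {
        rep(0, F)
      } else {
        compounds$amplitude[ci] * .hill(conc, spec$c50, spec$hillSlope) *
          templates[, kk] * sqrt(spec$sPerCluster) * sigma
      }
      for (r in seq_len(spec$nReplicates)) {
        addWell(
          mu + shift + stats::rnorm(F, 0, sigma),
          compounds$compound_id[ci], conc, FALSE
        )
        expected[[length(expected) + 1L]] <- mu + shift
      }
    }
  }
  featMat <- do.call(rbind, wells)
  colnames(featMat) <- featIds
  metaDf <- do.call(rbind, meta)
  expMat <- do.call(rbind, expected)
  dimnames(expMat) <- list(metaDf$well_id, featIds)
  truth <- list(
    cluster_labels = structure(
      ifelse(is.na(compounds$cluster), NA_character_,
             sprintf("cluster_%d", compounds$cluster)),
      names = compounds$compound_id
    ),
    effect_features = effectFeatures,
    templates = templates,
    expected_mean = expMat
  )
  list(plate = plateData(featMat, metaDf), truth = truth)
}

.TOY_NP <- c(
  mesembrine = "CN1CC[C@]2(c3ccc(OC)c(OC)c3)CC(=O)CC[C@H]12",
  artemisinin = "CC1CCC2C(C)C(=O)OC3OC4(C)CCC1C23OO4",
  camphor = "CC1(C)C2CCC1(C)C(=O)C2",
  menthol = "CC(C)C1CCC(C)CC1O",
  borneol = "CC1(C)C2CCC1(C)C(O)C2",
  decalinol = "OC1CCC2CCCCC2C1",
  sclareolide = "CC1(C)CCCC2(C)C1CCC1(C)OC(=O)CC12",
  quinuclidinol = "OC1CN2CCC1CC2",
  tropinone = "CN1C2CCC1CC(=O)C2",
  sparteine = "C1CCN2CC3CC(C2C1)CN1CCCCC31",
  caryophyllene = "CC1=CCCC(=C)C2CC(C)(C)C2CC1",
  ambroxide = "CC1(C)CCCC2(C)C1CCC1C2(C)CCO1",
  hydrindanone = "O=C1CCC2CCCCC12",
  cineole = "CC1(C)OC2CCC1(C)CC2",
  indolizidine_diol = "OC1CCN2CCCC(O)C12",
  nortropane_ol = "OC1CC2CCC(C1)N2C",
  pinanediol = "CC1(C)C2CC1C(C)(O)C(O)C2",
  octahydroindolone = "O=C1CCC2CCNC12"
)

.TOY_DRUG <- c(
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  paracetamol = "CC(=O)Nc1ccc(O)cc1",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  sulfamethoxazole = "Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1",
  celecoxib = "Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1",
  benzamide = "NC(=O)c1ccccc1",
  nicotinamide = "NC(=O)c1cccnc1",
  diflunisal = "O=C(O)c1cc(-c2ccc(F)cc2F)ccc1O",
  naproxen_flat = "COc1ccc2cc(C(C)C(=O)O)ccc2c1",
  diazepam_like = "CN1c2ccc(Cl)cc2C(=Nc2ccccc2)CC1=O",
  sulfadiazine = "Nc1ccc(S(=O)(=O)Nc2ncccn2)cc1",
  phenytoin = "O=C1NC(=O)C(c2ccccc2)(c2ccccc2)N1",
  indomethacin = "COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1",
  quinoline_amide = "O=C(Nc1ccccc1)c1ccc2ncccc2c1",
  triazole_arene = "Clc1ccc(-n2cncn2)cc1",
  benzimidazole = "c1ccc2[nH]cnc2c1",
  biphenyl_acid = "O=C(O)c1ccc(-c2ccccc2)cc1",
  pyrimidine_amine = "Nc1ncccn1"
)

#' Packaged toy compound classes
#'
#' A small curated collection in two classes: \code{"np_like"}
#' (stereocenter-rich fused polycyclics of natural-product character,
#' including the mesembrine structure, which is the single member matching
#' the packaged AOHI pattern) and \code{"drug_like"} (flat aromatic
#' drug-like molecules). Every structure is valid; the class contrast is
#' strong enough to exercise NP-likeness training, complexity scoring and
#' enrichment counting. The seed only shuffles record order, so the content
#' is fixed.
#'
#' @param seed Integer seed used to shuffle record order.
#' @return A \linkS4class{CompoundSet} with class labels \code{np_like} and
#'   \code{drug_like}.
#' @export
genToyCompoundClasses <- function(seed = 1L) {
  smi <- c(.TOY_NP, .TOY_DRUG)
  labs <- c(rep("np_like", length(.TOY_NP)), rep("drug_like", length(.TOY_DRUG)))
  set.seed(seed)
  ord <- sample(seq_along(smi))
  compoundSet(
    unname(smi[ord]),
    ids = names(smi)[ord],
    labels = labs[ord],
    names = names(smi)[ord],
    provenance = sprintf("genToyCompoundClasses(seed=%d)", seed)
  )
}

#' Generate a synthetic MitoStress OCR trace
#'
#' Builds a four-phase trace (baseline, oligomycin, FCCP,
#' rotenone+antimycin; 3 measurements per phase, 6.5 min apart) whose phase
#' means reproduce the target respiration parameters exactly before noise.
#' The post-FCCP phase is flat, so its mean and maximum coincide.
#'
#' @param targets Named list or vector with \code{basal},
#'   \code{proton_leak}, \code{maximal} and \code{non_mitochondrial}
#'   (OCR units). \code{atp_linked} and \code{spare_capacity}, if supplied,
#'   must satisfy the identities \code{atp_linked = basal - proton_leak}
#'   and \code{spare_capacity = maximal - basal}.
#' @param noise Gaussian noise standard deviation added to every
#'   measurement (default 0).
#' @param ecarBaseline Optional flat ECAR level; omitted when NULL.
#' @param seed Integer seed (relevant only when \code{noise > 0}).
#' @return An \linkS4class{OCRTrace}.
#' @export
genOCRTrace <- function(targets, noise = 0, ecarBaseline = NULL, seed = 1L) {
  t <- as.list(targets)
  need <- c("basal", "proton_leak", "maximal", "non_mitochondrial")
  miss <- setdiff(need, names(t))
  if (length(miss)) stop("targets missing: ", paste(miss, collapse = ", "))
  tol <- 1e-8
  if (!is.null(t$atp_linked) &&
      abs(t$atp_linked - (t$basal - t$proton_leak)) > tol) {
    stop("inconsistent targets: atp_linked must equal basal - proton_leak")
  }
  if (!is.null(t$spare_capacity) &&
      abs(t$spare_capacity - (t$maximal - t$basal)) > tol) {
    stop("inconsistent targets: spare_capacity must equal maximal - basal")
  }
  perPhase <- 3L
  time <- seq(0, by = 6.5, length.out = 4 * perPhase)
  levels <- c(
    t$basal + t$non_mitochondrial,
    t$proton_leak + t$non_mitochondrial,
    t$maximal + t$non_mitochondrial,
    t$non_mitochondrial
  )
  ocr <- rep(levels, each = perPhase)
  set.seed(seed)
  if (noise > 0) ocr <- ocr + stats::rnorm(length(ocr), 0, noise)
  inj <- data.frame(
    label = c("oligomycin", "FCCP", "rotenone+antimycin"),
    time_min = time[c(3, 6, 9)] + 6.5 / 2
  )
  ecar <- if (is.null(ecarBaseline)) {
    numeric()
  } else {
    e <- rep(ecarBaseline, length(time))
    if (noise > 0) e <- e + stats::rnorm(length(time), 0, noise) else e
  }
  ocrTrace(time, ocr, ecar, inj)
}
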