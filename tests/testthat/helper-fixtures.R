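# Shared fixtures, built in code.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

# Small plate: nCtrl control wells around a fixed per-feature baseline plus
# arbitrary treatment wells supplied as a named list of value matrices
# (wells x features).
make_plate <- function(ctrl, treatments, conc = 10) {
  nFeat <- ncol(ctrl)
  featNames <- sprintf("f_%04d", seq_len(nFeat))
  colnames(ctrl) <- featNames
  rows <- list(ctrl)
  meta <- list(data.frame(
    plate_id = "P1", well_id = sprintf("c%03d", seq_len(nrow(ctrl))),
    compound_id = NA_character_, concentration_um = NA_real_,
    is_control = TRUE, stringsAsFactors = FALSE
  ))
  for (nm in names(treatments)) {
    m <- treatments[[nm]]
    colnames(m) <- featNames
    rows[[length(rows) + 1L]] <- m
    meta[[length(meta) + 1L]] <- data.frame(
      plate_id = "P1",
      well_id = sprintf("%s_w%03d", nm, seq_len(nrow(m))),
      compound_id = nm, concentration_um = conc,
      is_control = FALSE, stringsAsFactors = FALSE
    )
  }
  plateData(do.call(rbind, rows), do.call(rbind, meta))
}

# Deterministic grammar-based SMILES generator used by the complexity-score
# oracle tests: substituent + ring core + terminal substituent.
random_smiles <- function(n, seed = 1) {
  pre <- c("", "C", "CC", "CCC", "OC", "NC", "C(C)C", "OCC", "FC", "ClC")
  core <- c(
    "C1CCCCC1", "C1CCCC1", "c1ccccc1", "C1CCNCC1",
    "C1CCOCC1", "c1ccncc1", "C1CCSC1", "C1=CCCCC1"
  )
  post <- c("", "O", "N", "C", "CC", "C(=O)C", "C#N", "Cl")
  grid <- expand.grid(pre = pre, core = core, post = post,
                      stringsAsFactors = FALSE)
  smi <- unique(paste0(grid$pre, grid$core, grid$post))
  set.seed(seed)
  sample(smi, n)
}

# Simple mean silhouette of a 2-class labeling on 2D coordinates.
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  sil <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(coords)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# MitoStress trace with explicitly chosen phase levels (3 points per phase).
flat_trace <- function(levels, ecar = NULL, perPhase = 3) {
  time <- seq(0, by = 5, length.out = 4 * perPhase)
  inj <- data.frame(
    label = c("oligomycin", "FCCP", "rotenone+antimycin"),
    time_min = time[c(perPhase, 2 * perPhase, 3 * perPhase)] + 2.5
  )
  ocrTrace(
    time, rep(levels, each = perPhase),
    if (is.null(ecar)) numeric() else rep(ecar, each = perPhase),
    inj
  )
}

# Structures used by the enrichment fixtures: four distinct molecules
# containing the aryl-octahydroindole core and six that do not.
AOHI_POSITIVES <- c(
  "C1CC2(c3ccccc3)CCCCC2N1",
  "C1CC2(c3ccc(C)cc3)CCCCC2N1",
  "C1CC2(c3ccc(Cl)cc3)CCCCC2N1",
  "CN1CC[C@]2(c3ccc(OC)c(OC)c3)CC(=O)CC[C@H]12"
)
AOHI_NEGATIVES <- c(
  "c1ccccc1", "Cc1ccccc1", "C1CCCCC1", "c1ccncc1", "Oc1ccccc1", "Nc1ccccc1"
)
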