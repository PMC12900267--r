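#' @include accessors.R
NULL

#' Construct an OCRTrace
#'
#' @param time Measurement times in minutes, strictly increasing.
#' @param ocr Oxygen consumption rate per timepoint (pmol O2/min).
#' @param ecar Optional extracellular acidification rate per timepoint
#'   (mpH/min).
#' @param injections \code{data.frame} with columns \code{label} and
#'   \code{time_min}; standard MitoStress labels are \code{"compound"},
#'   \code{"oligomycin"}, \code{"FCCP"}, \code{"rotenone+antimycin"}.
#' @return An \linkS4class{OCRTrace}.
#' @export
ocrTrace <- function(time, ocr, ecar = numeric(), injections) {
  injections <- as.data.frame(injections)
  new(
    "OCRTrace",
    time = as.numeric(time), ocr = as.numeric(ocr),
    ecar = as.numeric(ecar), injections = injections
  )
}

#' Read an OCR/ECAR trace from CSV plus an injections JSON
#'
#' The CSV needs columns \code{time_min}, \code{well_id}, \code{ocr} and
#' optionally \code{ecar} (plus an ignored \code{group}); replicate wells
#' are aggregated by the mean per timepoint before the trace is built. The
#' injections file is a JSON array of \code{{"label": ..., "time_min": ...}}
#' records.
#'
#' @param path Trace CSV path.
#' @param injectionsPath Injections JSON path.
#' @return An \linkS4class{OCRTrace}.
#' @export
readOCRTrace <- function(path, injectionsPath) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(injectionsPath)) stop("file not found: ", injectionsPath)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "well_id", "ocr")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("trace CSV missing columns: ", paste(miss, collapse = ", "))
  tpts <- sort(unique(df$time_min))
  ocr <- vapply(tpts, function(t) mean(df$ocr[df$time_min == t]), numeric(1))
  ecar <- numeric()
  if ("ecar" %in% colnames(df) && !all(is.na(df$ecar))) {
    ecar <- vapply(tpts, function(t) mean(df$ecar[df$time_min == t]), numeric(1))
  }
  inj <- jsonlite::fromJSON(injectionsPath)
  ocrTrace(tpts, ocr, ecar, inj[order(inj$time_min), c("label", "time_min")])
}

# Phase index per measurement: 0 = baseline (before the first injection),
# i = strictly after injection i and at/before the next. Measurements taken
# exactly at an injection time belong to the preceding phase.
.phaseIndex <- function(trace) {
  findInterval(trace@time, trace@injections$time_min, left.open = TRUE)
}

#' Per-phase mean OCR (and ECAR)
#'
#' Phases are delimited by the injection events; phase 0 is the baseline
#' before the first injection, phase i collects measurements strictly after
#' injection i.
#'
#' @param trace An \linkS4class{OCRTrace}.
#' @return A \code{data.frame} with one row per phase: \code{phase},
#'   \code{label} (\code{"baseline"} or the preceding injection's label),
#'   \code{n}, \code{ocr_mean} and (if present) \code{ecar_mean}.
#' @export
phaseMeans <- function(trace) {
  stopifnot(is(trace, "OCRTrace"))
  idx <- .phaseIndex(trace)
  phases <- 0:nrow(trace@injections)
  labels <- c("baseline", trace@injections$label)
  n <- vapply(phases, function(p) sum(idx == p), integer(1))
  if (any(n < 1)) {
    stop(
      "phase(s) without measurements: ",
      paste(labels[n < 1], collapse = ", ")
    )
  }
  out <- data.frame(
    phase = phases,
    label = labels,
    n = n,
    ocr_mean = vapply(phases, function(p) mean(trace@ocr[idx == p]), numeric(1)),
    stringsAsFactors = FALSE
  )
  if (length(trace@ecar)) {
    out$ecar_mean <- vapply(phases, function(p) mean(trace@ecar[idx == p]), numeric(1))
  }
  out
}

#' MitoStress respiration parameters from a four-phase trace
#'
#' Applies the standard mitochondrial stress test decomposition to a trace
#' with the oligomycin / FCCP / rotenone+antimycin injection layout (an
#' optional acute compound injection before oligomycin is tolerated):
#' non-mitochondrial respiration is the final-phase mean; basal respiration
#' the last pre-oligomycin phase mean minus non-mitochondrial; proton leak
#' the post-oligomycin mean minus non-mitochondrial; ATP-linked respiration
#' is basal minus proton leak; maximal respiration the best (maximum)
#' post-FCCP measurement minus non-mitochondrial; spare capacity maximal
#' minus basal.
#'
#' @param trace An \linkS4class{OCRTrace} whose injections include
#'   \code{oligomycin}, \code{FCCP} and \code{rotenone+antimycin}.
#' @return A \linkS4class{MitoParams}.
#' @export
mitoParams <- function(trace) {
  stopifnot(is(trace, "OCRTrace"))
  labels <- trace@injections$label
  need <- c("oligomycin", "FCCP", "rotenone+antimycin")
  miss <- setdiff(need, labels)
  if (length(miss)) {
    stop("missing required injection(s): ", paste(miss, collapse = ", "))
  }
  pm <- phaseMeans(trace)
  idx <- .phaseIndex(trace)
  phaseOf <- function(lab) which(pm$label == lab)  # row index in pm
  oligoRow <- phaseOf("oligomycin")
  fccpRow <- phaseOf("FCCP")
  rotRow <- phaseOf("rotenone+antimycin")
  nonMito <- pm$ocr_mean[rotRow]
  basal <- pm$ocr_mean[oligoRow - 1] - nonMito
  leak <- pm$ocr_mean[oligoRow] - nonMito
  fccpMax <- max(trace@ocr[idx == pm$phase[fccpRow]])
  maximal <- fccpMax - nonMito
  new(
    "MitoParams",
    basal = basal,
    atp_linked = basal - leak,
    proton_leak = leak,
    maximal = maximal,
    spare_capacity = maximal - basal,
    non_mitochondrial = nonMito
  )
}

#' Acute percent change across an injection
#'
#' 100 * (post-phase mean - pre-phase mean) / pre-phase mean, computed
#' separately for OCR and (if recorded) ECAR. Captures, e.g., an acute drop
#' in respiration with a compensatory rise in glycolysis after compound
#' injection.
#'
#' @param trace An \linkS4class{OCRTrace}.
#' @param injectionLabel Label of the injection to evaluate.
#' @return Named numeric vector with \code{ocr} and optionally \code{ecar}
#'   percent changes.
#' @export
acuteChange <- function(trace, injectionLabel) {
  stopifnot(is(trace, "OCRTrace"))
  pm <- phaseMeans(trace)
  row <- which(pm$label == injectionLabel)
  if (!length(row)) stop("no injection labeled '", injectionLabel, "'")
  if (row == 1) stop("injection has no preceding phase")
  pre <- pm$ocr_mean[row - 1]
  if (pre == 0) stop("undefined percent change: pre-phase mean is 0")
  out <- c(ocr = 100 * (pm$ocr_mean[row] - pre) / pre)
  if (!is.null(pm$ecar_mean)) {
    preE <- pm$ecar_mean[row - 1]
    if (preE == 0) stop("undefined percent change: pre-phase ECAR mean is 0")
    out["ecar"] <- 100 * (pm$ecar_mean[row] - preE) / preE
  }
  out
}
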