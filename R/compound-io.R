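#' @include backend.R accessors.R
NULL

#' Construct a CompoundSet from SMILES
#'
#' Canonicalizes the structures (largest covalent fragment, stereochemistry
#' retained), drops unparseable entries with a diagnostic, and drops
#' duplicate canonical structures within the same class label with a warning.
#' The same structure may appear under different labels (a compound can be
#' both a natural product and a drug).
#'
#' @param structures Character vector of SMILES.
#' @param ids Compound identifiers; defaults to \code{cpd_0001}-style ids.
#' @param labels Class label per compound (recycled if scalar); e.g.
#'   \code{"PNP"}, \code{"MIA"}, \code{"drug"}, \code{"screening"}.
#' @param names Optional human-readable names.
#' @param provenance Free-text origin note stored with the set.
#' @param allowDuplicates Keep duplicate canonical structures within one
#'   label instead of dropping them.
#' @return A \linkS4class{CompoundSet}.
#' @examples
#' \dontrun{
#' cs <- compoundSet(c("CCO", "c1ccccc1"), labels = "toy")
#' }
#' @export
compoundSet <- function(structures, ids = NULL, labels = "unlabeled",
                        names = NA_character_, provenance = "in-memory",
                        allowDuplicates = FALSE) {
  structures <- as.character(structures)
  n <- length(structures)
  if (is.null(ids)) ids <- sprintf("cpd_%04d", seq_len(n))
  labels <- rep_len(as.character(labels), n)
  names <- rep_len(as.character(names), n)
  if (anyDuplicated(ids)) {
    stop(
      "duplicate compound ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  parsed <- canonicalizeSmiles(structures)
  skipped <- !parsed$ok
  skipMsg <- sprintf(
    "%s: %s (%s)", ids[skipped], parsed$error[skipped], structures[skipped]
  )
  rec <- DataFrame(
    compound_id = ids[!skipped],
    structure = parsed$canonical[!skipped],
    class_label = labels[!skipped],
    name = names[!skipped]
  )
  if (nrow(rec) == 0) stop("zero parseable structures")
  if (!allowDuplicates) {
    dup <- duplicated(paste(rec$class_label, rec$structure, sep = "\r"))
    if (any(dup)) {
      warning(
        "dropping ", sum(dup), " duplicate structure(s) within a label: ",
        paste(rec$compound_id[dup], collapse = ", ")
      )
      rec <- rec[!dup, , drop = FALSE]
    }
  }
  new(
    "CompoundSet",
    records = rec, provenance = provenance,
    nSkipped = sum(skipped), skippedMessages = skipMsg
  )
}

#' Read a compound collection from disk
#'
#' Supported formats: \code{smiles} (one SMILES per line, optional
#' tab-separated id and label), \code{sdf} (V2000/V3000), \code{csv}
#' (comma-separated, UTF-8, header row required). Unparseable records are
#' skipped and counted (see \code{\link{nSkipped}}); a file yielding zero
#' parseable structures is an error, as are duplicate ids.
#'
#' @param path Input file.
#' @param format One of \code{"auto"} (by extension), \code{"smiles"},
#'   \code{"sdf"}, \code{"csv"}.
#' @param structureCol,idCol,labelCol,nameCol CSV column names holding the
#'   SMILES, id, class label and name (only \code{structureCol} must exist).
#' @param label Default class label when the file carries none.
#' @inheritParams compoundSet
#' @return A \linkS4class{CompoundSet}.
#' @export
readCompounds <- function(path, format = c("auto", "smiles", "sdf", "csv"),
                          structureCol = "smiles", idCol = "compound_id",
                          labelCol = "class_label", nameCol = "name",
                          label = "unlabeled", allowDuplicates = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      sdf = "sdf", csv = "csv", smi = "smiles", smiles = "smiles", txt = "smiles",
      stop("cannot infer format from extension '", ext, "'; pass format=")
    )
  }
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("zero parseable structures in ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smi <- vapply(parts, `[`, character(1), 1)
    ids <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, character(1))
    labs <- vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, character(1))
    if (all(is.na(ids))) ids <- NULL else if (anyNA(ids)) {
      stop("mixed presence of ids in SMILES file ", path)
    }
    labs <- ifelse(is.na(labs), label, labs)
    return(compoundSet(
      smi, ids = ids, labels = labs, provenance = path,
      allowDuplicates = allowDuplicates
    ))
  }
  if (format == "sdf") {
    res <- .callBackend("sdf", list(path = normalizePath(path)))$results
    if (!length(res)) stop("zero parseable structures in ", path)
    ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
    smi <- vapply(res[ok], function(r) r$canonical, character(1))
    nms <- vapply(res[ok], function(r) if (nzchar(r$name)) r$name else NA_character_, character(1))
    if (!length(smi)) stop("zero parseable structures in ", path)
    cs <- compoundSet(
      smi,
      ids = sprintf("sdf_%04d", which(ok)), labels = label, names = nms,
      provenance = path, allowDuplicates = allowDuplicates
    )
    cs@nSkipped <- cs@nSkipped + sum(!ok)
    cs@skippedMessages <- c(
      cs@skippedMessages,
      sprintf("SDF record %d: unparseable", which(!ok))
    )
    return(cs)
  }
  # csv
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!structureCol %in% colnames(df)) {
    stop("CSV is missing the structure column '", structureCol, "'")
  }
  if (nrow(df) == 0) stop("zero parseable structures in ", path)
  ids <- if (idCol %in% colnames(df)) as.character(df[[idCol]]) else NULL
  labs <- if (labelCol %in% colnames(df)) as.character(df[[labelCol]]) else label
  nms <- if (nameCol %in% colnames(df)) as.character(df[[nameCol]]) else NA_character_
  compoundSet(
    df[[structureCol]], ids = ids, labels = labs, names = nms,
    provenance = path, allowDuplicates = allowDuplicates
  )
}

#' Write a CompoundSet to CSV
#'
#' @param x A \linkS4class{CompoundSet}.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
writeCompounds <- function(x, path) {
  stopifnot(is(x, "CompoundSet"))
  df <- as.data.frame(x@records)
  colnames(df)[colnames(df) == "structure"] <- "smiles"
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

.PLATE_META <- c("plate_id", "well_id", "compound_id", "concentration_um", "is_control")

#' Construct a PlateData object
#'
#' @param features Numeric matrix, wells x features (as on disk) with
#'   feature names as column names.
#' @param meta \code{data.frame} of well metadata with columns
#'   \code{plate_id}, \code{well_id}, \code{compound_id},
#'   \code{concentration_um}, \code{is_control}; one row per well.
#' @return A \linkS4class{PlateData} (features x wells internally).
#' @export
plateData <- function(features, meta) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("feature values must be numeric")
  if (nrow(features) != nrow(meta)) {
    stop("feature matrix and metadata disagree on well count")
  }
  miss <- setdiff(.PLATE_META, colnames(meta))
  if (length(miss)) stop("missing metadata columns: ", paste(miss, collapse = ", "))
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f_%04d", seq_len(ncol(features)))
  }
  meta$is_control <- as.logical(meta$is_control)
  meta$compound_id <- as.character(meta$compound_id)
  meta$concentration_um <- as.numeric(meta$concentration_um)
  se <- SummarizedExperiment(
    assays = list(features = t(features)),
    colData = DataFrame(meta, row.names = meta$well_id)
  )
  new("PlateData", se)
}

#' Read a plate feature table from CSV
#'
#' Expects the package's single CSV dialect: comma-separated, UTF-8, header
#' row; metadata columns \code{plate_id}, \code{well_id}, \code{compound_id},
#' \code{concentration_um}, \code{is_control}; every remaining column is a
#' numeric feature. Row order is preserved. A non-numeric feature cell is a
#' fatal error naming the offending row and column.
#'
#' @param path CSV file path.
#' @return A \linkS4class{PlateData}.
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  miss <- setdiff(.PLATE_META, colnames(df))
  if (length(miss)) stop("missing metadata columns: ", paste(miss, collapse = ", "))
  featCols <- setdiff(colnames(df), .PLATE_META)
  if (!length(featCols)) stop("no feature columns found in ", path)
  feat <- matrix(NA_real_, nrow(df), length(featCols),
                 dimnames = list(NULL, featCols))
  for (j in seq_along(featCols)) {
    raw <- df[[featCols[j]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(is.na(raw) | raw %in% c("", "NA")))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric feature value at row %d, column '%s': '%s'",
        bad[1], featCols[j], raw[bad[1]]
      ))
    }
    na <- which(is.na(val))
    if (length(na)) {
      stop(sprintf(
        "missing feature value at row %d, column '%s'", na[1], featCols[j]
      ))
    }
    feat[, j] <- val
  }
  meta <- data.frame(
    plate_id = df$plate_id,
    well_id = df$well_id,
    compound_id = ifelse(df$compound_id %in% c("", "NA"), NA_character_, df$compound_id),
    concentration_um = suppressWarnings(as.numeric(df$concentration_um)),
    is_control = as.logical(df$is_control),
    stringsAsFactors = FALSE
  )
  plateData(feat, meta)
}

#' Write a plate feature table to CSV
#'
#' Emits the dialect read back by \code{\link{readFeatureTable}}; values are
#' written at full precision (17 significant digits) so a round trip
#' reproduces them exactly.
#'
#' @param plate A \linkS4class{PlateData}.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
writeFeatureTable <- function(plate, path) {
  stopifnot(is(plate, "PlateData"))
  if (ncol(plate) == 0 || nrow(plate) == 0) stop("refusing to write an empty table")
  feat <- t(assay(plate, "features"))
  cd <- as.data.frame(colData(plate))[, .PLATE_META, drop = FALSE]
  num <- as.data.frame(feat)
  num[] <- lapply(num, function(x) sprintf("%.17g", x))
  out <- cbind(cd, num)
  ok <- tryCatch(
    {
      utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) stop("cannot write feature table to ", path)
  invisible(path)
}
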