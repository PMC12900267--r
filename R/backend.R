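#' @include AllClasses.R
NULL

# In-memory result cache: molecular perception is deterministic, so repeated
# requests within a session are served from here instead of respawning the
# interpreter.
.backendCache <- new.env(parent = emptyenv())

.pythonBin <- function() Sys.getenv("PNPWORKBENCH_PYTHON", unset = "python")

.backendScript <- function() {
  p <- system.file("python", "rdkit_backend.py", package = "PNPWorkbench")
  if (!nzchar(p)) stop("rdkit_backend.py not found in the installed package")
  p
}

#' Low-level call into the molecular perception backend
#'
#' Serializes `payload` to JSON, runs the packaged RDKit helper script in a
#' python subprocess and parses its JSON answer. All chemistry primitives
#' (parsing, atom typing, SMARTS matching, conformer geometry) flow through
#' this single choke point; results are cached per session.
#'
#' @param cmd Backend command (parse, mol, conformer, smarts, sdf).
#' @param payload Named list, serialized as the request.
#' @return Parsed JSON answer as nested lists.
#' @keywords internal
.callBackend <- function(cmd, payload) {
  input <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  key <- paste0(cmd, "\r", input)
  hit <- .backendCache[[key]]
  if (!is.null(hit)) return(hit)
  errFile <- tempfile("rdkit_backend_err_")
  on.exit(unlink(errFile), add = TRUE)
  out <- suppressWarnings(system2(
    .pythonBin(), c(.backendScript(), cmd),
    input = input, stdout = TRUE, stderr = errFile
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    err <- tryCatch(readLines(errFile), error = function(e) character())
    stop(
      "molecular backend failed (command '", cmd, "'):\n",
      paste(utils::tail(err, 10), collapse = "\n")
    )
  }
  res <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  assign(key, res, envir = .backendCache)
  res
}

#' Canonicalize SMILES strings
#'
#' Parses each string, keeps the largest covalent fragment (stripping
#' counterions), retains stereochemistry and returns the canonical form.
#' Canonicalization is idempotent: applying it to its own output returns the
#' same string.
#'
#' @param smiles Character vector of SMILES strings.
#' @param keepLargestFragment Drop all but the largest covalent fragment
#'   (default TRUE).
#' @return A \code{data.frame} with columns \code{input}, \code{ok},
#'   \code{canonical} (NA where parsing failed) and \code{error}.
#' @examples
#' \dontrun{
#' canonicalizeSmiles(c("OCC", "C("))
#' }
#' @export
canonicalizeSmiles <- function(smiles, keepLargestFragment = TRUE) {
  if (!length(smiles)) {
    return(data.frame(
      input = character(), ok = logical(),
      canonical = character(), error = character()
    ))
  }
  res <- .callBackend("parse", list(
    smiles = as.list(as.character(smiles)),
    keep_largest_fragment = keepLargestFragment
  ))$results
  data.frame(
    input = as.character(smiles),
    ok = vapply(res, function(r) isTRUE(r$ok), logical(1)),
    canonical = vapply(res, function(r) {
      if (is.null(r$canonical)) NA_character_ else r$canonical
    }, character(1)),
    error = vapply(res, function(r) {
      if (is.null(r$error)) NA_character_ else r$error
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

# Batched per-molecule perception. `what` selects sections: atoms,
# descriptors, qed, morgan. Input structures must already be valid SMILES;
# a parse failure here is a hard error because upstream construction is
# supposed to have filtered them.
.molData <- function(smiles, what, radius = 2L) {
  res <- .callBackend("mol", list(
    smiles = as.list(as.character(smiles)),
    what = as.list(what),
    radius = radius
  ))$results
  bad <- which(!vapply(res, function(r) isTRUE(r$ok), logical(1)))
  if (length(bad)) {
    stop("unparseable structures at positions: ", paste(bad, collapse = ", "))
  }
  res
}

.smartsMatch <- function(smiles, pattern) {
  res <- .callBackend("smarts", list(
    smiles = as.list(as.character(smiles)),
    pattern = pattern
  ))
  if (!isTRUE(res$ok_pattern)) stop("invalid SMARTS pattern: ", pattern)
  vapply(res$matches, isTRUE, logical(1))
}
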