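# Structure identity via the first block of the standard InChI Key.
#
# Candidates and solutions arrive as SMILES or InChI text. Both are converted
# to the standard InChI Key; two structures are considered identical when the
# first 14 characters (the connectivity "skeleton" block) agree, which makes
# the comparison insensitive to stereochemistry, tautomer/isotope layers and
# charge state. Conversion runs through a pluggable chemistry backend; the
# default backend is OpenBabel (via ChemmineOB), which produces standard
# InChI.

.detect_structure_format <- function(text) {
  if (startsWith(trimws(text), "InChI=")) "INCHI" else "SMI"
}

# In-process conversion through ChemmineOB. Used for the mol2 molecular
# graph; stereochemistry does not survive this route, so InChI generation
# goes through the obabel executable instead.
.ob_convert <- function(from, to, text) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, source = text),
                  error = function(e) "")
  out <- trimws(out)
  if (!nzchar(out)) NA_character_ else out
}

# Conversion through the obabel executable (file in, stdout out), which
# produces standard InChI and preserves stereo descriptors in SMILES input.
.ob_cli <- function(text, to) {
  fmt <- if (.detect_structure_format(text) == "INCHI") "inchi" else "smi"
  inp <- tempfile(fileext = paste0(".", fmt))
  on.exit(unlink(inp))
  writeLines(text, inp)
  out <- tryCatch(
    suppressWarnings(system2("obabel", c(inp, paste0("-o", to)),
                             stdout = TRUE, stderr = FALSE)),
    error = function(e) character(0))
  out <- trimws(out)
  out <- out[nzchar(out)]
  if (length(out) == 0L) NA_character_ else out[1]
}

#' The default chemistry backend (OpenBabel)
#'
#' A chemistry backend is a list of deterministic functions used by the
#' structure and fingerprint layers: `inchikey(text)` and `inchi(text)` accept
#' SMILES or InChI (auto-detected by the `"InChI="` prefix) and return the
#' standard InChI Key / InChI or `NA` on failure; `mol2(text)` returns a
#' Tripos mol2 block (with perceived aromaticity) used by the graph-based
#' fingerprinter. Results are memoized per backend instance. An alternative
#' toolkit can be substituted by supplying a list with the same three
#' functions.
#'
#' @return a list with elements `name`, `inchikey`, `inchi`, `mol2`.
#' @export
openbabel_backend <- function() {
  cache <- new.env(parent = emptyenv())
  memo <- function(tag, text, compute) {
    key <- paste0(tag, "\r", text)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- compute(text)
  }
  list(
    name = "openbabel",
    inchikey = function(text)
      memo("key", text, function(tx) .ob_cli(tx, "inchikey")),
    inchi = function(text)
      memo("inchi", text, function(tx) .ob_cli(tx, "inchi")),
    mol2 = function(text)
      memo("mol2", text, function(tx)
        .ob_convert(.detect_structure_format(tx), "MOL2", tx))
  )
}

#' Convert a structure string to a structure record
#'
#' Parses a SMILES or InChI string with the chemistry backend and returns the
#' standard InChI Key together with its first (skeleton) block. An unparsable
#' structure raises an error of class `idrank_structure_error` carrying the
#' offending text; callers that ingest whole candidate lists catch this and
#' flag the row instead of dropping it.
#'
#' @param text structure string (SMILES, or InChI starting `"InChI="`).
#' @param backend a chemistry backend, see [openbabel_backend()].
#' @return an object of class `structure_record`: list with `source_text`,
#'   `inchikey` (27 characters) and `skeleton_block` (first 14 characters).
#' @examples
#' \dontrun{
#' rec <- to_structure_record("CCO")
#' rec$skeleton_block  # "LFQSCWFLJHTTHZ"
#' }
#' @export
to_structure_record <- function(text, backend = openbabel_backend()) {
  stopifnot(is.character(text), length(text) == 1L)
  key <- if (nzchar(trimws(text))) backend$inchikey(text) else NA_character_
  if (is.na(key) || !grepl("^[A-Z]{14}-[A-Z]{8}[A-Z]{2}-[A-Z]$", key)) {
    stop(structure(
      class = c("idrank_structure_error", "error", "condition"),
      list(message = sprintf("structure conversion error: %s", dQuote(text)),
           call = NULL, text = text)))
  }
  structure(list(source_text = text,
                 inchikey = key,
                 skeleton_block = substr(key, 1L, 14L)),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat("<structure_record>", x$inchikey, "\n  source:", x$source_text, "\n")
  invisible(x)
}

#' Stereochemistry-insensitive structure identity
#'
#' Two structures match when the first blocks of their standard InChI Keys
#' are identical (case-sensitive). Stereoisomers therefore match; positional
#' isomers do not.
#'
#' @param candidate,solution `structure_record` objects.
#' @return `TRUE` iff the skeleton blocks are identical.
#' @export
structures_match <- function(candidate, solution) {
  stopifnot(inherits(candidate, "structure_record"),
            inherits(solution, "structure_record"))
  identical(candidate$skeleton_block, solution$skeleton_block)
}

# Vectorized skeleton-block computation over candidate payloads. Unparsable
# rows yield NA with one warning per offending payload; duplicated payloads
# are converted once.
.skeleton_blocks <- function(texts, backend) {
  uniq <- unique(texts)
  blocks <- vapply(uniq, function(tx) {
    tryCatch(to_structure_record(tx, backend)$skeleton_block,
             idrank_structure_error = function(e) {
               warning(sprintf("unparsable candidate structure %s (row kept, counted as non-matching)",
                               dQuote(tx)), call. = FALSE)
               NA_character_
             })
  }, character(1))
  unname(blocks[match(texts, uniq)])
}

# Neutral molecular formula of a structure, read from the formula layer of
# its standard InChI. Used to cross-validate declared solution formulas.
.structure_formula <- function(text, backend = openbabel_backend()) {
  inchi <- backend$inchi(text)
  if (is.na(inchi)) return(NA_character_)
  layers <- strsplit(inchi, "/", fixed = TRUE)[[1]]
  if (length(layers) < 2L) return(NA_character_)
  layers[2]
}
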