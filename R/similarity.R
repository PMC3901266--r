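# Binary-fingerprint Tanimoto similarity between candidates and the
# solution. Fingerprint computation is pluggable: the default backend is
# OpenBabel's path-based 1024-bit FP2; a CDK-compatible hashed path
# fingerprint (see cdk_fingerprint.R) reproduces the reference bitsets used
# for the published worked values.

#' Construct a binary fingerprint bitset
#'
#' Bit positions are 1-based (R convention), i.e. in `[1, width]`.
#'
#' @param on_bits integer vector of set-bit positions, unique, in
#'   `[1, width]`.
#' @param width total number of bits (default 1024).
#' @return an object of class `fingerprint_bitset`.
#' @export
fingerprint_bitset <- function(on_bits, width = 1024L) {
  on_bits <- sort(unique(as.integer(on_bits)))
  stopifnot(width >= 1L, !anyNA(on_bits),
            all(on_bits >= 1L), all(on_bits <= width))
  structure(list(width = as.integer(width), on_bits = on_bits),
            class = "fingerprint_bitset")
}

#' @export
print.fingerprint_bitset <- function(x, ...) {
  cat(sprintf("<fingerprint_bitset> %d/%d bits on\n[%s]\n",
              length(x$on_bits), x$width, paste(x$on_bits, collapse = " ")))
  invisible(x)
}

#' Tanimoto similarity of two fingerprint bitsets
#'
#' With `A` and `B` the numbers of set bits and `C` the number of common set
#' bits, `TS = C / (A + B - C)`, between 0 and 1 (1 = identical
#' fingerprints). Two empty bitsets are defined to have `TS = 0` with a
#' degenerate-input warning.
#'
#' @param a,b `fingerprint_bitset` objects of equal width.
#' @return the Tanimoto similarity.
#' @examples
#' tanimoto(fingerprint_bitset(c(301, 638, 742, 743, 930)),
#'          fingerprint_bitset(c(638, 743)))  # 0.4
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint_bitset"),
            inherits(b, "fingerprint_bitset"))
  if (a$width != b$width) {
    stop(sprintf("fingerprint width mismatch: %d vs %d", a$width, b$width),
         call. = FALSE)
  }
  A <- length(a$on_bits); B <- length(b$on_bits)
  C <- length(intersect(a$on_bits, b$on_bits))
  if (A == 0L && B == 0L) {
    warning("both fingerprints are empty; Tanimoto similarity defined as 0",
            call. = FALSE)
    return(0)
  }
  C / (A + B - C)
}

#' OpenBabel FP2 fingerprint backend
#'
#' The default similarity backend: OpenBabel's path-based 1024-bit FP2
#' fingerprint, computed in-process through ChemmineOB. A fingerprint
#' backend is a function `(structure text) -> fingerprint_bitset` that is
#' deterministic for a fixed backend version; it carries `name` and `width`
#' attributes.
#'
#' @return a fingerprint backend function.
#' @seealso [cdk_fingerprint_backend()] for the CDK-compatible adapter.
#' @export
fp2_backend <- function() {
  f <- function(text) {
    fmt <- if (startsWith(trimws(text), "InChI=")) "INCHI" else "SMILES"
    bits <- tryCatch({
      mol <- ChemmineOB::forEachMol(fmt, text, identity)
      v <- ChemmineOB::fingerprint_OB(mol, "FP2")
      which(v != 0)
    }, error = function(e) NULL)
    if (is.null(bits)) {
      stop(structure(class = c("idrank_structure_error", "error", "condition"),
                     list(message = sprintf("fingerprint failure: %s",
                                            dQuote(text)),
                          call = NULL, text = text)))
    }
    fingerprint_bitset(bits, 1024L)
  }
  attr(f, "name") <- "fp2"
  attr(f, "width") <- 1024L
  f
}

#' Fingerprint a structure record
#'
#' @param structure a `structure_record` (or a bare structure string).
#' @param backend a fingerprint backend function, see [fp2_backend()] and
#'   [cdk_fingerprint_backend()].
#' @return a `fingerprint_bitset`.
#' @export
fingerprint <- function(structure, backend = fp2_backend()) {
  text <- if (inherits(structure, "structure_record")) structure$source_text
          else structure
  backend(text)
}

#' Similarity profile of a candidate list against the solution
#'
#' Computes the Tanimoto similarity of every candidate against the solution
#' (in the supplied candidate order, conventionally sorted by descending
#' score), locates the correct candidate via skeleton-block identity, and
#' marks the most similar candidate (smallest index on ties). Candidates
#' whose structure or fingerprint cannot be computed get `NA` similarity with
#' a warning and are never the best candidate.
#'
#' @param candidates character vector of candidate structure strings, or a
#'   list of `structure_record`s.
#' @param solution a `structure_record` for the correct answer.
#' @param backend fingerprint backend (default FP2).
#' @param structure_backend chemistry backend used to locate the correct
#'   candidate.
#' @return an object of class `similarity_profile`: list with
#'   `per_candidate_ts`, `correct_index` (`NA` when absent), `best_index`,
#'   `best_ts`.
#' @export
similarity_profile <- function(candidates, solution,
                               backend = fp2_backend(),
                               structure_backend = openbabel_backend()) {
  if (length(candidates) == 0L) stop("empty candidate list", call. = FALSE)
  stopifnot(inherits(solution, "structure_record"))
  texts <- if (is.list(candidates)) {
    vapply(candidates, function(x) x$source_text, character(1))
  } else as.character(candidates)

  sol_fp <- fingerprint(solution, backend)
  uniq <- unique(texts)
  uts <- vapply(uniq, function(tx) {
    tryCatch(tanimoto(backend(tx), sol_fp),
             idrank_structure_error = function(e) {
               warning(conditionMessage(e), call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  ts <- unname(uts[match(texts, uniq)])

  blocks <- .skeleton_blocks(texts, structure_backend)
  match_idx <- which(!is.na(blocks) & blocks == solution$skeleton_block)
  correct_index <- if (length(match_idx)) match_idx[1] else NA_integer_
  best_index <- if (all(is.na(ts))) NA_integer_ else which.max(ts)
  best_ts <- if (is.na(best_index)) NA_real_ else ts[best_index]
  structure(list(per_candidate_ts = ts,
                 correct_index = correct_index,
                 best_index = best_index,
                 best_ts = best_ts),
            class = "similarity_profile")
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat(sprintf("<similarity_profile> %d candidates, best TS %.3f at %d, correct at %s\n",
              length(x$per_candidate_ts), x$best_ts, x$best_index,
              ifelse(is.na(x$correct_index), "-", x$correct_index)))
  invisible(x)
}
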