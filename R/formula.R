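# Molecular formula parsing and Hill-order canonicalization.
#
# Formula answers (Categories 1 and 3) are compared as canonical strings, so
# notation variants ("H12C6O6", "CH3CH3") must collapse to one spelling.

# IUPAC element symbols (1..118).
.ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Parse a molecular formula string
#'
#' Tokenizes a neutral molecular formula into element counts and computes the
#' canonical Hill-order spelling: carbon first, hydrogen second, all other
#' elements alphabetical; if no carbon is present, all elements alphabetical.
#' Repeated element tokens are summed (`"CH3CH3"` parses like `"C2H6"`), so
#' any permutation of the tokens yields the same canonical form.
#'
#' Charged species, adduct notation (e.g. `"[M+H]+"`), isotope labels and the
#' deuterium shorthand `"D"` are rejected: solutions and submissions must be
#' neutral molecular formulas.
#'
#' @param text a single formula string, e.g. `"C6H12O6"`.
#' @return an object of class `molecular_formula`: a list with `counts`
#'   (named integer vector, element -> count) and `canonical` (Hill-order
#'   string).
#' @examples
#' parse_formula("H12C6O6")$canonical  # "C6H12O6"
#' @seealso [formulas_equal()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("formula parse error: input must be a single non-empty string",
         call. = FALSE)
  }
  text <- trimws(text)
  bad <- regmatches(text, regexpr("[][()+\\^{}*.=-]|\\[", text))
  if (length(bad) && nzchar(bad)) {
    stop(sprintf(paste0("formula parse error in %s: character %s not ",
                        "allowed (charges, adducts and isotope labels are ",
                        "not supported; supply a neutral molecular formula)"),
                 dQuote(text), dQuote(bad)), call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (m[1] == -1 || covered != nchar(text)) {
    stop(sprintf("formula parse error: %s is not a valid formula string",
                 dQuote(text)), call. = FALSE)
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    if (!sym %in% .ELEMENT_SYMBOLS) {
      stop(sprintf("formula parse error: unknown element symbol %s in %s",
                   dQuote(sym), dQuote(text)), call. = FALSE)
    }
    n <- if (nzchar(num)) suppressWarnings(as.integer(num)) else 1L
    if (is.na(n) || n < 1L) {
      stop(sprintf("formula parse error: invalid count %s for element %s",
                   dQuote(num), dQuote(sym)), call. = FALSE)
    }
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  structure(list(counts = counts, canonical = hill_formula(counts)),
            class = "molecular_formula")
}

#' Hill-order canonical string for an element-count vector
#'
#' @param counts named integer vector (element symbol -> positive count).
#' @return the canonical formula string.
#' @keywords internal
hill_formula <- function(counts) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 1))
  syms <- names(counts)
  if ("C" %in% syms) {
    order_syms <- c("C", if ("H" %in% syms) "H",
                    sort(setdiff(syms, c("C", "H"))))
  } else {
    order_syms <- sort(syms)
  }
  paste0(order_syms,
         ifelse(counts[order_syms] == 1L, "", counts[order_syms]),
         collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula>", x$canonical, "\n")
  invisible(x)
}

#' @export
format.molecular_formula <- function(x, ...) x$canonical

#' Compare two molecular formula strings for identity
#'
#' Both inputs are parsed and canonicalized; the comparison is a plain string
#' comparison of the canonical Hill-order forms, so notation variants compare
#' equal. Parse errors propagate.
#'
#' @param a,b formula strings (or `molecular_formula` objects).
#' @return `TRUE` iff both canonical forms are identical.
#' @examples
#' formulas_equal("CH4O", "H4CO")  # TRUE
#' @export
formulas_equal <- function(a, b) {
  ca <- if (inherits(a, "molecular_formula")) a$canonical
        else parse_formula(a)$canonical
  cb <- if (inherits(b, "molecular_formula")) b$canonical
        else parse_formula(b)$canonical
  identical(ca, cb)
}
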