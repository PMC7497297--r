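# Elemental-formula parsing, formatting, and mass/RDBE arithmetic. A formula
# is represented as a named integer vector of strictly positive counts
# (zero-count entries are dropped so equality is set equality).

#' Parse a molecular formula string
#'
#' Reads a plain concatenation of element symbols with optional positive
#' integer counts, in any order (`"H2O"` and `"OH2"` parse identically).
#' Parenthesised subgroups, hydrates, charges and isotope labels are not part
#' of the supported dialect: compound-table exports in this field write
#' expanded formulas.
#'
#' @param text A single formula string, e.g. `"C9H17N3O6"`. The empty string
#'   yields the empty formula.
#' @return Named integer vector of element counts (class `elemental_formula`).
#' @examples
#' parse_formula("C9H17N3O6")
#' @seealso [format_formula()], [monoisotopic_mass()], [rdbe()]
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (is.na(text) || !nzchar(text)) {
    return(structure(integer(0), class = "elemental_formula"))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula string: '", text, "'", call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Z][a-z]?", "", tokens)
  cnts <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
  bad <- setdiff(syms, .ELEMENTS$elements)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(cnts, syms, sum)
  counts <- counts[counts > 0L]
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out, class = "elemental_formula")
}

#' @keywords internal
as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && !is.null(names(f))) {
    f <- f[f > 0]
    out <- as.integer(f)
    names(out) <- names(f)
    return(structure(out, class = "elemental_formula"))
  }
  stop("cannot interpret object as an elemental formula", call. = FALSE)
}

#' Format a formula in Hill order
#'
#' Hill convention: carbon first, then hydrogen, then the remaining elements
#' alphabetically; when no carbon is present, all elements are alphabetical.
#' `parse_formula(format_formula(f))` is the identity.
#'
#' @param f Formula (string or parsed vector).
#' @return A formula string; `""` for the empty formula.
#' @examples
#' format_formula(c(O = 1, H = 2))  # "H2O"
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  if (!length(f)) return("")
  els <- names(f)
  if ("C" %in% els) {
    ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    ord <- sort(els)
  }
  f <- f[ord]
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.elemental_formula <- function(x, ...) format_formula(x)

#' Monoisotopic mass of a formula
#'
#' Sum of per-element monoisotopic masses (most abundant isotope) weighted by
#' count, in unified atomic mass units. Additive under formula union.
#'
#' @param f Formula (string or parsed vector).
#' @return Mass in u; `0` for the empty formula.
#' @examples
#' monoisotopic_mass("H2O")        # 18.01056
#' monoisotopic_mass("C9H17N3O6")  # 263.11174 (creatine riboside)
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (!length(f)) return(0)
  sum(.ELEMENTS$mono_mass[names(f)] * as.numeric(f))
}

#' Ring-plus-double-bond equivalents (RDBE)
#'
#' Valence-derived unsaturation count using fixed common valences:
#' `C + Si - (H + F + Cl + Br + I)/2 + (N + P)/2 + 1`. Half-integer values
#' indicate an odd-electron (radical) composition; negative values are
#' chemically invalid for a neutral molecule.
#'
#' @param f Formula (string or parsed vector).
#' @return RDBE as a (possibly half-integer, possibly negative) numeric.
#' @examples
#' rdbe("C6H6")  # benzene: 4
#' @export
rdbe <- function(f) {
  f <- as_formula(f)
  cnt <- function(e) if (e %in% names(f)) as.numeric(f[[e]]) else 0
  cnt("C") + cnt("Si") -
    (cnt("H") + cnt("F") + cnt("Cl") + cnt("Br") + cnt("I")) / 2 +
    (cnt("N") + cnt("P")) / 2 + 1
}

# union of two formulas (count-wise sum), used by adduct arithmetic tests
#' @keywords internal
formula_add <- function(f1, f2) {
  f1 <- as_formula(f1); f2 <- as_formula(f2)
  els <- union(names(f1), names(f2))
  out <- vapply(els, function(e) {
    s <- 0L
    if (e %in% names(f1)) s <- s + f1[[e]]
    if (e %in% names(f2)) s <- s + f2[[e]]
    s
  }, integer(1))
  as_formula(out)
}
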