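#' @keywords internal
"_PACKAGE"

# Supported elements, in Hill order for CH-containing formulas.
ELEMENTS <- c("C", "H", "N", "O", "S", "Na")

#' Monoisotopic masses used throughout the package
#'
#' Atomic monoisotopic masses (Da) of the supported elements plus the
#' electron mass. Fixed constants: changing them changes every theoretical
#' m/z the package reports.
#'
#' @format Named numeric vector with entries `C`, `H`, `N`, `O`, `S`, `Na`
#'   and `electron`.
#' @export
ISOTOPE_MASSES <- c(
  C  = 12,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  Na = 22.98976928,
  electron = 0.00054858
)

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector over the supported
#' elements (C, H, N, O, S, Na) with non-negative counts, carrying class
#' `chem_formula`. All mass arithmetic in the package consumes this type.
#'
#' @param ... Element counts by name, e.g. `chem_formula(C = 34, H = 42, O = 19)`.
#' @return A `chem_formula` object.
#' @examples
#' chem_formula(C = 11, H = 12, O = 5)  # sinapic acid
#' @export
chem_formula <- function(...) {
  counts <- c(...)
  f <- stats::setNames(integer(length(ELEMENTS)), ELEMENTS)
  if (length(counts)) {
    bad <- setdiff(names(counts), ELEMENTS)
    if (length(bad)) {
      stop("unsupported element symbol(s): ", paste(bad, collapse = ", "))
    }
    if (any(counts < 0)) stop("element counts must be non-negative")
    f[names(counts)] <- as.integer(counts)
  }
  structure(f, class = "chem_formula")
}

as_chem_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) return(do.call(chem_formula, as.list(x)))
  stop("cannot interpret object as an elemental formula")
}

#' Parse a composition string
#'
#' Parses Hill-like notation ("C34H42O19", "CH4", "H2O") into a
#' [chem_formula()]. Element symbols are case-sensitive; an omitted count
#' means one atom; the empty string is the all-zero formula.
#'
#' @param text Composition string.
#' @return A `chem_formula`.
#' @examples
#' parse_formula("C34H42O19")
#' parse_formula("")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (!nzchar(text)) return(chem_formula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(nchar(toks)) != nchar(text)) {
    stop("cannot parse formula text: '", text, "'")
  }
  f <- stats::setNames(integer(length(ELEMENTS)), ELEMENTS)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Z][a-z]?", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% ELEMENTS) {
      stop("unsupported element symbol: '", sym, "' in '", text, "'")
    }
    f[sym] <- f[sym] + n
  }
  structure(f, class = "chem_formula")
}

#' Format a formula in canonical Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetically;
#' count 1 is implicit; zero-count elements are omitted. The all-zero
#' formula formats as `""`.
#'
#' @param f A `chem_formula` (or anything [parse_formula()] accepts).
#' @return Character scalar.
#' @export
format_formula <- function(f) {
  f <- as_chem_formula(f)
  ord <- c("C", "H", sort(setdiff(ELEMENTS, c("C", "H"))))
  parts <- vapply(ord, function(el) {
    n <- f[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  paste0(parts, collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  txt <- format_formula(x)
  cat("<chem_formula> ", if (nzchar(txt)) txt else "(empty)",
      "  [", sprintf("%.5f", monoisotopic_mass(x)), " Da]\n", sep = "")
  invisible(x)
}

#' Element-wise formula addition and subtraction
#'
#' Subtraction producing a negative count is an error (`formula_subtract`)
#' or reported by `formula_can_subtract`. Signed deltas (used by
#' biotransformation rules) are applied with [apply_delta()].
#'
#' @param a,b `chem_formula` objects.
#' @return A `chem_formula`.
#' @export
formula_add <- function(a, b) {
  a <- as_chem_formula(a); b <- as_chem_formula(b)
  structure(stats::setNames(as.integer(unclass(a) + unclass(b)), ELEMENTS),
            class = "chem_formula")
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  a <- as_chem_formula(a); b <- as_chem_formula(b)
  d <- unclass(a) - unclass(b)
  if (any(d < 0)) {
    stop("subtraction yields negative count for: ",
         paste(ELEMENTS[d < 0], collapse = ", "))
  }
  structure(stats::setNames(as.integer(d), ELEMENTS), class = "chem_formula")
}

#' @rdname formula_add
#' @export
formula_can_subtract <- function(a, b) {
  a <- as_chem_formula(a); b <- as_chem_formula(b)
  all(unclass(a) - unclass(b) >= 0)
}

#' Is `a` an element-wise sub-formula of `b`?
#' @param a,b `chem_formula` objects.
#' @return Logical scalar.
#' @export
is_subformula <- function(a, b) formula_can_subtract(b, a)

#' Apply a signed element-count delta to a formula
#'
#' @param f A `chem_formula`.
#' @param delta Named numeric vector of signed counts (names in
#'   C,H,N,O,S,Na), e.g. `c(C = -1, H = -2)` for demethylation.
#' @return A `chem_formula`, or `NULL` if any count would go negative.
#' @export
apply_delta <- function(f, delta) {
  f <- as_chem_formula(f)
  d <- stats::setNames(numeric(length(ELEMENTS)), ELEMENTS)
  bad <- setdiff(names(delta), ELEMENTS)
  if (length(bad)) stop("unsupported element symbol(s) in delta: ",
                        paste(bad, collapse = ", "))
  d[names(delta)] <- delta
  out <- unclass(f) + d
  if (any(out < 0)) return(NULL)
  structure(stats::setNames(as.integer(out), ELEMENTS), class = "chem_formula")
}

#' Monoisotopic mass of a formula
#'
#' Sum of count times most-abundant-isotope mass over the supported
#' elements. Additive over [formula_add()].
#'
#' @param f A `chem_formula` (or parseable string).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C34H42O19")  # DISS, 754.23203
#' @export
monoisotopic_mass <- function(f) {
  f <- as_chem_formula(f)
  sum(unclass(f) * ISOTOPE_MASSES[ELEMENTS])
}

#' Ring-double-bond equivalents
#'
#' RDB = C + 1 - (H + Na)/2 + N/2, computed on the neutral formula
#' (adduct atoms excluded). Oxygen and sulfur contribute nothing; sodium
#' is counted monovalent like hydrogen. Values are integers or
#' half-integers.
#'
#' @param f A `chem_formula` (or parseable string).
#' @return RDB value (possibly half-integer, possibly negative for
#'   impossible compositions).
#' @examples
#' rdbe("C34H42O19")  # 14
#' rdbe("CH4")        # 0
#' @export
rdbe <- function(f) {
  f <- as_chem_formula(f)
  f[["C"]] + 1 - (f[["H"]] + f[["Na"]]) / 2 + f[["N"]] / 2
}
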