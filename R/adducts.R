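# ESI adduct arithmetic: singly charged even-electron ions only, with
# explicit electron-mass correction (proton = H - e-, sodiated = +Na - e-).

ADDUCTS <- list(
  "[M+H]+" = list(name = "[M+H]+",  charge = +1L,
                  atoms = c(H = 1),  electron_delta = -1L),
  "[M-H]-" = list(name = "[M-H]-",  charge = -1L,
                  atoms = c(H = -1), electron_delta = +1L),
  "[M+Na]+" = list(name = "[M+Na]+", charge = +1L,
                  atoms = c(Na = 1), electron_delta = -1L)
)

# Accept the typographic minus sign used in print.
normalize_adduct_name <- function(name) {
  gsub("−", "-", name)
}

#' Supported ESI adducts
#'
#' @return Character vector of adduct names: `[M+H]+`, `[M-H]-`, `[M+Na]+`.
#' @export
supported_adducts <- function() names(ADDUCTS)

get_adduct <- function(name) {
  name <- normalize_adduct_name(name)
  spec <- ADDUCTS[[name]]
  if (is.null(spec)) {
    stop("unknown adduct '", name, "'; supported: ",
         paste(names(ADDUCTS), collapse = ", "))
  }
  spec
}

# Mass added to the neutral molecule by the adduct, including the
# electron correction (e.g. +1.00727646 for [M+H]+).
adduct_mass_shift <- function(adduct) {
  spec <- if (is.list(adduct)) adduct else get_adduct(adduct)
  atoms <- spec$atoms
  sum(ISOTOPE_MASSES[names(atoms)] * atoms) +
    spec$electron_delta * ISOTOPE_MASSES[["electron"]]
}

#' Theoretical m/z of an adduct ion
#'
#' m/z = (neutral mass + adduct atom mass - electron_delta * m_e) / |charge|.
#' All supported adducts are singly charged, so the result is the ion mass.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct Adduct name (`"[M+H]+"`, `"[M-H]-"`, `"[M+Na]+"`).
#' @return Ion m/z in Th.
#' @examples
#' adduct_mz(monoisotopic_mass("C34H42O19"), "[M+Na]+")  # 777.22125
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass > 0))
  spec <- get_adduct(adduct)
  (neutral_mass + adduct_mass_shift(spec)) / abs(spec$charge)
}

#' Neutral mass deduced from an adduct ion m/z
#'
#' Exact inverse of [adduct_mz()] for singly charged ions.
#'
#' @param mz Ion m/z (> 0).
#' @param adduct Adduct name.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass_from_adduct <- function(mz, adduct) {
  stopifnot(is.numeric(mz), all(mz > 0))
  spec <- get_adduct(adduct)
  mz * abs(spec$charge) - adduct_mass_shift(spec)
}

#' Ion composition of a neutral formula under an adduct
#'
#' The atom inventory of the observed ion, e.g. C34H42O19 under
#' `[M+Na]+` gives C34H42O19Na; under `[M-H]-` gives C34H41O19.
#'
#' @param f Neutral `chem_formula` (or string).
#' @param adduct Adduct name.
#' @return A `chem_formula` of the ion's atoms.
#' @export
ion_composition <- function(f, adduct) {
  f <- as_chem_formula(f)
  spec <- get_adduct(adduct)
  out <- apply_delta(f, spec$atoms)
  if (is.null(out)) stop("adduct ", spec$name,
                         " cannot be formed from ", format_formula(f))
  out
}

#' m/z of an explicit ion atom inventory
#'
#' For a singly charged ion whose atoms are given explicitly (e.g. the
#' sinapoyl anion C11H9O4): cation m/z = mass - m_e, anion m/z =
#' mass + m_e.
#'
#' @param f Ion atom inventory (`chem_formula` or string).
#' @param charge `+1L` or `-1L`.
#' @return Ion m/z in Th.
#' @export
ion_mz_from_composition <- function(f, charge) {
  stopifnot(charge %in% c(-1L, 1L))
  monoisotopic_mass(f) - charge * ISOTOPE_MASSES[["electron"]]
}

#' Signed parts-per-million mass error
#'
#' 1e6 * (measured - theoretical) / theoretical; a measured value above
#' theory gives a positive error.
#'
#' @param measured,theoretical m/z values; `theoretical` must be > 0.
#' @return Signed ppm error.
#' @examples
#' ppm_error(777.22101, adduct_mz(monoisotopic_mass("C34H42O19"), "[M+Na]+"))
#' @export
ppm_error <- function(measured, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * (measured - theoretical) / theoretical
}

#' Nominal (nearest-integer) mass shift between two ions
#'
#' Used for reasoning like "206 Da lower than the sodium adduct of the
#' parent".
#'
#' @param mz_a,mz_b m/z values.
#' @return Integer Da difference, `round(mz_a - mz_b)`.
#' @examples
#' nominal_shift(777.22101, 571.16290)  # 206
#' @export
nominal_shift <- function(mz_a, mz_b) {
  as.integer(round(mz_a - mz_b))
}
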