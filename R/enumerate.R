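# Molecular-formula enumeration under element-count, RDB and ppm
# constraints (the formula-predictor settings used for Orbitrap data:
# C 0-50, H 0-100, O 0-50, N 0-5, S 0-5, RDB 0-15, 5 ppm).

#' Element and RDB bounds for formula enumeration
#'
#' Defaults are the formula-predictor settings used for the DISS study:
#' C 0-50, H 0-100, O 0-50, N 0-5, S 0-5, Na 0, RDB 0-15, tolerance
#' 5 ppm. No valence heuristics beyond the RDB range are applied.
#'
#' @param C,H,N,O,S,Na Length-2 integer vectors `c(min, max)`.
#' @param rdb Length-2 numeric `c(min, max)` RDB range.
#' @param tol_ppm Mass tolerance in ppm (> 0).
#' @return An `element_bounds` list.
#' @export
element_bounds <- function(C = c(0, 50), H = c(0, 100), N = c(0, 5),
                           O = c(0, 50), S = c(0, 5), Na = c(0, 0),
                           rdb = c(0, 15), tol_ppm = 5) {
  b <- list(C = C, H = H, N = N, O = O, S = S, Na = Na,
            rdb = rdb, tol_ppm = tol_ppm)
  for (el in ELEMENTS) {
    v <- b[[el]]
    if (length(v) != 2L || v[1] > v[2] || v[1] < 0)
      stop("bad bounds for ", el)
  }
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  structure(b, class = "element_bounds")
}

#' Enumerate molecular formulas matching a neutral mass
#'
#' Returns every formula inside `bounds` whose monoisotopic mass lies
#' within `bounds$tol_ppm` of `target_neutral_mass` and whose RDB lies in
#' the RDB range, sorted by absolute ppm error (ties by Hill-notation
#' text). Exhaustive over the bounded lattice: heavy elements are
#' enumerated directly and the hydrogen count is solved from the residual
#' mass window, which is exact because H is the lightest element.
#'
#' @param target_neutral_mass Neutral mass in Da (> 0).
#' @param bounds An [element_bounds()] object.
#' @return A data.frame with columns `formula` (Hill text), `mass`,
#'   `ppm`, `rdb`, zero rows if nothing matches.
#' @examples
#' enumerate_formulas(224.06847, element_bounds())  # contains C11H12O5
#' @export
enumerate_formulas <- function(target_neutral_mass, bounds = element_bounds()) {
  if (!inherits(bounds, "element_bounds")) stop("bounds must be element_bounds()")
  if (bounds$tol_ppm <= 0) stop("tol_ppm must be > 0")
  empty <- data.frame(formula = character(), mass = numeric(),
                      ppm = numeric(), rdb = numeric(),
                      stringsAsFactors = FALSE)
  if (target_neutral_mass <= 0) return(empty)

  tol_da <- target_neutral_mass * bounds$tol_ppm * 1e-6
  lo <- target_neutral_mass - tol_da
  hi <- target_neutral_mass + tol_da
  m <- ISOTOPE_MASSES

  # Cap heavy-element counts by the mass window, then enumerate the grid.
  cap <- function(el) min(bounds[[el]][2], floor(hi / m[[el]]))
  grid <- expand.grid(C = bounds$C[1]:cap("C"),
                      N = bounds$N[1]:cap("N"),
                      O = bounds$O[1]:cap("O"),
                      S = bounds$S[1]:cap("S"),
                      Na = bounds$Na[1]:max(bounds$Na[1], cap("Na")),
                      KEEP.OUT.ATTRS = FALSE)
  base <- grid$C * m[["C"]] + grid$N * m[["N"]] + grid$O * m[["O"]] +
    grid$S * m[["S"]] + grid$Na * m[["Na"]]
  keep <- base <= hi
  grid <- grid[keep, , drop = FALSE]
  base <- base[keep]
  if (!nrow(grid)) return(empty)

  h_lo <- pmax(bounds$H[1], ceiling((lo - base) / m[["H"]] - 1e-9))
  h_hi <- pmin(bounds$H[2], floor((hi - base) / m[["H"]] + 1e-9))
  rows <- which(h_lo <= h_hi)
  out <- vector("list", length(rows))
  k <- 0L
  for (i in rows) {
    for (h in h_lo[i]:h_hi[i]) {
      mass <- base[i] + h * m[["H"]]
      if (mass < lo || mass > hi) next
      rdb <- grid$C[i] + 1 - (h + grid$Na[i]) / 2 + grid$N[i] / 2
      if (rdb < bounds$rdb[1] || rdb > bounds$rdb[2]) next
      k <- k + 1L
      out[[k]] <- data.frame(
        formula = format_formula(chem_formula(
          C = grid$C[i], H = h, N = grid$N[i], O = grid$O[i],
          S = grid$S[i], Na = grid$Na[i])),
        mass = mass,
        ppm = ppm_error(target_neutral_mass, mass),
        rdb = rdb,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty)
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(abs(res$ppm), res$formula), , drop = FALSE]
  rownames(res) <- NULL
  res
}
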