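# MS2 fragment annotation: element-wise sub-formulas of the precursor
# ion, even-electron by default with whitelisted CH3-radical losses, and
# canonical neutral-loss labelling.

# Canonical neutral-loss dictionary (composition text -> label).
NEUTRAL_LOSSES <- c(
  "H2O"      = "H2O",
  "CO"       = "CO",
  "CO2"      = "CO2",
  "CH3"      = "CH3",
  "CH2O"     = "CH2O",
  "CH4O"     = "CH3OH",
  "C6H10O5"  = "C6H10O5",
  "C11H10O4" = "C11H10O4"
)

#' Canonical label for a neutral-loss composition
#'
#' @param loss A `chem_formula` (or string) lost between precursor and
#'   fragment.
#' @return The dictionary label (e.g. `"H2O"`, `"CH3OH"`) or `NA` when
#'   the composition is not in the dictionary.
#' @export
neutral_loss_label <- function(loss) {
  key <- format_formula(as_chem_formula(loss))
  hit <- match(key, names(NEUTRAL_LOSSES))
  if (is.na(hit)) NA_character_ else unname(NEUTRAL_LOSSES[hit])
}

# Even-electron test for a singly charged ion atom inventory: with H and
# Na monovalent, an even-electron ion has half-integer ring-double-bond
# value; integer RDB marks a radical (odd-electron) ion.
is_even_electron_ion <- function(f) {
  r <- rdbe(f)
  abs((r * 2) %% 2 - 1) < 1e-9
}

# All element-wise sub-formulas of an ion composition with their ion m/z
# for the given charge sign; cached per call via a plain data.frame.
subformula_grid <- function(ion_comp, charge) {
  f <- unclass(ion_comp)
  grids <- lapply(ELEMENTS, function(el) 0:f[[el]])
  names(grids) <- ELEMENTS
  g <- do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE))
  mass <- as.matrix(g) %*% ISOTOPE_MASSES[ELEMENTS]
  g$mz <- as.numeric(mass) - charge * ISOTOPE_MASSES[["electron"]]
  g$rdb_ion <- g$C + 1 - (g$H + g$Na) / 2 + g$N / 2
  g
}

#' Annotate MS2 peaks with precursor sub-formulas and neutral losses
#'
#' For each peak, every element-wise sub-formula of the precursor ion
#' inventory whose ion m/z (same polarity) lies within `frag_tol_ppm` is
#' considered; the smallest absolute ppm wins. Candidates must be
#' even-electron ions (half-integer ion RDB) unless `allow_radical` is
#' set, in which case odd-electron fragments are admitted when the loss
#' from the precursor can contain a methyl radical (at least CH3).
#' The complementary composition is reported as the neutral loss, with a
#' canonical label when it matches the loss dictionary.
#'
#' @param precursor_formula Neutral formula of the precursor (object or
#'   string).
#' @param adduct Precursor adduct name.
#' @param peaks Data.frame with columns `mz` and `intensity` (relative,
#'   base peak 100).
#' @param frag_tol_ppm Fragment tolerance, default 10 ppm.
#' @param allow_radical Permit CH3-radical-type odd-electron fragments
#'   (default TRUE).
#' @return Data.frame: `mz`, `intensity`, `formula` (assigned ion
#'   composition, NA if unassigned), `ppm`, `neutral_loss`,
#'   `loss_label`, `status` (`assigned`/`unassigned`).
#' @export
annotate_fragments <- function(precursor_formula, adduct, peaks,
                               frag_tol_ppm = 10, allow_radical = TRUE) {
  stopifnot(frag_tol_ppm > 0)
  spec <- get_adduct(adduct)
  ion <- ion_composition(precursor_formula, adduct)
  grid <- subformula_grid(ion, spec$charge)

  even <- abs((grid$rdb_ion * 2) %% 2 - 1) < 1e-9
  # Radical fragments: the complementary loss must be able to carry CH3.
  ionc <- unclass(ion)
  radical_ok <- allow_radical &
    (ionc[["C"]] - grid$C >= 1) & (ionc[["H"]] - grid$H >= 3)
  eligible <- (grid$rdb_ion >= -0.5) & (even | radical_ok)

  out <- data.frame(mz = peaks$mz, intensity = peaks$intensity,
                    formula = NA_character_, ppm = NA_real_,
                    neutral_loss = NA_character_,
                    loss_label = NA_character_,
                    status = "unassigned", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    tol_da <- peaks$mz[i] * frag_tol_ppm * 1e-6
    hit <- which(eligible & abs(grid$mz - peaks$mz[i]) <= tol_da)
    if (!length(hit)) next
    pp <- ppm_error(peaks$mz[i], grid$mz[hit])
    best <- hit[which.min(abs(pp))]
    frag <- chem_formula(C = grid$C[best], H = grid$H[best],
                         N = grid$N[best], O = grid$O[best],
                         S = grid$S[best], Na = grid$Na[best])
    loss <- formula_subtract(ion, frag)
    out$formula[i] <- format_formula(frag)
    out$ppm[i] <- pp[which.min(abs(pp))]
    out$neutral_loss[i] <- format_formula(loss)
    out$loss_label[i] <- neutral_loss_label(loss)
    out$status[i] <- "assigned"
  }
  out
}

#' Audit the printed fragment-formula assignments of the fixture
#'
#' For every fragment printed with an ion composition, reports whether
#' that composition is an element-wise sub-formula of its precursor ion
#' inventory and whether its theoretical ion m/z falls within
#' `tol_ppm` of the printed fragment m/z. Violations are listed, never
#' corrected: several printed assignments are impossible sub-formulas of
#' their precursors and are flagged as such.
#'
#' @param features Fixture feature table (needs `feature_id`, `formula`,
#'   `adduct`, `polarity`).
#' @param fragments Fixture fragment table (needs `feature_id`, `mz`,
#'   `printed_formula`; `-` or NA marks peaks printed without one).
#' @param tol_ppm Mass agreement tolerance, default 10 ppm.
#' @return Data.frame: `feature_id`, `mz`, `printed_formula`,
#'   `subformula_ok`, `ppm`, `mass_ok`, `consistent`.
#' @export
validate_printed_fragments <- function(features, fragments, tol_ppm = 10) {
  frags <- fragments[!is.na(fragments$printed_formula) &
                       fragments$printed_formula != "-", , drop = FALSE]
  if (!nrow(frags)) {
    return(data.frame(feature_id = character(), mz = numeric(),
                      printed_formula = character(),
                      subformula_ok = logical(), ppm = numeric(),
                      mass_ok = logical(), consistent = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(frags)), function(i) {
    fid <- frags$feature_id[i]
    feat <- features[features$feature_id == fid, , drop = FALSE]
    if (nrow(feat) != 1L) stop("fragment references unknown feature: ", fid)
    spec <- get_adduct(feat$adduct)
    ion <- ion_composition(feat$formula, feat$adduct)
    frag <- parse_formula(frags$printed_formula[i])
    sub_ok <- is_subformula(frag, ion)
    theo <- ion_mz_from_composition(frag, spec$charge)
    pp <- ppm_error(frags$mz[i], theo)
    data.frame(feature_id = fid, mz = frags$mz[i],
               printed_formula = frags$printed_formula[i],
               subformula_ok = sub_ok, ppm = pp,
               mass_ok = abs(pp) <= tol_ppm,
               consistent = sub_ok && abs(pp) <= tol_ppm,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
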