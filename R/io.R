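# Readers and writers for the package's plain-text dialects: tab-
# delimited feature/identification tables with '#' comment lines, and
# MGF peak lists. m/z serializes to 5 decimals, ppm to 3.

read_table_file <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  miss <- setdiff(required, names(tab))
  if (length(miss)) stop("missing required column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  tab
}

#' Read an MS1 feature table
#'
#' Tab-delimited with header; required columns `feature_id`, `rt_min`,
#' `polarity`, `adduct`, `mz`. Extra columns (matrix codes, formulas,
#' provenance) pass through as character. Malformed rows (non-numeric or
#' non-positive m/z, negative RT, adduct/polarity mismatch) are rejected
#' with their row numbers.
#'
#' @param path File path.
#' @return Data.frame of features.
#' @export
read_feature_table <- function(path) {
  tab <- read_table_file(path, c("feature_id", "rt_min", "polarity",
                                 "adduct", "mz"))
  if (nrow(tab) == 0L) {
    tab$rt_min <- numeric(); tab$mz <- numeric()
    return(tab)
  }
  rt <- suppressWarnings(as.numeric(tab$rt_min))
  mz <- suppressWarnings(as.numeric(tab$mz))
  tab$adduct <- normalize_adduct_name(tab$adduct)
  pol_of <- vapply(tab$adduct, function(a) {
    if (!a %in% supported_adducts()) NA_character_
    else if (get_adduct(a)$charge > 0) "+" else "-"
  }, character(1))
  bad <- which(is.na(mz) | mz <= 0 | is.na(rt) | rt < 0 |
                 is.na(pol_of) | pol_of != tab$polarity)
  if (length(bad)) {
    stop("malformed feature row(s) at line(s): ",
         paste(bad, collapse = ", "),
         " (require mz > 0, rt_min >= 0, known adduct matching polarity)")
  }
  tab$rt_min <- rt
  tab$mz <- mz
  tab
}

#' Write a feature table
#'
#' @param features Data.frame of features.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  if ("mz" %in% names(out)) out$mz <- sprintf("%.5f", out$mz)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed writing feature table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read an MGF tandem-spectra file
#'
#' BEGIN IONS / END IONS blocks with `TITLE` (used as the feature key),
#' `PEPMASS`, `CHARGE` (`1+`/`1-`) and `mz intensity` peak lines. Peak
#' intensities are normalized so the base peak is 100.
#'
#' @param path File path.
#' @return Named list (by TITLE) of lists with `pepmass`, `charge`,
#'   `peaks` (data.frame `mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  spectra <- list()
  i <- 1L; block <- 0L
  n <- length(lines)
  while (i <= n) {
    if (lines[i] != "BEGIN IONS") { i <- i + 1L; next }
    block <- block + 1L
    title <- NULL; pepmass <- NULL; charge <- NA_character_
    mzs <- numeric(); ints <- numeric()
    i <- i + 1L
    closed <- FALSE
    while (i <= n) {
      ln <- lines[i]
      if (ln == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (startsWith(ln, "TITLE=")) title <- substring(ln, 7)
      else if (startsWith(ln, "PEPMASS=")) {
        pepmass <- as.numeric(strsplit(substring(ln, 9), "[ \t]")[[1]][1])
      } else if (startsWith(ln, "CHARGE=")) charge <- substring(ln, 8)
      else if (grepl("^[0-9]", ln)) {
        xy <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
        mzs <- c(mzs, xy[1]); ints <- c(ints, xy[2])
      }
      i <- i + 1L
    }
    if (!closed) stop("unterminated MGF block #", block)
    if (is.null(pepmass) || is.na(pepmass)) {
      stop("MGF block #", block, " lacks PEPMASS")
    }
    if (is.null(title)) title <- paste0("spectrum_", block)
    peaks <- data.frame(mz = mzs, intensity = ints)
    if (nrow(peaks) && max(peaks$intensity) > 0) {
      peaks$intensity <- 100 * peaks$intensity / max(peaks$intensity)
    }
    spectra[[title]] <- list(pepmass = pepmass, charge = charge,
                             peaks = peaks)
  }
  spectra
}

#' Write spectra to MGF
#'
#' @param spectra Named list as returned by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (title in names(spectra)) {
    sp <- spectra[[title]]
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", title),
                 paste0("PEPMASS=", sprintf("%.5f", sp$pepmass)),
                 paste0("CHARGE=", sp$charge)), con)
    if (nrow(sp$peaks)) {
      writeLines(sprintf("%.5f %.4f", sp$peaks$mz, sp$peaks$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Write / read the identification table
#'
#' Columnar output mirroring the published summary-table schema:
#' metabolite label, consensus RT, formula, theoretical neutral mass,
#' per-adduct ppm, reaction path, distribution codes. Ordering is
#' deterministic: RT then label.
#'
#' @param identifications Identification data.frame (from
#'   [assign_candidates()] or [run_full_pipeline()]).
#' @param path Output path.
#' @return `path` invisibly (`write_identification_table`); the
#'   data.frame (`read_identification_table`).
#' @export
write_identification_table <- function(identifications, path) {
  out <- identifications
  out <- out[order(out$rt_min, out$label %||% out$group), , drop = FALSE]
  for (col in intersect(c("rt_min"), names(out))) {
    out[[col]] <- sprintf("%.2f", out[[col]])
  }
  for (col in intersect(c("theoretical_mass"), names(out))) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.5f", as.numeric(out[[col]])))
  }
  for (col in intersect(c("mean_abs_ppm"), names(out))) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.3f", as.numeric(out[[col]])))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed writing identification table to ", path,
                        ": ", conditionMessage(ok))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_identification_table
#' @export
read_identification_table <- function(path) {
  tab <- read_table_file(path, character())
  for (col in intersect(c("rt_min", "theoretical_mass", "mean_abs_ppm"),
                        names(tab))) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  for (col in intersect(c("group", "depth", "n_features"), names(tab))) {
    tab[[col]] <- suppressWarnings(as.integer(tab[[col]]))
  }
  tab
}

#' Run the full identification pipeline
#'
#' Grouping, rule closure, candidate assignment, optional MS2 fragment
#' annotation, network construction, and (when per-group matrix-code
#' columns are present) the tissue-distribution differential report.
#' Deterministic given its inputs.
#'
#' @param features Feature data.frame ([read_feature_table()] shape).
#' @param spectra Optional named list of MS2 spectra keyed by feature id.
#' @param parent Parent compound formula (default DISS, C34H42O19).
#' @param rules Biotransformation catalog.
#' @param tol_ppm MS1 candidate tolerance (default 5 ppm).
#' @param frag_tol_ppm MS2 fragment tolerance (default 10 ppm).
#' @param group_tol_ppm Cross-polarity neutral-mass grouping tolerance
#'   (default 10 ppm).
#' @param rt_tol_min Grouping RT tolerance (default 0.2 min).
#' @param max_depth Closure depth (default 8).
#' @return List: `features` (grouped), `closure`, `candidates`,
#'   `identifications`, `network`, `fragment_annotations` (NULL without
#'   spectra), `differential` (NULL without matrix-code columns).
#' @export
run_full_pipeline <- function(features, spectra = NULL,
                              parent = "C34H42O19",
                              rules = default_rules(), tol_ppm = 5,
                              frag_tol_ppm = 10, group_tol_ppm = 10,
                              rt_tol_min = 0.2, max_depth = 8) {
  if (nrow(features) == 0L) {
    return(list(features = features, closure = NULL,
                candidates = NULL,
                identifications = data.frame(),
                network = list(nodes = data.frame(), edges = data.frame()),
                fragment_annotations = NULL, differential = NULL))
  }
  grouped <- group_features(features, group_tol_ppm, rt_tol_min)
  closure <- rule_closure(parent, rules, max_depth)
  assigned <- assign_candidates(grouped, closure, tol_ppm)
  ids <- assigned$identifications
  ids$theoretical_mass <- vapply(ids$formula, function(f) {
    if (is.na(f)) NA_real_ else monoisotopic_mass(f)
  }, numeric(1))
  net <- build_network(ids, parent, rules)

  frag_ann <- NULL
  if (!is.null(spectra)) {
    frag_ann <- list()
    for (fid in intersect(names(spectra), grouped$feature_id)) {
      row <- grouped[grouped$feature_id == fid, , drop = FALSE]
      g <- row$group[1]
      idrow <- ids[ids$group == g, , drop = FALSE]
      if (idrow$status[1] != "identified") next
      frag_ann[[fid]] <- annotate_fragments(idrow$formula[1],
                                            row$adduct[1],
                                            spectra[[fid]]$peaks,
                                            frag_tol_ppm)
    }
  }

  differential <- NULL
  if (all(c("metabolite", "sham", "model") %in% names(grouped))) {
    differential <- differential_report(distribution_records(grouped))
  }
  list(features = grouped, closure = closure,
       candidates = assigned$candidates, identifications = ids,
       network = net, fragment_annotations = frag_ann,
       differential = differential)
}
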