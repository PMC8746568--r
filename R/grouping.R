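# Cross-polarity feature grouping and candidate-formula assignment.

#' Group MS1 features into putative metabolites
#'
#' Single-linkage partition: two features link iff their deduced neutral
#' masses agree within `mass_tol_ppm` (relative to the pair mean) and
#' their retention times differ by at most `rt_tol_min`. This merges
#' dual-polarity detections of one metabolite while keeping co-formula
#' positional isomers with distinct retention times apart.
#'
#' @param features Data.frame with columns `feature_id`, `rt_min`,
#'   `polarity`, `adduct`, `mz` (extra columns pass through).
#' @param mass_tol_ppm Neutral-mass agreement tolerance (default 10 ppm).
#' @param rt_tol_min Retention-time tolerance in minutes (default 0.2).
#' @return The input with added columns `neutral_mass` and `group`
#'   (integer ids ordered by group mean retention time, ties by mass).
#' @export
group_features <- function(features, mass_tol_ppm = 10, rt_tol_min = 0.2) {
  stopifnot(mass_tol_ppm > 0, rt_tol_min > 0)
  need <- c("feature_id", "rt_min", "adduct", "mz")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("features missing column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(features)
  features$neutral_mass <- vapply(seq_len(n), function(i) {
    neutral_mass_from_adduct(features$mz[i], features$adduct[i])
  }, numeric(1))
  if (n == 0L) {
    features$group <- integer()
    return(features)
  }

  # Union-find over all linked pairs.
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  ord <- order(features$neutral_mass)
  m <- features$neutral_mass[ord]
  rt <- features$rt_min[ord]
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      dm <- m[b] - m[a]
      if (1e6 * dm / ((m[a] + m[b]) / 2) > mass_tol_ppm) break
      if (abs(rt[b] - rt[a]) <= rt_tol_min) union(ord[a], ord[b])
    }
    if (a + 1 > n) break
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, unique(roots))
  grp_rt <- tapply(features$rt_min, comp, mean)
  grp_mass <- tapply(features$neutral_mass, comp, mean)
  relabel <- match(seq_along(grp_rt), order(grp_rt, grp_mass))
  features$group <- relabel[comp]
  features
}

#' Assign candidate formulas from a biotransformation closure to groups
#'
#' A closure member is a candidate for a group when its theoretical
#' adduct m/z lies within `tol_ppm` of *every* member feature's measured
#' m/z. Candidates are ranked by biotransformation depth (fewer steps
#' preferred), then mean absolute ppm. The top candidate is the group's
#' identification; groups with none are reported `unidentified`.
#' Metabolites sharing a top formula are suffix-labelled by retention
#' time rank (earlier elution, lower suffix).
#'
#' @param grouped Output of [group_features()].
#' @param closure A [rule_closure()] result.
#' @param tol_ppm MS1 tolerance, default 5 ppm.
#' @return List with `candidates` (all candidates per group, ranked) and
#'   `identifications` (one row per group: `group`, `rt_min`,
#'   `formula`, `depth`, `path`, `mean_abs_ppm`, `n_features`,
#'   `status`, `label`).
#' @export
assign_candidates <- function(grouped, closure, tol_ppm = 5) {
  stopifnot(tol_ppm > 0)
  if (nrow(closure) == 0L) stop("closure is empty")
  cl_formulas <- lapply(closure$formula, parse_formula)
  cl_mass <- vapply(cl_formulas, monoisotopic_mass, numeric(1))

  groups <- sort(unique(grouped$group))
  cand_rows <- list()
  id_rows <- list()
  for (g in groups) {
    sub <- grouped[grouped$group == g, , drop = FALSE]
    # ppm of each member's measured m/z against each closure formula.
    ok <- rep(TRUE, nrow(closure))
    ppm_mat <- matrix(NA_real_, nrow(closure), nrow(sub))
    for (j in seq_len(nrow(sub))) {
      theo <- adduct_mz(cl_mass, sub$adduct[j])
      ppm_mat[, j] <- ppm_error(sub$mz[j], theo)
      ok <- ok & abs(ppm_mat[, j]) <= tol_ppm
    }
    idx <- which(ok)
    rt <- mean(sub$rt_min)
    if (length(idx)) {
      mean_abs <- rowMeans(abs(ppm_mat[idx, , drop = FALSE]))
      o <- order(closure$depth[idx], mean_abs, closure$formula[idx])
      idx <- idx[o]; mean_abs <- mean_abs[o]
      cand_rows[[length(cand_rows) + 1L]] <- data.frame(
        group = g, rank = seq_along(idx),
        formula = closure$formula[idx], depth = closure$depth[idx],
        path = closure$path[idx], mean_abs_ppm = mean_abs,
        stringsAsFactors = FALSE)
      id_rows[[length(id_rows) + 1L]] <- data.frame(
        group = g, rt_min = rt,
        formula = closure$formula[idx[1]], depth = closure$depth[idx[1]],
        path = closure$path[idx[1]], mean_abs_ppm = mean_abs[1],
        n_features = nrow(sub), status = "identified",
        stringsAsFactors = FALSE)
    } else {
      id_rows[[length(id_rows) + 1L]] <- data.frame(
        group = g, rt_min = rt,
        formula = NA_character_, depth = NA_integer_,
        path = NA_character_, mean_abs_ppm = NA_real_,
        n_features = nrow(sub), status = "unidentified",
        stringsAsFactors = FALSE)
    }
  }
  ids <- do.call(rbind, id_rows)
  rownames(ids) <- NULL
  # Isomer labels: formula, suffixed by RT rank when shared.
  ids$label <- ids$formula
  for (f in unique(stats::na.omit(ids$formula))) {
    sel <- which(!is.na(ids$formula) & ids$formula == f)
    if (length(sel) > 1L) {
      rk <- rank(ids$rt_min[sel], ties.method = "first")
      ids$label[sel] <- paste0(f, " (isomer ", rk, ")")
    }
  }
  list(
    candidates = if (length(cand_rows)) do.call(rbind, cand_rows) else
      data.frame(group = integer(), rank = integer(), formula = character(),
                 depth = integer(), path = character(),
                 mean_abs_ppm = numeric(), stringsAsFactors = FALSE),
    identifications = ids
  )
}
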