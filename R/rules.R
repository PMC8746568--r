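# Biotransformation rules: named signed element-count deltas applied
# during candidate generation (phase-I style chemistry: de/methylation,
# demethoxylation, redox, (de)hydration, ester and glycosidic cleavage).

#' Read a biotransformation-rule catalog
#'
#' Tab-delimited text with header `name  delta  class`; `delta` is a
#' signed composition such as `-CH2` or `+H2O` (one sign for the whole
#' rule: a rule is a pure loss or a pure gain). Lines starting with `#`
#' are comments.
#'
#' @param path File path.
#' @return A `biotransformation_rules` data.frame with columns `name`,
#'   `delta` (text), `class`, `direction`, and a list column `delta_counts`
#'   of signed named vectors.
#' @export
read_rules <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("name", "delta", "class")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("rule catalog missing column(s): ",
                         paste(miss, collapse = ", "))
  as_rules(tab)
}

#' Build a rule catalog from a data.frame
#'
#' @param tab Data.frame with character columns `name`, `delta` (signed
#'   composition, e.g. `-CH2`), `class`.
#' @return A `biotransformation_rules` data.frame.
#' @export
as_rules <- function(tab) {
  if (anyDuplicated(tab$name)) stop("duplicate rule names in catalog")
  tab$direction <- ifelse(startsWith(tab$delta, "-"), "loss", "gain")
  tab$delta_counts <- lapply(tab$delta, parse_signed_delta)
  class(tab) <- c("biotransformation_rules", "data.frame")
  tab
}

parse_signed_delta <- function(text) {
  sign <- 1
  body <- text
  if (startsWith(text, "-")) { sign <- -1; body <- substring(text, 2) }
  else if (startsWith(text, "+")) { body <- substring(text, 2) }
  f <- parse_formula(body)
  counts <- unclass(f) * sign
  counts[counts != 0]
}

#' The default DISS biotransformation catalog
#'
#' Formula deltas covering the reaction classes seen for sucrose
#' di-esters of sinapic acid: de/methylation (±CH2), demethoxylation
#' (−CH2O), reduction/dehydrogenation (±H2), hydroxylation/
#' dehydroxylation (±O), hydration/dehydration (±H2O), sinapoyl ester
#' cleavage (−C11H10O4), glycosidic anhydrohexose loss (−C6H10O5) and
#' C7H6 loss. Shipped as `extdata/rules_default.tsv`.
#'
#' @return A `biotransformation_rules` data.frame.
#' @export
default_rules <- function() {
  path <- system.file("extdata", "rules_default.tsv", package = "dissmet")
  if (!nzchar(path)) stop("packaged rule catalog not found")
  read_rules(path)
}

#' Breadth-first biotransformation closure from a parent formula
#'
#' All formulas reachable from `parent` by at most `max_depth` rule
#' applications, deduplicated by formula keeping the shortest path
#' (ties broken by the lexicographically earliest rule-name sequence).
#' Element counts never go negative (such applications are skipped) and
#' are capped by `ceilings` to keep gain chains bounded.
#'
#' @param parent Parent `chem_formula` or composition string.
#' @param rules A rule catalog ([default_rules()] shape).
#' @param max_depth Maximum number of rule applications (>= 0).
#' @param ceilings Named integer vector of per-element maxima. Default:
#'   parent count + 2 for C, N, O, S, Na and parent count + 6 for H
#'   (hydrogen rises two atoms per reduction; chains of up to three
#'   reductions are admitted).
#' @return A `rule_closure` data.frame with columns `formula` (Hill
#'   text), `depth`, `path` (rule names joined by `;`, empty for the
#'   parent), sorted by depth then formula. Attributes `parent` and
#'   `rules` record the inputs.
#' @export
rule_closure <- function(parent, rules = default_rules(), max_depth = 8,
                         ceilings = NULL) {
  parent <- as_chem_formula(parent)
  stopifnot(max_depth >= 0)
  if (is.null(ceilings)) {
    ceilings <- unclass(parent) + c(C = 2L, H = 6L, N = 2L, O = 2L,
                                    S = 2L, Na = 2L)[ELEMENTS]
  }
  if (nrow(rules) == 0L && max_depth > 0) {
    warning("empty rule catalog: closure is the parent alone")
  }

  key <- function(f) format_formula(f)
  seen <- new.env(parent = emptyenv())
  pk <- key(parent)
  assign(pk, list(formula = parent, depth = 0L, path = character()),
         envir = seen)
  frontier <- stats::setNames(list(list(formula = parent, path = character())), pk)
  depth <- 0L
  rule_order <- order(rules$name)

  while (depth < max_depth && length(frontier)) {
    depth <- depth + 1L
    candidates <- list()   # key -> list of candidate paths at this depth
    for (node in frontier) {
      for (ri in rule_order) {
        child <- apply_delta(node$formula, rules$delta_counts[[ri]])
        if (is.null(child) || sum(unclass(child)) == 0L) next
        if (any(unclass(child) > ceilings)) next
        ck <- key(child)
        if (exists(ck, envir = seen, inherits = FALSE)) next
        cand <- list(formula = child,
                     path = c(node$path, rules$name[[ri]]))
        candidates[[ck]] <- c(candidates[[ck]], list(cand))
      }
    }
    frontier <- list()
    for (ck in names(candidates)) {
      alts <- candidates[[ck]]
      if (length(alts) > 1L) {
        keys <- vapply(alts, function(a) paste(a$path, collapse = "\001"),
                       character(1))
        alts <- alts[order(keys)]
      }
      best <- alts[[1L]]
      assign(ck, list(formula = best$formula, depth = depth,
                      path = best$path), envir = seen)
      frontier[[ck]] <- best
    }
  }

  keys <- ls(envir = seen)
  recs <- lapply(keys, get, envir = seen)
  out <- data.frame(
    formula = keys,
    depth = vapply(recs, function(r) r$depth, integer(1)),
    path = vapply(recs, function(r) paste(r$path, collapse = ";"),
                  character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$depth, out$formula), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "parent") <- format_formula(parent)
  attr(out, "rules") <- rules
  class(out) <- c("rule_closure", "data.frame")
  out
}

#' Replay a rule path from a parent formula
#'
#' @param parent Parent formula (object or string).
#' @param path Character vector of rule names (or `;`-joined string).
#' @param rules Rule catalog.
#' @return The resulting `chem_formula`; errors if a step is inapplicable.
#' @export
replay_path <- function(parent, path, rules = default_rules()) {
  f <- as_chem_formula(parent)
  if (length(path) == 1L && grepl(";", path)) {
    path <- strsplit(path, ";", fixed = TRUE)[[1]]
  }
  path <- path[nzchar(path)]
  for (nm in path) {
    i <- match(nm, rules$name)
    if (is.na(i)) stop("unknown rule: ", nm)
    f2 <- apply_delta(f, rules$delta_counts[[i]])
    if (is.null(f2)) stop("rule '", nm, "' not applicable to ",
                          format_formula(f))
    f <- f2
  }
  f
}

#' Label the reaction linking a parent to a candidate metabolite
#'
#' Shortest rule path from `parent_f` to `child_f` within the
#' depth-limited closure, or `"unexplained"` if none exists.
#'
#' @param parent_f,child_f Formulas (objects or strings).
#' @param rules Rule catalog.
#' @param max_depth Closure depth limit.
#' @return List with `status` (`"explained"`/`"unexplained"`), `path`
#'   (character vector of rule names, empty for identity) and `depth`.
#' @export
label_reaction <- function(parent_f, child_f, rules = default_rules(),
                           max_depth = 8) {
  child_key <- format_formula(as_chem_formula(child_f))
  cl <- rule_closure(parent_f, rules, max_depth)
  i <- match(child_key, cl$formula)
  if (is.na(i)) {
    return(list(status = "unexplained", path = character(), depth = NA_integer_))
  }
  path <- strsplit(cl$path[i], ";", fixed = TRUE)[[1]]
  list(status = "explained", path = path[nzchar(path)], depth = cl$depth[i])
}
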