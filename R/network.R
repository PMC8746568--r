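# Metabolic-network construction from identified reaction paths.

#' Build the metabolic network from identifications
#'
#' One node per identified metabolite plus, where a reaction path has
#' more than one step, virtual intermediate nodes (marked unobserved,
#' keyed and merged by formula). One directed edge per rule application
#' along each record's path from the parent.
#'
#' @param identifications Identification table
#'   ([assign_candidates()]`$identifications` shape) with columns
#'   `formula`, `path`, `status` and a node id column (`label` used when
#'   present, else `group`).
#' @param parent Parent formula (object or string).
#' @param rules Rule catalog used to replay paths.
#' @return List of two data.frames: `nodes` (`id`, `formula`,
#'   `observed`) and `edges` (`from`, `to`, `rule`).
#' @export
build_network <- function(identifications, parent = "C34H42O19",
                          rules = default_rules()) {
  parent <- as_chem_formula(parent)
  parent_key <- format_formula(parent)
  ids <- identifications[identifications$status == "identified", , drop = FALSE]
  node_id <- if ("label" %in% names(ids)) ids$label else as.character(ids$group)

  nodes <- data.frame(id = character(), formula = character(),
                      observed = logical(), stringsAsFactors = FALSE)
  edges <- data.frame(from = character(), to = character(),
                      rule = character(), stringsAsFactors = FALSE)
  add_node <- function(id, formula, observed) {
    if (id %in% nodes$id) {
      if (observed) nodes$observed[nodes$id == id] <<- TRUE
      return(invisible())
    }
    nodes <<- rbind(nodes, data.frame(id = id, formula = formula,
                                      observed = observed,
                                      stringsAsFactors = FALSE))
  }
  # Observed node for the parent formula, if identified.
  parent_node <- node_id[match(parent_key, ids$formula)]
  if (is.na(parent_node)) parent_node <- parent_key
  add_node(parent_node, parent_key, !is.na(match(parent_key, ids$formula)))

  for (i in seq_len(nrow(ids))) {
    path <- strsplit(ids$path[i], ";", fixed = TRUE)[[1]]
    path <- path[nzchar(path)]
    if (!length(path)) next
    f <- parent
    prev <- parent_node
    for (k in seq_along(path)) {
      ri <- match(path[k], rules$name)
      if (is.na(ri)) stop("unknown rule in path: ", path[k])
      f <- apply_delta(f, rules$delta_counts[[ri]])
      if (is.null(f)) stop("path of ", node_id[i], " not replayable")
      fk <- format_formula(f)
      last <- k == length(path)
      nid <- if (last) node_id[i] else {
        # Virtual intermediate: reuse an observed node with this formula
        # if one exists, else a formula-keyed unobserved node.
        obs <- node_id[match(fk, ids$formula)]
        if (!is.na(obs)) obs else fk
      }
      add_node(nid, fk, last || nid %in% node_id)
      if (!any(edges$from == prev & edges$to == nid & edges$rule == path[k])) {
        edges <- rbind(edges, data.frame(from = prev, to = nid,
                                         rule = path[k],
                                         stringsAsFactors = FALSE))
      }
      prev <- nid
    }
  }
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
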