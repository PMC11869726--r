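## Per-document synthesis graphs and extraction of convergent routes.
##
## Molecules are nodes; a directed edge runs from a product to each of its
## reactants (retrosynthetic direction). No separate reaction nodes are kept
## at this stage. A cleaned, weakly connected component with at least one
## common intermediate shared by two or more targets is a convergent route.

#' Construct a synthesis graph
#'
#' @param edges Data frame with character columns `parent` (product) and
#'   `child` (reactant). Repeated edges are collapsed.
#' @param nodes Optional character vector of node keys; defaults to the
#'   union of the edge endpoints.
#' @param document_ids Provenance document identifier(s).
#' @param id Optional route identifier.
#' @return An object of class `synthesis_graph`: list with `nodes`, `edges`,
#'   `roles` (named list, filled by [assign_roles()]) and provenance fields.
#' @export
synthesis_graph <- function(edges, nodes = NULL, document_ids = character(0),
                            id = NULL) {
  edges <- unique(data.frame(parent = as.character(edges$parent),
                             child = as.character(edges$child),
                             stringsAsFactors = FALSE))
  if (is.null(nodes)) nodes <- union(edges$parent, edges$child)
  structure(list(nodes = nodes, edges = edges, roles = NULL,
                 document_ids = document_ids, id = id),
            class = "synthesis_graph")
}

#' @export
print.synthesis_graph <- function(x, ...) {
  cat("<synthesis_graph", if (!is.null(x$id)) paste0(" ", x$id) else "", ": ",
      length(x$nodes), " molecules, ", nrow(x$edges), " reactions",
      if (!is.null(x$roles)) paste0(", ", sum(vapply(x$roles, function(r)
        "target" %in% r, logical(1))), " targets") else "",
      ">\n", sep = "")
  invisible(x)
}

sg_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = data.frame(name = graph$nodes))
}

#' Build the retrosynthetic graph of one document
#'
#' Adds one `product -> reactant` edge per reactant of every record;
#' repeated identical edges collapse.
#'
#' @param records Rows of a `reaction_corpus` sharing one `document_id`.
#' @return A `synthesis_graph` (roles unassigned).
#' @export
build_document_graph <- function(records) {
  if (nrow(records) == 0L) {
    return(synthesis_graph(data.frame(parent = character(0), child = character(0))))
  }
  doc <- unique(records$document_id)
  if (length(doc) > 1L) stop("records span multiple documents: ",
                             paste(doc, collapse = ", "))
  parent <- rep(records$product, lengths(records$reactants))
  child <- unlist(records$reactants, use.names = FALSE)
  synthesis_graph(data.frame(parent = parent, child = child,
                             stringsAsFactors = FALSE),
                  document_ids = doc)
}

#' Split a synthesis graph into weakly connected components
#'
#' @param graph A `synthesis_graph`.
#' @return List of `synthesis_graph` objects, one per weakly connected
#'   component, in order of each component's lexicographically smallest
#'   node.
#' @export
split_components <- function(graph) {
  if (length(graph$nodes) == 0L) return(list())
  g <- sg_igraph(graph)
  comp <- igraph::components(g, mode = "weak")
  member <- split(names(comp$membership), comp$membership)
  member <- member[order(vapply(member, min, character(1)))]
  lapply(member, function(nodes) {
    keep <- graph$edges$parent %in% nodes | graph$edges$child %in% nodes
    synthesis_graph(graph$edges[keep, , drop = FALSE], nodes = sort(nodes),
                    document_ids = graph$document_ids, id = graph$id)
  })
}

#' Assign molecule roles within a synthesis graph
#'
#' A node with no incoming edges is a target; a node with no outgoing edges
#' is a building block; a node with more than one incoming edge that is
#' reachable from at least two distinct targets is a common intermediate (a
#' building block can simultaneously be a common intermediate). Remaining
#' nodes are plain intermediates.
#'
#' @param graph A `synthesis_graph`.
#' @return The graph with its `roles` field set (named list of role
#'   character vectors per node).
#' @export
assign_roles <- function(graph) {
  g <- sg_igraph(graph)
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  targets <- names(indeg)[indeg == 0]
  reach_count <- rep(0L, length(graph$nodes))
  names(reach_count) <- igraph::V(g)$name
  if (length(targets)) {
    d <- igraph::distances(g, v = targets, mode = "out")
    reach_count <- colSums(is.finite(d))
  }
  roles <- lapply(igraph::V(g)$name, function(v) {
    r <- character(0)
    if (indeg[v] == 0) r <- c(r, "target")
    if (outdeg[v] == 0) r <- c(r, "building_block")
    if (indeg[v] > 1 && reach_count[v] >= 2) r <- c(r, "common_intermediate")
    if (length(r) == 0L) r <- "intermediate"
    r
  })
  names(roles) <- igraph::V(g)$name
  graph$roles <- roles[graph$nodes]
  graph
}

#' Role accessors for a role-assigned synthesis graph
#'
#' @param graph A `synthesis_graph` after [assign_roles()].
#' @return Character vector of molecule keys holding the role.
#' @export
graph_targets <- function(graph) {
  stopifnot(!is.null(graph$roles))
  names(graph$roles)[vapply(graph$roles, function(r) "target" %in% r, logical(1))]
}

#' @rdname graph_targets
#' @export
graph_common_intermediates <- function(graph) {
  stopifnot(!is.null(graph$roles))
  names(graph$roles)[vapply(graph$roles, function(r) "common_intermediate" %in% r,
                            logical(1))]
}

#' @rdname graph_targets
#' @export
graph_building_blocks <- function(graph) {
  stopifnot(!is.null(graph$roles))
  names(graph$roles)[vapply(graph$roles, function(r) "building_block" %in% r,
                            logical(1))]
}

#' Tally reaction directions over a whole corpus
#'
#' Counts, over every record of the corpus, how often each ordered
#' (product, reactant) pair occurs. Used to resolve direction conflicts.
#'
#' @param corpus A `reaction_corpus`.
#' @return Named integer vector; names are `parent\r child` pairs.
#' @export
tally_directions <- function(corpus) {
  parent <- rep(corpus$product, lengths(corpus$reactants))
  child <- unlist(corpus$reactants, use.names = FALSE)
  tab <- table(paste(parent, child, sep = "\r"))
  stats::setNames(as.integer(tab), names(tab))
}

#' Resolve conflicting reaction directions within a graph
#'
#' When both orientations of a molecule pair occur as edges, the orientation
#' with the strictly higher corpus-wide count is kept and the other dropped.
#' If the counts tie the direction cannot be resolved and the whole graph is
#' discarded.
#'
#' @param graph A `synthesis_graph`.
#' @param direction_counts Corpus-wide tally from [tally_directions()].
#' @return The graph with losing orientations removed, or `NULL` when any
#'   conflict is unresolvable.
#' @export
resolve_directions <- function(graph, direction_counts) {
  e <- graph$edges
  fwd <- paste(e$parent, e$child, sep = "\r")
  rev <- paste(e$child, e$parent, sep = "\r")
  conflict <- which(rev %in% fwd)
  if (!length(conflict)) return(graph)
  drop <- logical(nrow(e))
  for (i in conflict) {
    cf <- direction_counts[fwd[i]]
    cr <- direction_counts[rev[i]]
    cf <- if (is.na(cf)) 0L else cf
    cr <- if (is.na(cr)) 0L else cr
    if (cf == cr) return(NULL)
    if (cf < cr) drop[i] <- TRUE
  }
  synthesis_graph(e[!drop, , drop = FALSE], nodes = graph$nodes,
                  document_ids = graph$document_ids, id = graph$id)
}

#' Canonical hash of a synthesis graph
#'
#' Order-independent identity used for exact-structure deduplication: the
#' sorted list of canonical `(parent, child)` edges.
#'
#' @param graph A `synthesis_graph`.
#' @return A single character key.
#' @export
graph_hash <- function(graph) {
  paste(sort(paste(graph$edges$parent, graph$edges$child, sep = ">")),
        collapse = "|")
}

#' Filter role-assigned components down to clean convergent routes
#'
#' Retains a graph only when it is acyclic, contains at least one common
#' intermediate, has at least two targets that are not mere stereoisomers of
#' one another, and is not an exact duplicate of an already retained graph.
#'
#' @param graphs List of `synthesis_graph` components (roles may be missing;
#'   they are assigned on the fly for acyclic graphs).
#' @return List with `routes` (retained graphs, roles assigned) and
#'   `discards` (tibble of `reason`, `n`).
#' @export
filter_convergent <- function(graphs) {
  retained <- list()
  seen <- character(0)
  reasons <- character(0)
  for (graph in graphs) {
    g <- sg_igraph(graph)
    if (!igraph::is_dag(g)) { reasons <- c(reasons, "cycle"); next }
    if (is.null(graph$roles)) graph <- assign_roles(graph)
    if (length(graph_common_intermediates(graph)) == 0L) {
      reasons <- c(reasons, "no_common_intermediate"); next
    }
    targets <- graph_targets(graph)
    stereo_free <- vapply(targets, function(t)
      tryCatch(standardize_stereo_free(t), error = function(e) strip_stereo(t)),
      character(1))
    if (length(unique(stereo_free)) < 2L) {
      reasons <- c(reasons, "stereoisomer_targets"); next
    }
    h <- graph_hash(graph)
    if (h %in% seen) { reasons <- c(reasons, "duplicate"); next }
    seen <- c(seen, h)
    retained <- c(retained, list(graph))
  }
  tab <- if (length(reasons)) {
    as.data.frame(table(reason = reasons), stringsAsFactors = FALSE)
  } else data.frame(reason = character(0), Freq = integer(0))
  names(tab) <- c("reason", "n")
  list(routes = retained, discards = tibble::as_tibble(tab))
}

#' Extract the convergent routes dataset from a reaction corpus
#'
#' Full pipeline: per-document graphs, weakly connected components,
#' corpus-wide direction resolution (before cycle detection, so a two-cycle
#' born of direction ambivalence is distinguished from a genuine reaction
#' cycle), role assignment, and convergence filtering with per-reason
#' discard accounting.
#'
#' @param corpus A `reaction_corpus` (see [load_corpus()]).
#' @return List with `routes` (retained `synthesis_graph`s, ids assigned),
#'   `summary` (tibble of discard reasons and the retained count) and
#'   `stats` (per-route statistics tibble, see [route_stats()]).
#' @export
extract_convergent_routes <- function(corpus) {
  counts <- tally_directions(corpus)
  components <- list()
  unresolved <- 0L
  for (doc in unique(corpus$document_id)) {
    records <- corpus[corpus$document_id == doc, , drop = FALSE]
    doc_graph <- build_document_graph(records)
    for (comp in split_components(doc_graph)) {
      res <- resolve_directions(comp, counts)
      if (is.null(res)) { unresolved <- unresolved + 1L; next }
      ## dropping edges can disconnect the component
      parts <- split_components(res)
      parts <- Filter(function(p) nrow(p$edges) > 0L, parts)
      components <- c(components, parts)
    }
  }
  filtered <- filter_convergent(components)
  routes <- filtered$routes
  if (length(routes)) {
    for (i in seq_along(routes)) routes[[i]]$id <- sprintf("route-%04d", i)
  }
  discards <- filtered$discards
  if (unresolved > 0L) {
    discards <- rbind(discards,
                      tibble::tibble(reason = "unresolved_direction", n = unresolved))
  }
  summary <- rbind(discards,
                   tibble::tibble(reason = "retained", n = length(routes)))
  list(routes = routes, summary = summary, stats = route_stats(routes))
}

#' Per-route summary statistics
#'
#' One row per convergent route: counts of targets, common intermediates,
#' building blocks, molecules and reactions, the maximum and mean (over
#' targets) longest path length in reaction steps, mean reactants per
#' reaction, and targets per common intermediate.
#'
#' @param routes List of role-assigned `synthesis_graph`s.
#' @return A tibble.
#' @export
route_stats <- function(routes) {
  rows <- lapply(routes, function(graph) {
    g <- sg_igraph(graph)
    targets <- graph_targets(graph)
    cis <- graph_common_intermediates(graph)
    depth_per_target <- vapply(targets, function(t) {
      ## longest path from target in a DAG: negate unit weights
      d <- -igraph::distances(g, v = t, mode = "out",
                              weights = rep(-1, nrow(graph$edges)))
      max(d[is.finite(d)])
    }, numeric(1))
    n_reactions <- length(unique(graph$edges$parent))
    targets_per_ci <- if (length(cis)) {
      d <- igraph::distances(g, v = targets, to = cis, mode = "out")
      mean(colSums(is.finite(d)))
    } else NA_real_
    tibble::tibble(
      route_id = if (is.null(graph$id)) NA_character_ else graph$id,
      document_ids = paste(graph$document_ids, collapse = ";"),
      n_targets = length(targets),
      n_common_intermediates = length(cis),
      n_building_blocks = length(graph_building_blocks(graph)),
      n_molecules = length(graph$nodes),
      n_reactions = n_reactions,
      depth_max = max(depth_per_target),
      depth_mean = mean(depth_per_target),
      reactants_per_reaction = nrow(graph$edges) / n_reactions,
      targets_per_intermediate = targets_per_ci
    )
  })
  if (!length(rows)) {
    return(tibble::tibble(route_id = character(0), document_ids = character(0),
                          n_targets = integer(0), n_common_intermediates = integer(0),
                          n_building_blocks = integer(0), n_molecules = integer(0),
                          n_reactions = integer(0), depth_max = numeric(0),
                          depth_mean = numeric(0), reactants_per_reaction = numeric(0),
                          targets_per_intermediate = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Write a convergent routes dataset to JSON
#'
#' One JSON object per route: `route_id`, `document_ids`, `nodes` (with
#' `smiles` and `roles`) and `edges` as `[parent, child]` pairs.
#'
#' @param routes List of role-assigned `synthesis_graph`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_routes_json <- function(routes, path) {
  payload <- lapply(routes, function(graph) {
    list(route_id = graph$id,
         document_ids = as.list(graph$document_ids),
         nodes = lapply(graph$nodes, function(v)
           list(smiles = v, roles = as.list(graph$roles[[v]]))),
         edges = lapply(seq_len(nrow(graph$edges)), function(i)
           list(graph$edges$parent[i], graph$edges$child[i])))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a convergent routes dataset from JSON
#'
#' Inverse of [write_routes_json()].
#'
#' @param path JSON file written by [write_routes_json()].
#' @return List of role-assigned `synthesis_graph`s.
#' @export
read_routes_json <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(rt) {
    edges <- data.frame(
      parent = vapply(rt$edges, function(e) e[[1]], character(1)),
      child = vapply(rt$edges, function(e) e[[2]], character(1)),
      stringsAsFactors = FALSE)
    nodes <- vapply(rt$nodes, `[[`, character(1), "smiles")
    graph <- synthesis_graph(edges, nodes = nodes,
                             document_ids = unlist(rt$document_ids),
                             id = rt$route_id)
    graph$roles <- stats::setNames(
      lapply(rt$nodes, function(n) unlist(n$roles)), nodes)
    graph
  })
}
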