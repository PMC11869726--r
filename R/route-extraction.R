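## Route extraction from a finished search graph: prune to building-block
## terminated chemistry, seed complete convergent routes from the
## best-scoring building blocks, rank and summarize to molecule-only DAGs.

copy_search_graph <- function(graph) {
  g <- new.env(parent = emptyenv())
  g$mol <- list2env(as.list(graph$mol, all.names = TRUE), parent = emptyenv())
  g$rxn <- list2env(as.list(graph$rxn, all.names = TRUE), parent = emptyenv())
  g$mol_rxns <- list2env(as.list(graph$mol_rxns, all.names = TRUE), parent = emptyenv())
  g$mol_in <- list2env(as.list(graph$mol_in, all.names = TRUE), parent = emptyenv())
  g$stock <- graph$stock
  g$targets <- graph$targets
  g$config <- graph$config
  g$pruned <- graph$pruned
  class(g) <- "search_graph"
  g
}

remove_reaction <- function(g, rid) {
  rx <- g$rxn[[rid]]
  if (is.null(rx)) return(invisible())
  rm(list = rid, envir = g$rxn)
  p <- rx$parent
  if (!is.null(g$mol_rxns[[p]])) {
    left <- setdiff(g$mol_rxns[[p]], rid)
    if (length(left)) assign(p, left, envir = g$mol_rxns) else rm(list = p, envir = g$mol_rxns)
  }
  for (k in rx$children) {
    if (!is.null(g$mol_in[[k]])) {
      left <- setdiff(g$mol_in[[k]], rid)
      if (length(left)) assign(k, left, envir = g$mol_in) else rm(list = k, envir = g$mol_in)
    }
  }
  invisible()
}

remove_molecule <- function(g, m) {
  for (rid in mol_children(g, m)) remove_reaction(g, rid)
  if (!is.null(g$mol_rxns[[m]])) rm(list = m, envir = g$mol_rxns)
  if (!is.null(g$mol_in[[m]])) rm(list = m, envir = g$mol_in)
  rm(list = m, envir = g$mol)
  invisible()
}

#' Prune a search graph to building-block terminated chemistry
#'
#' Iteratively removes invalidated reaction nodes, reaction nodes missing
#' any of their reactant molecules (a reaction needs all of its reactants),
#' molecule leaves that are neither building blocks nor targets, and
#' anything no longer reachable from a target, until a fixpoint. Unsolved
#' targets are kept as bare roots. The input graph is not modified.
#'
#' @param graph A `search_graph`.
#' @return A pruned copy in which every non-target leaf is a building block.
#' @export
prune_unsolvable <- function(graph) {
  g <- copy_search_graph(graph)
  repeat {
    changed <- FALSE
    for (rid in reaction_ids(g)) {
      rx <- g$rxn[[rid]]
      broken <- !rx$valid ||
        any(vapply(rx$children, function(k) is.null(g$mol[[k]]), logical(1)))
      if (broken) { remove_reaction(g, rid); changed <- TRUE }
    }
    for (m in molecule_keys(g)) {
      node <- g$mol[[m]]
      if (!node$is_bb && !node$is_target && length(mol_children(g, m)) == 0L) {
        remove_molecule(g, m); changed <- TRUE
      }
    }
    ## drop everything no longer reachable from a target
    reach <- new.env(parent = emptyenv())
    queue <- g$targets[vapply(g$targets, function(t) !is.null(g$mol[[t]]), logical(1))]
    for (t in queue) assign(t, TRUE, envir = reach)
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (rid in mol_children(g, cur)) {
        for (k in g$rxn[[rid]]$children) {
          if (is.null(reach[[k]])) {
            assign(k, TRUE, envir = reach)
            queue <- c(queue, k)
          }
        }
      }
    }
    for (m in molecule_keys(g)) {
      if (is.null(reach[[m]])) { remove_molecule(g, m); changed <- TRUE }
    }
    if (!changed) break
  }
  g$pruned <- TRUE
  g
}

#' Score the building blocks of a pruned search graph
#'
#' Applies the end-node scoring rule (maximum path product per reaching
#' target, averaged over reaching targets) with each building block as the
#' end node. A target that is itself in stock scores 1 through the empty
#' path product.
#'
#' @param graph A pruned `search_graph`.
#' @return Named numeric vector, one score per building block.
#' @export
score_building_blocks <- function(graph) {
  keys <- molecule_keys(graph)
  bbs <- keys[vapply(keys, function(k) isTRUE(graph$mol[[k]]$is_bb), logical(1))]
  if (!length(bbs)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(score_nodes(graph, bbs), bbs)
}

## Greedy best sub-route below each molecule: the reaction child maximizing
## probability times the best sub-routes of its reactants. NULL = unsolvable.
best_subroute <- function(g, m, memo) {
  hit <- memo[[m]]
  if (!is.null(hit)) return(if (identical(hit, list(unsolvable = TRUE))) NULL else hit)
  node <- g$mol[[m]]
  res <- NULL
  if (isTRUE(node$is_bb)) {
    res <- list(log = 0, rid = NA_character_)
  } else {
    best <- NULL
    for (rid in sort(mol_children(g, m))) {
      rx <- g$rxn[[rid]]
      if (!rx$valid) next
      subs <- lapply(rx$children, function(k) best_subroute(g, k, memo))
      if (any(vapply(subs, is.null, logical(1)))) next
      val <- rx$logprob + sum(vapply(subs, `[[`, numeric(1), "log"))
      if (is.null(best) || val > best$log) best <- list(log = val, rid = rid)
    }
    res <- best
  }
  assign(m, if (is.null(res)) list(unsolvable = TRUE) else res, envir = memo)
  res
}

## All viable reaction choices of a molecule, best sub-route first.
viable_reactions <- function(g, m, memo) {
  rids <- sort(mol_children(g, m))
  vals <- vapply(rids, function(rid) {
    rx <- g$rxn[[rid]]
    if (!rx$valid) return(NA_real_)
    subs <- lapply(rx$children, function(k) best_subroute(g, k, memo))
    if (any(vapply(subs, is.null, logical(1)))) return(NA_real_)
    rx$logprob + sum(vapply(subs, `[[`, numeric(1), "log"))
  }, numeric(1))
  rids <- rids[!is.na(vals)]
  vals <- vals[!is.na(vals)]
  rids[order(-vals, rids)]
}

## Assemble one complete route seeded at a building block. Targets that
## reach the seed are tied to it through their maximum-probability path;
## every other solvable target and every unresolved molecule is resolved
## greedily. `overrides` forces a particular reaction choice per molecule.
build_route <- function(g, seed_bb, sub_memo, score_memo, overrides = list()) {
  chosen <- new.env(parent = emptyenv())
  v_seed <- best_log_to(g, seed_bb, score_memo)
  reaching <- names(v_seed)[is.finite(v_seed)]
  for (t in sort(reaching)) {
    if (t == seed_bb) next
    cur <- seed_bb
    while (cur != t) {
      target_val <- best_log_to(g, cur, score_memo)[[t]]
      cand <- NULL
      for (rid in sort(mol_feeds(g, cur))) {
        rx <- g$rxn[[rid]]
        up <- best_log_to(g, rx$parent, score_memo)[[t]]
        if (is.finite(up) && abs(up + rx$logprob - target_val) < 1e-9 &&
            rid %in% viable_reactions(g, rx$parent, sub_memo)) {
          cand <- rid
          break
        }
      }
      if (is.null(cand)) break  # defensive; cannot happen on a finite path
      p <- g$rxn[[cand]]$parent
      if (is.null(chosen[[p]])) assign(p, cand, envir = chosen)
      cur <- p
    }
  }
  solvable_targets <- g$targets[vapply(g$targets, function(t) {
    !is.null(g$mol[[t]]) && !is.null(best_subroute(g, t, sub_memo))
  }, logical(1))]
  included <- new.env(parent = emptyenv())
  queue <- unique(c(solvable_targets, seed_bb))
  reactions <- list()
  while (length(queue)) {
    m <- queue[[1]]; queue <- queue[-1]
    if (!is.null(included[[m]])) next
    assign(m, TRUE, envir = included)
    node <- g$mol[[m]]
    if (isTRUE(node$is_bb)) next
    rid <- chosen[[m]]
    if (is.null(rid) && !is.null(overrides[[m]])) {
      alt <- overrides[[m]]
      if (alt %in% viable_reactions(g, m, sub_memo)) rid <- alt
    }
    if (is.null(rid)) {
      bs <- best_subroute(g, m, sub_memo)
      if (is.null(bs)) next  # unsolved target kept out of the route
      rid <- bs$rid
    }
    assign(m, rid, envir = chosen)
    rx <- g$rxn[[rid]]
    reactions[[m]] <- list(rid = rid, reactants = sort(rx$children),
                           probability = exp(rx$logprob))
    queue <- c(queue, rx$children)
  }
  mols <- ls(included)
  ## a single route must be one connected synthesis graph: keep only the
  ## weak component holding the seed; disconnected targets get their own
  ## routes from seeds inside their components
  if (length(reactions)) {
    e <- do.call(rbind, lapply(names(reactions), function(p)
      data.frame(from = p, to = reactions[[p]]$reactants,
                 stringsAsFactors = FALSE)))
    gg <- igraph::graph_from_data_frame(e, directed = TRUE,
                                        vertices = data.frame(name = mols))
    comp <- igraph::components(gg, mode = "weak")
    keep <- names(comp$membership)[comp$membership ==
                                     comp$membership[[seed_bb]]]
    mols <- keep
    reactions <- reactions[names(reactions) %in% keep]
  }
  covered <- intersect(g$targets, mols)
  logsum <- sum(vapply(reactions, function(r) log(r$probability), numeric(1)))
  structure(list(molecules = sort(mols), targets = sort(covered),
                 reactions = reactions, rank_score = exp(logsum),
                 seed = seed_bb),
            class = "planned_route")
}

#' Summarize a route to a molecule-only DAG
#'
#' Removes the reaction nodes: each product is connected directly to each
#' chosen reactant, with the step probability kept as an edge annotation.
#' Role flags are recomputed on the summarized edges (roots are targets,
#' leaves are building blocks, nodes with in-degree above one reachable
#' from at least two roots are common intermediates).
#'
#' @param route A `planned_route` from [extract_routes()]'s assembly.
#' @return An object of class `route_summary`: `nodes`, `edges` (tibble
#'   `parent`, `child`, `probability`), `roles`, `reactions`, `rank_score`
#'   and the covered `targets`.
#' @export
summarize_route <- function(route) {
  if (inherits(route, "route_summary")) return(route)
  parents <- names(route$reactions)
  edges <- if (length(parents)) {
    do.call(rbind, lapply(parents, function(p) {
      r <- route$reactions[[p]]
      data.frame(parent = p, child = r$reactants,
                 probability = r$probability, stringsAsFactors = FALSE)
    }))
  } else data.frame(parent = character(0), child = character(0),
                    probability = numeric(0), stringsAsFactors = FALSE)
  sg <- synthesis_graph(edges[, c("parent", "child")], nodes = route$molecules)
  sg <- assign_roles(sg)
  structure(list(nodes = sg$nodes, edges = tibble::as_tibble(edges),
                 roles = sg$roles,
                 reactions = lapply(route$reactions, function(r)
                   r[c("reactants", "probability")]),
                 rank_score = route$rank_score,
                 targets = route$targets, rank = NA_integer_),
            class = "route_summary")
}

#' @export
print.route_summary <- function(x, ...) {
  cat("<route_summary: ", length(x$nodes), " molecules, ",
      nrow(x$edges), " edges, ", length(x$targets), " targets, score ",
      signif(x$rank_score, 4), ">\n", sep = "")
  invisible(x)
}

route_edge_hash <- function(route) {
  paste(sort(paste(route$edges$parent, route$edges$child, sep = ">")),
        collapse = "|")
}

#' Rank routes by probability product
#'
#' Sorts summarized routes by the product of their step probabilities,
#' descending; ties are broken by fewer reactions, then by canonical
#' edge-list order. The `rank` field is filled in.
#'
#' @param routes List of `route_summary` objects.
#' @return The sorted list.
#' @export
rank_routes <- function(routes) {
  if (!length(routes)) return(routes)
  score <- vapply(routes, `[[`, numeric(1), "rank_score")
  nrx <- vapply(routes, function(r) length(r$reactions), integer(1))
  key <- vapply(routes, route_edge_hash, character(1))
  ord <- order(-score, nrx, key)
  routes <- routes[ord]
  for (i in seq_along(routes)) routes[[i]]$rank <- i
  routes
}

#' Extract ranked convergent routes from a search graph
#'
#' Prunes the graph (if not already pruned), scores its building blocks,
#' and assembles complete routes greedily: the best-scoring building block
#' seeds the first route, each unresolved molecule is completed with its
#' highest-scoring reaction choice whose sub-route terminates in building
#' blocks, and alternative reaction choices provide further route variants
#' per seed. Duplicate routes (identical summarized edge sets) are removed
#' and the result is ranked.
#'
#' @param graph A `search_graph` (a finished search).
#' @param budget Wall-clock extraction budget in seconds; `0` returns an
#'   empty list.
#' @param max_routes_per_block Maximum route variants generated per seed
#'   building block.
#' @return Ordered list of `route_summary` objects.
#' @export
extract_routes <- function(graph, budget = 30, max_routes_per_block = 3L) {
  g <- if (isTRUE(graph$pruned)) graph else prune_unsolvable(graph)
  t0 <- proc.time()[["elapsed"]]
  elapsed <- function() proc.time()[["elapsed"]] - t0
  bb_scores <- score_building_blocks(g)
  if (!length(bb_scores)) return(list())
  ord <- order(-bb_scores, names(bb_scores))
  seeds <- names(bb_scores)[ord]
  sub_memo <- new.env(parent = emptyenv())
  score_memo <- new.env(parent = emptyenv())
  routes <- list()
  seen <- character(0)
  for (b in seeds) {
    if (elapsed() >= budget) break
    base <- summarize_route(build_route(g, b, sub_memo, score_memo))
    n_block <- 0L
    h <- route_edge_hash(base)
    if (nrow(base$edges) && !h %in% seen) {
      seen <- c(seen, h)
      routes <- c(routes, list(base))
      n_block <- 1L
    }
    if (max_routes_per_block > 1L && nrow(base$edges)) {
      for (m in sort(names(base$reactions))) {
        if (n_block >= max_routes_per_block || elapsed() >= budget) break
        alts <- viable_reactions(g, m, sub_memo)
        if (length(alts) < 2L) next
        for (alt in alts[-1]) {
          if (n_block >= max_routes_per_block || elapsed() >= budget) break
          ov <- stats::setNames(list(alt), m)
          variant <- summarize_route(build_route(g, b, sub_memo, score_memo,
                                                 overrides = ov))
          hv <- route_edge_hash(variant)
          if (nrow(variant$edges) && !hv %in% seen) {
            seen <- c(seen, hv)
            routes <- c(routes, list(variant))
            n_block <- n_block + 1L
          }
        }
      }
    }
  }
  rank_routes(routes)
}
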