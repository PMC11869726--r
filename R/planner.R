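## Multi-target multi-step retrosynthetic search.
##
## All targets of a compound library are instantiated together in one
## bipartite search graph of molecule nodes and reaction nodes. Each
## iteration scores the open end nodes by the best single-step probability
## product along any path from each reaching target (averaged over those
## targets), selects the top n, queries the single-step policy for all of
## them in one batch, and expands. Probabilities are accumulated in log
## space to avoid underflow on deep routes.

#' Search configuration
#'
#' @param K Beam size: maximum reactant-set proposals used per molecule.
#' @param n_promising Number of promising end nodes expanded per iteration.
#' @param max_depth Maximum route depth L in reaction steps; end nodes are
#'   eligible only while their shortest distance to a target is `< L`.
#' @param time_per_molecule Wall-clock search budget in seconds per target
#'   molecule.
#' @param iterations_per_molecule Iteration budget per target molecule; the
#'   total is divided by `batch_size` to give the allowed number of policy
#'   batches.
#' @param max_targets Hard cap on the library size of one search.
#' @param batch_size Policy batch width used to rescale the iteration
#'   budget.
#' @param seed Seed handed to stochastic policies; the search itself is
#'   deterministic given a deterministic policy.
#' @return A list of class `search_config`.
#' @export
search_config <- function(K = 5L, n_promising = 10L, max_depth = 8L,
                          time_per_molecule = 120, iterations_per_molecule = 300L,
                          max_targets = 300L, batch_size = 10L, seed = 1L) {
  cfg <- list(K = as.integer(K), n_promising = as.integer(n_promising),
              max_depth = as.integer(max_depth),
              time_per_molecule = as.numeric(time_per_molecule),
              iterations_per_molecule = as.integer(iterations_per_molecule),
              max_targets = as.integer(max_targets),
              batch_size = as.integer(batch_size), seed = as.integer(seed))
  bad <- names(cfg)[vapply(cfg, function(x) !is.finite(x) || x <= 0, logical(1))]
  if (length(bad)) stop("search_config fields must be positive: ",
                        paste(bad, collapse = ", "))
  structure(cfg, class = "search_config")
}

#' Initialize a multi-target search graph
#'
#' Every distinct target becomes an unexplored molecule node; targets
#' already present in the purchasable stock are flagged building blocks
#' immediately (and are never expanded).
#'
#' @param targets Character vector of target SMILES / canonical keys.
#' @param stock Character vector of building-block SMILES (one molecule
#'   each).
#' @param config A [search_config()].
#' @return A mutable object of class `search_graph`.
#' @export
initialize_search <- function(targets, stock, config = search_config()) {
  targets <- unique(standardize_molecule(targets))
  if (length(targets) < 1L) stop("at least one target is required")
  if (length(targets) > config$max_targets) {
    stop("library of ", length(targets), " targets exceeds the limit of ",
         config$max_targets, " target molecules per convergent search")
  }
  stock_keys <- if (length(stock)) unique(standardize_molecule(stock)) else character(0)
  g <- new.env(parent = emptyenv())
  g$mol <- new.env(parent = emptyenv())       # key -> flags
  g$rxn <- new.env(parent = emptyenv())       # rid -> reaction node
  g$mol_rxns <- new.env(parent = emptyenv())  # key -> child reaction ids
  g$mol_in <- new.env(parent = emptyenv())    # key -> reaction ids it feeds
  g$stock <- new.env(parent = emptyenv())
  for (s in stock_keys) assign(s, TRUE, envir = g$stock)
  g$targets <- sort(targets)
  g$config <- config
  g$pruned <- FALSE
  for (t in targets) {
    assign(t, list(is_target = TRUE, is_bb = !is.null(g$stock[[t]]),
                   explored = FALSE, invalid_expansion = FALSE), envir = g$mol)
  }
  class(g) <- "search_graph"
  g
}

#' @export
print.search_graph <- function(x, ...) {
  cat("<search_graph: ", length(ls(x$mol)), " molecule nodes, ",
      length(ls(x$rxn)), " reaction nodes, ", length(x$targets),
      " targets>\n", sep = "")
  invisible(x)
}

molecule_keys <- function(graph) ls(graph$mol)
reaction_ids <- function(graph) ls(graph$rxn)

mol_children <- function(graph, m) {
  r <- graph$mol_rxns[[m]]
  if (is.null(r)) character(0) else r
}

mol_feeds <- function(graph, m) {
  r <- graph$mol_in[[m]]
  if (is.null(r)) character(0) else r
}

## all molecules from which m can be reached going product -> reactant
mol_ancestors <- function(graph, m) {
  seen <- new.env(parent = emptyenv())
  stack <- m
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    for (rid in mol_feeds(graph, cur)) {
      p <- graph$rxn[[rid]]$parent
      if (is.null(seen[[p]])) {
        assign(p, TRUE, envir = seen)
        stack <- c(stack, p)
      }
    }
  }
  ls(seen)
}

#' Expand a molecule node with single-step policy proposals
#'
#' Each proposal becomes a reaction node under `m` carrying the proposal
#' probability (stored as a log); at most `K` proposals are used and
#' duplicate reactant sets under the same parent collapse to one reaction
#' node. Reactant molecules are created, or linked when the molecule node
#' already exists. A proposal containing an invalid reactant (unparsable,
#' equal to the parent, or an ancestor of the parent) yields a childless,
#' invalidated reaction node. The node is marked explored.
#'
#' @param graph A `search_graph`.
#' @param m Molecule key to expand (not a building block, not explored).
#' @param proposals List of proposals, each `list(reactants =, probability =)`
#'   with the probability in `(0, 1]`.
#' @return The graph, invisibly (modified in place).
#' @export
expand_node <- function(graph, m, proposals) {
  node <- graph$mol[[m]]
  if (is.null(node)) stop("unknown molecule node: ", m)
  if (node$is_bb) stop("cannot expand a building block: ", m)
  if (node$explored) stop("molecule already explored: ", m)
  K <- graph$config$K
  if (length(proposals) > K) proposals <- proposals[seq_len(K)]
  ancestors <- c(m, mol_ancestors(graph, m))
  for (pr in proposals) {
    reactants <- pr$reactants
    prob <- pr$probability
    if (!is.numeric(prob) || length(prob) != 1L || is.na(prob) ||
        prob <= 0 || prob > 1) {
      stop("policy proposal probability must lie in (0, 1]")
    }
    if (length(reactants) == 0L) next
    keys <- vapply(reactants, function(r) {
      tryCatch(standardize_molecule(r), error = function(e) NA_character_)
    }, character(1), USE.NAMES = FALSE)
    valid <- !anyNA(keys) && !any(keys %in% ancestors)
    keys <- unique(keys)
    rid <- if (valid) {
      paste0(m, " <= ", paste(sort(keys), collapse = " . "))
    } else {
      paste0(m, " <= !", paste(sort(reactants), collapse = " . "))
    }
    existing <- graph$rxn[[rid]]
    if (!is.null(existing)) {
      if (log(prob) > existing$logprob) {
        existing$logprob <- log(prob)
        assign(rid, existing, envir = graph$rxn)
      }
      next
    }
    assign(rid, list(parent = m,
                     children = if (valid) keys else character(0),
                     logprob = log(prob), valid = valid),
           envir = graph$rxn)
    assign(m, c(mol_children(graph, m), rid), envir = graph$mol_rxns)
    if (valid) {
      for (k in keys) {
        if (is.null(graph$mol[[k]])) {
          assign(k, list(is_target = FALSE, is_bb = !is.null(graph$stock[[k]]),
                         explored = FALSE, invalid_expansion = FALSE),
                 envir = graph$mol)
        }
        assign(k, c(mol_feeds(graph, k), rid), envir = graph$mol_in)
      }
    }
  }
  node$explored <- TRUE
  assign(m, node, envir = graph$mol)
  invisible(graph)
}

#' Shortest reaction-step depth of every molecule node
#'
#' Breadth-first distance (counting one per reaction step) from the nearest
#' target; unreachable nodes get `Inf`.
#'
#' @param graph A `search_graph`.
#' @return Named numeric vector over all molecule keys.
#' @export
node_depths <- function(graph) {
  keys <- molecule_keys(graph)
  depth <- stats::setNames(rep(Inf, length(keys)), keys)
  queue <- graph$targets[graph$targets %in% keys]
  depth[queue] <- 0
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    d <- depth[[cur]] + 1
    for (rid in mol_children(graph, cur)) {
      rx <- graph$rxn[[rid]]
      if (!rx$valid) next
      for (k in rx$children) {
        if (d < depth[[k]]) {
          depth[[k]] <- d
          queue <- c(queue, k)
        }
      }
    }
  }
  depth
}

#' Eligible end nodes of the search graph
#'
#' Molecule nodes with no reaction children that are not building blocks,
#' have not been explored, and whose shortest distance to any target is
#' strictly below the maximum depth. On a fresh search these are the target
#' nodes themselves.
#'
#' @param graph A `search_graph`.
#' @return Character vector of molecule keys.
#' @export
eligible_end_nodes <- function(graph) {
  depth <- node_depths(graph)
  keys <- molecule_keys(graph)
  keep <- vapply(keys, function(k) {
    node <- graph$mol[[k]]
    !node$is_bb && !node$explored && length(mol_children(graph, k)) == 0L &&
      is.finite(depth[[k]]) && depth[[k]] < graph$config$max_depth
  }, logical(1))
  keys[keep]
}

## Best log-probability from every target to molecule m, memoized across a
## scoring pass. Valid because the search graph is kept acyclic.
best_log_to <- function(graph, m, memo) {
  hit <- memo[[m]]
  if (!is.null(hit)) return(hit)
  nt <- length(graph$targets)
  v <- stats::setNames(rep(-Inf, nt), graph$targets)
  node <- graph$mol[[m]]
  if (isTRUE(node$is_target)) v[[m]] <- 0
  for (rid in mol_feeds(graph, m)) {
    rx <- graph$rxn[[rid]]
    up <- best_log_to(graph, rx$parent, memo) + rx$logprob
    v <- pmax(v, up)
  }
  assign(m, v, envir = memo)
  v
}

#' Score an end node
#'
#' For every target with a path to `m`, the best score is the maximum over
#' linear paths of the product of the reaction-node probabilities along the
#' path; the node score is the mean of these best scores over the reaching
#' targets only.
#'
#' @param graph A `search_graph`.
#' @param m Molecule key of an end node.
#' @return Score in `[0, 1]`.
#' @export
score_end_node <- function(graph, m) {
  memo <- new.env(parent = emptyenv())
  v <- best_log_to(graph, m, memo)
  reach <- is.finite(v)
  if (!any(reach)) stop("end node unreachable from every target: ", m)
  mean(exp(v[reach]))
}

score_nodes <- function(graph, nodes) {
  memo <- new.env(parent = emptyenv())
  vapply(nodes, function(m) {
    v <- best_log_to(graph, m, memo)
    reach <- is.finite(v)
    if (!any(reach)) return(NA_real_)
    mean(exp(v[reach]))
  }, numeric(1))
}

#' Select the most promising end nodes
#'
#' Eligible end nodes ranked by score (descending), with deterministic tie
#' breaking by shortest depth then canonical key, truncated to `n`.
#'
#' @param graph A `search_graph`.
#' @param n Maximum number of nodes to return.
#' @return Character vector of at most `n` molecule keys, best first.
#' @export
select_promising <- function(graph, n = graph$config$n_promising) {
  nodes <- eligible_end_nodes(graph)
  if (!length(nodes)) return(character(0))
  scores <- score_nodes(graph, nodes)
  ok <- !is.na(scores)
  nodes <- nodes[ok]; scores <- scores[ok]
  if (!length(nodes)) return(character(0))
  depth <- node_depths(graph)[nodes]
  ord <- order(-scores, depth, nodes)
  utils::head(nodes[ord], n)
}

#' Run the multi-target multi-step search
#'
#' Iterates select-batch-expand until no eligible end nodes remain
#' (`all_explored`), the wall-clock budget `time_per_molecule * |targets|`
#' is exceeded (`time_limit`), or the number of policy batches reaches
#' `floor(iterations_per_molecule * |targets| / batch_size)`
#' (`iteration_limit`). A policy error on a molecule marks that node as an
#' invalid expansion and the search continues.
#'
#' @param targets Character vector of target molecules.
#' @param policy Single-step policy: a function taking a character vector of
#'   product keys and returning, per product, a list of at most `K`
#'   proposals `list(reactants =, probability =)`.
#' @param stock Character vector of purchasable building blocks.
#' @param config A [search_config()].
#' @return List of class `search_result` with `graph` (the final
#'   `search_graph`) and `log` (iterations, policy calls, stop reason,
#'   elapsed seconds).
#' @export
run_search <- function(targets, policy, stock, config = search_config()) {
  graph <- initialize_search(targets, stock, config)
  n_targets <- length(graph$targets)
  max_batches <- floor(config$iterations_per_molecule * n_targets / config$batch_size)
  time_budget <- config$time_per_molecule * n_targets
  t0 <- proc.time()[["elapsed"]]
  batches <- 0L
  policy_calls <- 0L
  stop_reason <- NULL
  repeat {
    elapsed <- proc.time()[["elapsed"]] - t0
    if (elapsed > time_budget) { stop_reason <- "time_limit"; break }
    promising <- select_promising(graph, config$n_promising)
    if (!length(promising)) { stop_reason <- "all_explored"; break }
    if (batches + 1L > max_batches) { stop_reason <- "iteration_limit"; break }
    batch_proposals <- tryCatch(policy(promising), error = function(e) NULL)
    batches <- batches + 1L
    policy_calls <- policy_calls + length(promising)
    if (is.null(batch_proposals)) {
      ## whole-batch failure: retry each molecule on its own
      batch_proposals <- lapply(promising, function(m) {
        tryCatch(policy(m)[[1]], error = function(e) NULL)
      })
    }
    for (i in seq_along(promising)) {
      m <- promising[i]
      props <- batch_proposals[[i]]
      if (is.null(props)) {
        node <- graph$mol[[m]]
        node$invalid_expansion <- TRUE
        node$explored <- TRUE
        assign(m, node, envir = graph$mol)
      } else {
        expand_node(graph, m, props)
      }
    }
  }
  log <- list(iterations = batches, policy_calls = policy_calls,
              stop_reason = stop_reason,
              elapsed = proc.time()[["elapsed"]] - t0,
              n_targets = n_targets, max_batches = max_batches)
  structure(list(graph = graph, log = log), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result: ", x$log$iterations, " iterations, stop: ",
      x$log$stop_reason, ">\n", sep = "")
  print(x$graph)
  invisible(x)
}

#' Validate search-graph structural invariants
#'
#' Checks that every molecule node has at most `K` reaction children, every
#' valid reaction node has as many outgoing edges as reactants (invalidated
#' nodes have zero), all cross-references are consistent, and the graph is
#' acyclic. Errors on the first violation.
#'
#' @param graph A `search_graph`.
#' @return `TRUE`, invisibly.
#' @export
validate_search_graph <- function(graph) {
  K <- graph$config$K
  for (m in molecule_keys(graph)) {
    rids <- mol_children(graph, m)
    if (length(rids) > K) stop("molecule out-degree exceeds K: ", m)
    for (rid in rids) {
      if (is.null(graph$rxn[[rid]])) stop("dangling reaction id: ", rid)
      if (graph$rxn[[rid]]$parent != m) stop("parent mismatch at ", rid)
    }
  }
  edges <- list()
  for (rid in reaction_ids(graph)) {
    rx <- graph$rxn[[rid]]
    if (!rx$valid && length(rx$children)) {
      stop("invalidated reaction node with children: ", rid)
    }
    for (k in rx$children) {
      if (is.null(graph$mol[[k]])) stop("reaction child missing: ", k)
      if (!rid %in% mol_feeds(graph, k)) stop("missing back-reference: ", rid)
      edges[[length(edges) + 1L]] <- c(rx$parent, k)
    }
  }
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::graph_from_data_frame(
      data.frame(from = e[, 1], to = e[, 2], stringsAsFactors = FALSE))
    if (!igraph::is_dag(g)) stop("search graph contains a cycle")
  }
  invisible(TRUE)
}
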