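## Shared fixtures and independent oracles for the test suite.

## memoised small universes so multiple test files reuse one generation
.universe_cache <- new.env(parent = emptyenv())
cached_universe <- function(..., seed = 7L) {
  key <- paste(deparse(list(..., seed = seed)), collapse = "")
  if (is.null(.universe_cache[[key]])) {
    assign(key, generate_universe(universe_config(..., seed = seed)),
           envir = .universe_cache)
  }
  .universe_cache[[key]]
}

## distinct, trivially canonical molecule keys (unbranched alkanes)
alkane <- function(i) strrep("C", i)

## Build a search graph from an explicit plan without running a policy.
## `plan` is a list of expansions: list(parent =, proposals = list(...)).
## Targets are the declared roots; iteration order must be topological.
build_toy_search <- function(targets, plan, stock = character(0),
                             config = search_config(K = 12L)) {
  g <- initialize_search(targets, stock, config)
  for (step in plan) {
    expand_node(g, step$parent, step$proposals)
  }
  g
}

prop <- function(reactants, probability) {
  list(reactants = reactants, probability = probability)
}

## Independent scoring oracle: enumerate every simple linear path from each
## target to `m`, multiply the reaction probabilities along it, keep the
## maximum per target, and average over targets that reach `m` at all.
oracle_score <- function(g, m) {
  paths_product <- function(u, acc) {
    if (u == m) return(acc)
    out <- numeric(0)
    for (rid in convergentretro:::mol_children(g, u)) {
      rx <- g$rxn[[rid]]
      if (!rx$valid) next
      for (child in rx$children) {
        out <- c(out, paths_product(child, acc * exp(rx$logprob)))
      }
    }
    out
  }
  best <- vapply(g$targets, function(t) {
    p <- paths_product(t, 1)
    if (length(p)) max(p) else NA_real_
  }, numeric(1))
  best <- best[!is.na(best)]
  if (!length(best)) return(NA_real_)
  mean(best)
}

## Random search-graph DAGs over alkane keys; reactions point from earlier
## to later nodes so the graph is acyclic by construction.
random_search_dag <- function(n_nodes, seed, stock_frac = 0.3) {
  set.seed(seed)
  keys <- vapply(seq_len(n_nodes), alkane, character(1))
  incoming <- rep(FALSE, n_nodes)
  plan_children <- vector("list", n_nodes)
  for (i in seq_len(n_nodes - 1L)) {
    n_rxn <- sample(0:3, 1L)
    props <- list()
    for (r in seq_len(n_rxn)) {
      pool <- (i + 1L):n_nodes
      kids <- pool[sample.int(length(pool), min(length(pool), sample(1:2, 1L)))]
      props[[r]] <- prop(keys[kids], round(stats::runif(1, 0.05, 1), 3))
      incoming[kids] <- TRUE
    }
    plan_children[[i]] <- props
  }
  roots <- keys[!incoming]
  leaves <- which(vapply(plan_children, length, integer(1)) == 0L |
                    seq_len(n_nodes) == n_nodes)
  stock <- keys[leaves[sample.int(length(leaves),
                                  max(1L, floor(length(leaves) * stock_frac)))]]
  g <- initialize_search(roots, stock, search_config(K = 12L))
  for (i in seq_len(n_nodes)) {
    props <- plan_children[[i]]
    if (!length(props)) next
    node <- g$mol[[keys[i]]]
    if (is.null(node) || node$is_bb) next
    expand_node(g, keys[i], props)
  }
  g
}

## route_summary constructed directly from a molecule-only edge list
make_summary <- function(edges, probability = 0.5, targets = NULL) {
  edges <- data.frame(parent = edges$parent, child = edges$child,
                      stringsAsFactors = FALSE)
  sg <- assign_roles(synthesis_graph(edges))
  reactions <- lapply(split(edges$child, edges$parent), function(kids)
    list(reactants = sort(kids), probability = probability))
  if (is.null(targets)) targets <- graph_targets(sg)
  structure(list(nodes = sg$nodes,
                 edges = tibble::tibble(parent = edges$parent,
                                        child = edges$child,
                                        probability = probability),
                 roles = sg$roles, reactions = reactions,
                 rank_score = probability^length(reactions),
                 targets = sort(targets), rank = NA_integer_),
            class = "route_summary")
}

## reference synthesis graph from an edge list
make_reference <- function(edges) {
  assign_roles(synthesis_graph(data.frame(parent = edges$parent,
                                          child = edges$child,
                                          stringsAsFactors = FALSE)))
}
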