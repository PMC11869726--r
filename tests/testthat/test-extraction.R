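## Synthesis-graph construction, role assignment and convergence filtering.
## Node keys here are opaque strings except where stereochemistry matters.

records_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    document_id = vapply(rows, `[[`, character(1), 1),
    product = vapply(rows, `[[`, character(1), 2),
    reactants = lapply(rows, `[[`, 3),
    reagents = rep(list(character(0)), length(rows)),
    yield = NA_real_)
}

test_that("document graphs collapse repeated edges and records", {
  g1 <- build_document_graph(records_tbl(list("D", "P", c("A", "B"))))
  expect_setequal(g1$nodes, c("P", "A", "B"))
  expect_equal(nrow(g1$edges), 2L)

  chain <- build_document_graph(records_tbl(list("D", "P", "A"),
                                            list("D", "A", "C")))
  expect_setequal(paste(chain$edges$parent, chain$edges$child),
                  c("P A", "A C"))

  twice <- build_document_graph(records_tbl(list("D", "P", c("A", "B")),
                                            list("D", "P", c("A", "B"))))
  expect_identical(graph_hash(twice), graph_hash(g1))
})

test_that("weak components match a union-find oracle on random graphs", {
  union_find_components <- function(nodes, edges) {
    parent <- stats::setNames(nodes, nodes)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (i in seq_len(nrow(edges))) {
      a <- find(edges$parent[i]); b <- find(edges$child[i])
      if (a != b) parent[[a]] <- b
    }
    length(unique(vapply(nodes, find, character(1))))
  }
  for (seed in 1:5) {
    set.seed(seed)
    nodes <- paste0("n", 1:50)
    edges <- data.frame(parent = sample(nodes, 40, replace = TRUE),
                        child = sample(nodes, 40, replace = TRUE))
    edges <- edges[edges$parent != edges$child, ]
    g <- synthesis_graph(edges, nodes = nodes)
    comps <- split_components(g)
    expect_equal(length(comps), union_find_components(nodes, g$edges))
    expect_setequal(unlist(lapply(comps, `[[`, "nodes")), nodes)
  }
})

test_that("roles follow the degree and reachability rules", {
  g <- assign_roles(synthesis_graph(data.frame(
    parent = c("T1", "T2", "I"), child = c("I", "I", "B"))))
  expect_setequal(graph_targets(g), c("T1", "T2"))
  expect_setequal(graph_common_intermediates(g), "I")
  expect_setequal(graph_building_blocks(g), "B")

  chain <- assign_roles(synthesis_graph(data.frame(
    parent = c("T", "A"), child = c("A", "B"))))
  expect_length(graph_common_intermediates(chain), 0)

  ## a leaf fed by two targets holds both roles at once
  both <- assign_roles(synthesis_graph(data.frame(
    parent = c("T1", "T2"), child = c("X", "X"))))
  expect_setequal(intersect(graph_building_blocks(both),
                            graph_common_intermediates(both)), "X")

  ## diamond under a single target: in-degree 2 but only one reaching target
  diamond <- assign_roles(synthesis_graph(data.frame(
    parent = c("T", "T", "A", "B"), child = c("A", "B", "X", "X"))))
  expect_length(graph_common_intermediates(diamond), 0)
})

test_that("direction conflicts resolve by strict corpus majority", {
  g <- synthesis_graph(data.frame(parent = c("A", "B", "A"),
                                  child = c("B", "A", "C")))
  counts <- c("A\rB" = 7L, "B\rA" = 2L, "A\rC" = 1L)
  res <- resolve_directions(g, counts)
  expect_setequal(paste(res$edges$parent, res$edges$child), c("A B", "A C"))

  tie <- c("A\rB" = 3L, "B\rA" = 3L, "A\rC" = 1L)
  expect_null(resolve_directions(g, tie))

  clean <- synthesis_graph(data.frame(parent = "A", child = "C"))
  expect_identical(graph_hash(resolve_directions(clean, counts)),
                   graph_hash(clean))
})

test_that("convergence filtering discards with the right reasons", {
  cyclic <- synthesis_graph(data.frame(parent = c("P", "A", "C"),
                                       child = c("A", "C", "P")))
  no_ci <- synthesis_graph(data.frame(parent = c("T", "A"), child = c("A", "B")))
  good <- synthesis_graph(data.frame(parent = c("T1", "T2", "I"),
                                     child = c("I", "I", "B")))
  dup <- synthesis_graph(good$edges, document_ids = "other")
  stereo <- synthesis_graph(data.frame(
    parent = c("C/C=C/CCO", "C/C=C\\CCO", "CCCCO"),
    child = c("CCCCO", "CCCCO", "CCO")))

  res <- filter_convergent(list(cyclic, no_ci, good, dup, stereo))
  expect_length(res$routes, 1L)
  expect_identical(graph_hash(res$routes[[1]]), graph_hash(good))
  got <- stats::setNames(res$discards$n, res$discards$reason)
  expect_equal(got[["cycle"]], 1L)
  expect_equal(got[["no_common_intermediate"]], 1L)
  expect_equal(got[["duplicate"]], 1L)
  expect_equal(got[["stereoisomer_targets"]], 1L)
})

test_that("the full extraction pipeline is deterministic and counts add up", {
  uni <- cached_universe(n_libraries = 3, targets_per_library = c(2, 4),
                         depth = c(1, 3))
  corpus <- process_raw_reactions(uni$documents)
  res1 <- extract_convergent_routes(corpus)
  res2 <- extract_convergent_routes(corpus)
  expect_identical(lapply(res1$routes, graph_hash),
                   lapply(res2$routes, graph_hash))
  expect_identical(res1$summary, res2$summary)
  expect_equal(res1$summary$n[res1$summary$reason == "retained"],
               length(res1$routes))
  st <- res1$stats
  expect_true(all(st$n_targets >= 2))
  expect_true(all(st$n_common_intermediates >= 1))
  expect_true(all(st$depth_mean <= st$depth_max))
})

test_that("retained routes satisfy the structural invariants", {
  uni <- cached_universe(n_libraries = 3, targets_per_library = c(2, 4),
                         depth = c(1, 3))
  res <- extract_convergent_routes(process_raw_reactions(uni$documents))
  for (route in res$routes) {
    ig <- convergentretro:::sg_igraph(route)
    expect_true(igraph::is_dag(ig))
    expect_equal(igraph::components(ig, mode = "weak")$no, 1L)
    targets <- graph_targets(route)
    expect_gte(length(targets), 2L)
    ## every node lies on some target -> building-block path
    d_from_t <- igraph::distances(ig, v = targets, mode = "out")
    expect_true(all(is.finite(apply(d_from_t, 2, min))))
    bbs <- graph_building_blocks(route)
    d_to_b <- igraph::distances(ig, v = bbs, mode = "in")
    expect_true(all(is.finite(apply(d_to_b, 2, min))))
    ## shared-edge economy: the convergent route never needs more reactions
    ## than the sum of its per-target sub-routes
    per_target_edges <- vapply(targets, function(t) {
      reach <- names(which(is.finite(d_from_t[t, ])))
      sum(route$edges$parent %in% reach)
    }, numeric(1))
    expect_lte(nrow(route$edges), sum(per_target_edges))
  }
})

test_that("routes JSON round-trips", {
  uni <- cached_universe(n_libraries = 3, targets_per_library = c(2, 4),
                         depth = c(1, 3))
  res <- extract_convergent_routes(process_raw_reactions(uni$documents))
  path <- withr::local_tempfile(fileext = ".json")
  write_routes_json(res$routes, path)
  back <- read_routes_json(path)
  expect_identical(lapply(back, graph_hash), lapply(res$routes, graph_hash))
  expect_identical(back[[1]]$roles, res$routes[[1]]$roles)
})
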