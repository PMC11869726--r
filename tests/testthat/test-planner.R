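## Multi-target search graph mechanics and scoring.

test_that("search initialization deduplicates targets and flags stock", {
  g <- initialize_search(c("CCO", "OCC", "CCN"), stock = "CCN",
                         config = search_config())
  keys <- convergentretro:::molecule_keys(g)
  expect_length(keys, 2L)
  expect_true(g$mol[[standardize_molecule("CCN")]]$is_bb)
  expect_false(g$mol[[standardize_molecule("CCO")]]$is_bb)
  expect_error(
    initialize_search(vapply(1:4, alkane, character(1)), character(0),
                      search_config(max_targets = 3)),
    "target molecules")
})

test_that("expansion creates, collapses and invalidates reaction nodes", {
  g <- initialize_search("CCCCCC", character(0), search_config())
  m <- standardize_molecule("CCCCCC")
  expand_node(g, m, list(prop(c("CCO", "CCN"), 0.8),
                         prop("CCS", 0.1),
                         prop("OCC", 0.2),            # duplicate set of CCO? no: single
                         prop("CCO.x(", 0.3)))        # unparsable reactant
  rids <- convergentretro:::mol_children(g, m)
  expect_length(rids, 4L)
  valid <- vapply(rids, function(r) g$rxn[[r]]$valid, logical(1))
  expect_equal(sum(!valid), 1L)
  bad <- g$rxn[[rids[!valid][1]]]
  expect_length(bad$children, 0L)  # invalid proposals stay childless
  expect_true(g$mol[[m]]$explored)
  expect_error(expand_node(g, m, list(prop("C", 0.5))), "explored")
})

test_that("duplicate reactant sets under one parent collapse to one node", {
  g <- initialize_search("CCCCCC", character(0), search_config())
  m <- standardize_molecule("CCCCCC")
  expand_node(g, m, list(prop("CC", 0.8), prop("CC", 0.5), prop("CC", 0.9)))
  expect_length(convergentretro:::mol_children(g, m), 1L)
  rid <- convergentretro:::mol_children(g, m)[1]
  expect_equal(exp(g$rxn[[rid]]$logprob), 0.9)  # best duplicate kept
})

test_that("molecule out-degree never exceeds the beam size", {
  g <- initialize_search("CCCCCCCC", character(0), search_config(K = 2))
  m <- standardize_molecule("CCCCCCCC")
  expand_node(g, m, list(prop("C", 0.9), prop("CC", 0.8), prop("CCC", 0.7)))
  expect_length(convergentretro:::mol_children(g, m), 2L)
  validate_search_graph(g)
})

test_that("loop-guarded proposals are invalidated", {
  g <- initialize_search("CCCC", character(0), search_config())
  t <- standardize_molecule("CCCC")
  expand_node(g, t, list(prop("CCC", 0.9)))
  a <- standardize_molecule("CCC")
  ## proposing the parent itself or an ancestor dead-ends the reaction node
  expand_node(g, a, list(prop(a, 0.5), prop(t, 0.5), prop("CC", 0.4)))
  rids <- convergentretro:::mol_children(g, a)
  valid <- vapply(rids, function(r) g$rxn[[r]]$valid, logical(1))
  expect_equal(sum(valid), 1L)
  validate_search_graph(g)
})

test_that("eligibility follows out-degree, stock and the strict depth bound", {
  L <- 3L
  cfg <- search_config(max_depth = L)
  g <- initialize_search("CCCCC", "CCCCO", cfg)
  t <- standardize_molecule("CCCCC")
  expect_identical(eligible_end_nodes(g), t)  # fresh search: the target

  expand_node(g, t, list(prop(c("CCCC", "CCCCO"), 0.9)))
  expect_identical(eligible_end_nodes(g), standardize_molecule("CCCC"))  # stock leaf excluded
  expand_node(g, standardize_molecule("CCCC"), list(prop("CCC", 0.9)))
  expand_node(g, standardize_molecule("CCC"), list(prop("CC", 0.9)))
  ## depth of "CC" is exactly L = 3: excluded by the strict bound;
  ## cross-check depths against an igraph shortest-path oracle
  expect_length(eligible_end_nodes(g), 0L)
  d <- node_depths(g)
  expect_equal(d[[standardize_molecule("CC")]], 3)
})

test_that("end-node scores reproduce the worked examples", {
  ## single path with probabilities 0.8 then 0.5
  g <- build_toy_search(alkane(10), list(
    list(parent = alkane(10), proposals = list(prop(alkane(6), 0.8))),
    list(parent = alkane(6), proposals = list(prop(alkane(3), 0.5)))))
  expect_equal(score_end_node(g, alkane(3)), 0.4)

  ## two paths to the same node: max wins
  g2 <- build_toy_search(alkane(10), list(
    list(parent = alkane(10), proposals = list(prop(alkane(6), 0.8),
                                               prop(alkane(5), 0.5))),
    list(parent = alkane(6), proposals = list(prop(alkane(3), 1))),
    list(parent = alkane(5), proposals = list(prop(alkane(3), 1)))))
  expect_equal(score_end_node(g2, alkane(3)), 0.8)

  ## mean over reaching targets only: (0.8 + 0.4) / 2, third target ignored
  g3 <- build_toy_search(c(alkane(10), alkane(11), alkane(12)), list(
    list(parent = alkane(10), proposals = list(prop(alkane(3), 0.8))),
    list(parent = alkane(11), proposals = list(prop(alkane(3), 0.4))),
    list(parent = alkane(12), proposals = list(prop(alkane(4), 0.9)))))
  expect_equal(score_end_node(g3, alkane(3)), 0.6)
  expect_error(score_end_node(g3, alkane(5)), "unknown|unreachable")
})

test_that("scores match the brute-force path oracle on random DAGs", {
  for (seed in 1:30) {
    g <- random_search_dag(sample(4:12, 1), seed = seed)
    validate_search_graph(g)
    nodes <- eligible_end_nodes(g)
    for (m in nodes) {
      expect_equal(score_end_node(g, m), oracle_score(g, m), tolerance = 1e-12)
    }
  }
})

test_that("scores stay in [0,1] and untouched end nodes are unaffected", {
  g <- build_toy_search(alkane(10), list(
    list(parent = alkane(10), proposals = list(prop(alkane(4), 0.7),
                                               prop(alkane(5), 0.6)))))
  before <- score_end_node(g, alkane(4))
  expect_true(before >= 0 && before <= 1)
  expand_node(g, alkane(5), list(prop(alkane(2), 0.5)))
  expect_equal(score_end_node(g, alkane(4)), before)
})

test_that("promising-node selection ranks, tie-breaks and truncates", {
  g <- build_toy_search(alkane(10), list(
    list(parent = alkane(10), proposals = list(prop(alkane(4), 0.9),
                                               prop(alkane(5), 0.5),
                                               prop(alkane(6), 0.1)))))
  expect_identical(select_promising(g, 2),
                   c(alkane(4), alkane(5)))
  ## equal scores: canonical-key order decides, stable across runs
  g2 <- build_toy_search(alkane(10), list(
    list(parent = alkane(10), proposals = list(prop(alkane(5), 0.5),
                                               prop(alkane(4), 0.5)))))
  expect_identical(select_promising(g2, 2), select_promising(g2, 2))
  expect_identical(select_promising(g2, 2), c(alkane(4), alkane(5)))
})

test_that("stop criteria: all-stock library, iteration budget, batch count", {
  uni <- cached_universe(n_libraries = 3, targets_per_library = c(2, 4),
                         depth = c(1, 3))
  pol <- oracle_policy(uni)
  doc <- names(uni$libraries)[1]
  targets <- uni$libraries[[doc]]

  solved <- run_search(targets, pol, stock = targets, search_config())
  expect_identical(solved$log$stop_reason, "all_explored")
  expect_equal(solved$log$iterations, 0L)

  one <- run_search(targets, pol, uni$stock,
                    search_config(iterations_per_molecule = 1,
                                  batch_size = length(targets)))
  expect_identical(one$log$stop_reason, "iteration_limit")
  expect_equal(one$log$iterations, 1L)
})

test_that("a policy error marks the node and the search continues", {
  uni <- cached_universe(n_libraries = 3, targets_per_library = c(2, 4),
                         depth = c(1, 3))
  pol <- oracle_policy(uni)
  doc <- names(uni$libraries)[1]
  targets <- uni$libraries[[doc]]
  poison <- targets[1]
  flaky <- function(products) {
    if (poison %in% products) stop("model failure")
    pol(products)
  }
  res <- run_search(targets, flaky, uni$stock,
                    search_config(iterations_per_molecule = 30,
                                  time_per_molecule = 20))
  expect_true(res$graph$mol[[poison]]$invalid_expansion)
  expect_gt(length(convergentretro:::reaction_ids(res$graph)), 0L)
})

test_that("a perfect oracle leaves the true route inside the search graph", {
  uni <- cached_universe(n_libraries = 3, targets_per_library = c(2, 4),
                         depth = c(1, 3))
  pol <- oracle_policy(uni)
  for (doc in names(uni$libraries)) {
    res <- run_search(uni$libraries[[doc]], pol, uni$stock,
                      search_config(iterations_per_molecule = 40,
                                    time_per_molecule = 20))
    validate_search_graph(res$graph)
    truth <- uni$true_routes[[doc]]
    for (i in seq_len(nrow(truth$edges))) {
      parent <- truth$edges$parent[i]
      kids <- truth$edges$child[truth$edges$parent == parent]
      rids <- convergentretro:::mol_children(res$graph, parent)
      hit <- any(vapply(rids, function(r)
        all(kids %in% res$graph$rxn[[r]]$children), logical(1)))
      expect_true(hit, info = paste("missing true reaction under", parent))
    }
  }
})
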