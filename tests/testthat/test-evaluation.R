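## Solvability, accuracy, F1 and reaction-type metrics.

ref_edges <- data.frame(parent = c("T1", "T2", "I", "I"),
                        child = c("I", "I", "B1", "B2"))
reference <- make_reference(ref_edges)

test_that("complete and partial solvability read the ranked list correctly", {
  both <- make_summary(ref_edges)
  only_t1 <- make_summary(data.frame(parent = c("T1", "I", "I"),
                                     child = c("I", "B1", "B2")))
  only_t2 <- make_summary(data.frame(parent = c("T2", "I", "I"),
                                     child = c("I", "B1", "B2")))
  targets <- c("T1", "T2")

  expect_true(complete_solvability(list(both), targets, 1))
  expect_false(complete_solvability(list(only_t1, only_t2), targets, 10))
  expect_false(complete_solvability(list(), targets, 10))

  expect_true(partial_solvability(list(only_t1, only_t2), targets, 2))
  expect_false(partial_solvability(list(only_t1, only_t2), targets, 1))
  expect_false(partial_solvability(list(only_t1), targets, 10))
  ## complete implies partial
  expect_true(partial_solvability(list(both), targets, 1))
})

test_that("route accuracy is exact edge-set equality", {
  shuffled <- make_summary(ref_edges[c(3, 1, 4, 2), ])
  expect_true(route_accuracy(shuffled, reference))
  extra <- make_summary(rbind(ref_edges, data.frame(parent = "B1", child = "X")))
  expect_false(route_accuracy(extra, reference))
  ## one different molecule anywhere breaks accuracy (intended stringency)
  analog <- make_summary(data.frame(parent = c("T1", "T2", "I", "I"),
                                    child = c("I", "I", "B1", "B3")))
  expect_false(route_accuracy(analog, reference))
})

test_that("intermediate accuracy compares common-intermediate sets", {
  different_downstream <- make_summary(data.frame(
    parent = c("T1", "T2", "I"), child = c("I", "I", "B9")))
  expect_true(intermediate_accuracy(different_downstream, reference))
  other_ci <- make_summary(data.frame(parent = c("T1", "T2", "J", "J"),
                                      child = c("J", "J", "B1", "B2")))
  expect_false(intermediate_accuracy(other_ci, reference))
  linear_ref <- make_reference(data.frame(parent = c("T", "A"),
                                          child = c("A", "B")))
  expect_error(intermediate_accuracy(different_downstream, linear_ref),
               "convergent")
})

test_that("F1 follows the tp/fp/fn arithmetic, including the worked case", {
  ## reference: 2 targets, 4 edges and 5 non-target molecules; the proposed
  ## route adds one extra edge and one extra non-target molecule
  ref_e <- data.frame(parent = c("T1", "T2", "I", "I"),
                      child = c("I", "I", "B1", "B2"))
  ref <- synthesis_graph(ref_e, nodes = c("T1", "T2", "I", "B1", "B2",
                                          "C1", "C2"))
  ref$roles <- stats::setNames(
    list("target", "target", "common_intermediate", "building_block",
         "building_block", "building_block", "building_block"), ref$nodes)
  proposed <- make_summary(rbind(ref_e, data.frame(parent = "B1", child = "X1")),
                           targets = c("T1", "T2"))
  proposed$nodes <- union(ref$nodes, proposed$nodes)
  res <- f1_score(proposed, ref)
  expect_equal(res$reaction_f1, 2 * (4 / 5) * 1 / ((4 / 5) + 1))  # 8/9
  expect_equal(res$molecule_f1, 2 * (5 / 6) * 1 / ((5 / 6) + 1))  # 10/11
  expect_equal(res$combined, (res$reaction_f1 + res$molecule_f1) / 2)

  identical_route <- make_summary(ref_e)
  ref2 <- make_reference(ref_e)
  expect_equal(f1_score(identical_route, ref2)$combined, 1)

  disjoint <- make_summary(data.frame(parent = c("S1", "S2"),
                                      child = c("J", "J")))
  expect_equal(f1_score(disjoint, ref2)$combined, 0)
})

test_that("F1 matches a set-arithmetic oracle on random route pairs", {
  f1_oracle <- function(a, b) {
    tp <- length(intersect(a, b))
    if (tp == 0) return(if (!length(a) && !length(b)) 1 else 0)
    p <- tp / length(a); r <- tp / length(b)
    2 * p * r / (p + r)
  }
  set.seed(99)
  pool <- expand.grid(parent = paste0("p", 1:6), child = paste0("c", 1:6),
                      stringsAsFactors = FALSE)
  for (i in 1:200) {
    e1 <- pool[sample.int(nrow(pool), sample(2:10, 1)), ]
    e2 <- pool[sample.int(nrow(pool), sample(2:10, 1)), ]
    a <- make_summary(e1); b <- make_reference(e2)
    got <- f1_score(a, b)
    targets <- union(a$targets, graph_targets(b))
    expect_equal(got$reaction_f1,
                 f1_oracle(paste(e1$parent, e1$child, sep = ">"),
                           paste(e2$parent, e2$child, sep = ">")))
    expect_equal(got$molecule_f1,
                 f1_oracle(setdiff(a$nodes, targets), setdiff(b$nodes, targets)))
  }
})

test_that("reaction name/class accuracy uses sets and drops Unrecognized", {
  classify <- function(tab) function(reactants, product) {
    hit <- tab[[product]]
    if (is.null(hit)) list(name = "Unrecognized", class = "Unrecognized")
    else list(name = hit[1], class = hit[2])
  }
  ref <- make_reference(data.frame(parent = c("T1", "T2", "I"),
                                   child = c("I", "I", "B")))
  ## same reaction names through a different intermediate
  other <- make_summary(data.frame(parent = c("T1", "T2", "J"),
                                   child = c("J", "J", "B")))
  tab <- list(T1 = c("amide", "acyl"), T2 = c("ester", "acyl"),
              I = c("ether", "subst"), J = c("ether", "subst"))
  res <- reaction_type_accuracy(other, ref, classify(tab))
  expect_true(res$name_match)
  expect_false(route_accuracy(other, ref))

  ## different names, same classes
  tab2 <- list(T1 = c("amide", "acyl"), T2 = c("ester", "acyl"),
               I = c("ether", "subst"), J = c("thioether", "subst"))
  res2 <- reaction_type_accuracy(other, ref, classify(tab2))
  expect_false(res2$name_match)
  expect_true(res2$class_match)

  ## everything unrecognized on both sides: vacuous match, flagged
  res3 <- reaction_type_accuracy(other, ref, classify(list()))
  expect_true(res3$name_match && res3$class_match)
  expect_true(res3$degenerate)

  ## a crashing classifier is treated as Unrecognized
  res4 <- reaction_type_accuracy(other, ref,
                                 function(r, p) stop("licence expired"))
  expect_true(res4$degenerate)
})

test_that("test-set evaluation aggregates per library and per compound", {
  ref_a <- make_reference(data.frame(parent = c("T1", "T2", "I", "I"),
                                     child = c("I", "I", "B1", "B2")))
  ref_b <- make_reference(data.frame(parent = c("U1", "U2", "J"),
                                     child = c("J", "J", "B3")))
  pred_a <- list(make_summary(data.frame(parent = c("T1", "T2", "I", "I"),
                                         child = c("I", "I", "B1", "B2"))))
  report <- evaluate_testset(list(A = pred_a), list(A = ref_a, B = ref_b),
                             Ns = c(1, 10))
  agg <- report$aggregate
  val <- function(metric, N)
    agg$value[agg$metric == metric & agg$N == N]
  expect_equal(val("complete_solved", 10), 0.5)  # one of two libraries
  expect_equal(val("route_accuracy", 1), 0.5)
  expect_equal(val("f1_median", 1), 0.5)
  pc <- report$per_compound
  expect_true(all(pc$solved[pc$library == "A"]))
  expect_false(any(pc$solved[pc$library == "B"]))  # missing prediction
})

test_that("metric implications and top-N monotonicity hold (property)", {
  set.seed(123)
  pool <- expand.grid(parent = paste0("p", 1:5), child = paste0("c", 1:5),
                      stringsAsFactors = FALSE)
  ref <- make_reference(data.frame(parent = c("p1", "p2", "p3", "p3"),
                                   child = c("p3", "p3", "c1", "c2")))
  targets <- graph_targets(ref)
  for (i in 1:40) {
    routes <- lapply(seq_len(sample(1:6, 1)), function(j)
      make_summary(pool[sample.int(nrow(pool), sample(2:8, 1)), ]))
    routes <- rank_routes(routes)
    prev <- c(complete = FALSE, partial = FALSE)
    for (N in 1:6) {
      comp <- complete_solvability(routes, targets, N)
      part <- partial_solvability(routes, targets, N)
      if (comp) expect_true(part)          # complete implies partial
      expect_true(comp >= prev[["complete"]])  # monotone in N
      expect_true(part >= prev[["partial"]])
      prev <- c(complete = comp, partial = part)
    }
    for (r in routes) {
      if (route_accuracy(r, ref)) {
        expect_true(intermediate_accuracy(r, ref))
        expect_equal(f1_score(r, ref)$combined, 1)
      }
      ## F1 = 1 iff exact node+edge match (targets removed)
      f <- f1_score(r, ref)
      if (f$combined == 1) expect_true(route_accuracy(r, ref))
    }
  }
})
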