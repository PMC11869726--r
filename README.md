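# convergentretro

Convergent retrosynthesis planning for compound libraries, in R.

Drug-discovery teams synthesize *libraries* of related target molecules,
not single compounds, and good syntheses branch late: several targets are
made from shared **common intermediates** (a *convergent route*), which
cuts the number of reactions, the time and the cost of making the set.
Most computational retrosynthesis tools plan one target at a time and never
see this structure. This package provides:

- **Convergent route extraction** from atom-mapped reaction corpora:
  reactant/reagent partitioning by atom-map contribution (a left-side
  compound is a reactant when its mapped heavy atoms cover ≥ 20% of the
  product's), per-document synthesis graphs (molecules as nodes, one edge
  per product→reactant), weakly connected components, role assignment
  (target / building block / common intermediate), and cleaning filters
  for direction conflicts, cycles, stereoisomer-only target sets and
  duplicates — with per-reason discard accounting.
- **Multi-target multi-step planning**: all targets of a library are
  instantiated in one search graph; a pluggable single-step policy
  proposes up to K reactant sets per molecule; end nodes are scored by

  $$\mathrm{score}(m_i) = \frac{1}{|T_{m_i}|}\sum_{t \in T_{m_i}} \max_{P(t,\,m_i)} \prod_{c \in P} \mathbb{P}(c)$$

  (best probability product over linear paths from each reaching target,
  averaged over reaching targets), so intermediates shared by many targets
  are explored first. Search stops on exhaustion, wall-clock time, or a
  policy-batch budget.
- **Route extraction and ranking**: pruning to building-block-terminated
  chemistry, building-block scoring, greedy assembly of complete
  convergent routes, ranking by probability product, and summarization to
  molecule-only DAGs.
- **Evaluation**: complete/partial solvability, exact route and
  common-intermediate accuracy, a combined route F1 (reaction-edge F1 +
  non-target molecule F1), and reaction name/class accuracy through a
  pluggable classifier interface.
- **A synthetic toy chemistry** (`generate_universe()`) with real,
  parseable SMILES, exact atom maps, known convergent ground truth,
  controlled corruptions and an oracle policy — so every stage is testable
  end to end without external data or a trained model.

Chemistry standardization (canonical SMILES, salt stripping, stereo
preservation) is delegated to OpenBabel via ChemmineOB; graphs lean on
igraph.

## Worked example

```r
library(convergentretro)

# a small synthetic benchmark with known ground truth
uni <- generate_universe(universe_config(n_libraries = 4,
                                         targets_per_library = c(2, 5),
                                         depth = c(1, 4), seed = 2026))
uni
#> <synthetic_universe: 4 libraries, 23 reactions, 40 stock molecules>

# curate the raw documents back into convergent routes
corpus <- process_raw_reactions(uni$documents)
extraction <- extract_convergent_routes(corpus)
extraction$summary
#> # A tibble: 1 × 2
#>   reason       n
#>   <chr>    <int>
#> 1 retained     4
extraction$stats[, c("route_id", "n_targets", "n_common_intermediates",
                     "n_reactions", "depth_max")]
#> # A tibble: 4 × 5
#>   route_id   n_targets n_common_intermediates n_reactions depth_max
#>   <chr>          <int>                  <int>       <int>     <dbl>
#> 1 route-0001         2                      1           4         3
#> 2 route-0002         3                      2           9         4
#> 3 route-0003         4                      1           6         3
#> 4 route-0004         3                      2           4         2

# plan one library with the oracle single-step policy
doc <- names(uni$libraries)[1]
result <- run_search(uni$libraries[[doc]], oracle_policy(uni), uni$stock,
                     search_config(iterations_per_molecule = 40))
result$log$stop_reason
#> [1] "all_explored"
routes <- extract_routes(result$graph)
routes[[1]]
#> <route_summary: 7 molecules, 6 edges, 2 targets, score 0.6561>

# score against the experimentally validated reference
reference <- uni$true_routes[[doc]]
complete_solvability(routes, graph_targets(reference), N = 1)
#> [1] TRUE
route_accuracy(routes[[1]], reference)
#> [1] TRUE
f1_score(routes[[1]], reference)$combined
#> [1] 1
```

The four generated libraries are all recovered by extraction (`retained:
4`, no discards); the planner's top route for the first library covers both
of its targets in a single connected route (`complete_solvability` at
N = 1), reproduces the reference exactly, and scores a combined F1 of 1.
The route's rank score 0.6561 = 0.9⁴ is the product of the oracle's
single-step probabilities along its four reactions.

To plan with a real single-step model, wrap it in the policy contract — a
function taking a character vector of product keys and returning, per
product, up to K proposals `list(reactants =, probability =)` — and pass it
to `run_search()`. A command-line wrapper for the four stages (`simulate`,
`extract`, `plan`, `evaluate`) ships in `inst/cli/convergent-retro`.

## The methods vignette

`vignettes/convergent-route-planning.Rmd` documents the models and
procedures in full: the scoring rule and its reading of path-less targets,
invalid-reactant and tie-breaking rules, budget semantics, the pruning
fixpoint, what the synthetic universe does and does not emulate, and known
limitations.
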