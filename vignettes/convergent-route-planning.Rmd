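---
title: "Convergent retrosynthesis: route extraction, multi-target planning and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergent retrosynthesis: route extraction, multi-target planning and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Medicinal chemists rarely make one compound at a time. A library of
structurally related targets is usually synthesized together, branching late
from shared *common intermediates* — a convergent route. This package
implements three connected pieces of machinery around that idea, plus a
synthetic chemistry that makes all of it testable end to end without any
external data or trained model:

1. **Extraction** of experimentally validated convergent routes from
   atom-mapped reaction corpora (`load_corpus()`,
   `extract_convergent_routes()`).
2. **Planning**: a multi-target multi-step retrosynthetic search that
   instantiates a whole compound library in one search graph and biases
   exploration toward molecules shared between targets (`run_search()`,
   `extract_routes()`).
3. **Evaluation** of proposed routes against reference routes:
   solvability, exact-match accuracies and a route-level F1
   (`evaluate_testset()`).

```{r setup, eval = FALSE}
library(convergentretro)
```

## The data model

Molecules are identified by a canonical key: the canonical SMILES of the
largest fragment after salt splitting, with atom maps removed and all
reported stereochemistry preserved (`standardize_molecule()`). OpenBabel
performs the canonicalization; atom-map bookkeeping is done by the package
because maps carry the reaction roles and must be read before they are
stripped.

A reaction record partitions its left side by **atom-map contribution**: a
compound whose mapped heavy atoms cover at least 20% of the product's heavy
atoms is a reactant, everything else is a reagent and retained only as
metadata. The threshold is inclusive at exactly 0.20 and is computed on
heavy atoms (atom maps are defined on heavy atoms in standard corpora; the
field's corpora do not map hydrogens, so a heavy-atom fraction is the only
interpretation that is computable from the data).

A per-document **synthesis graph** has molecules as nodes and one directed
edge from each product to each of its reactants. No reaction nodes are kept
at this stage. Roles follow the degree structure:

* in-degree 0 → *target*;
* out-degree 0 → *building block*;
* in-degree > 1 **and** reachable from ≥ 2 targets → *common
  intermediate* (a building block can hold this role simultaneously).

The reachability condition matters: in-degree alone would misclassify a
diamond motif under a single target as convergent.

## Extraction and filtering

`extract_convergent_routes()` builds one graph per document, splits weakly
connected components, and then cleans:

* **Direction conflicts.** If both orientations of a molecule pair occur,
  the orientation with the strictly higher corpus-wide count wins; a tie
  discards the graph (`unresolved_direction`). Counts are tallied over the
  whole corpus rather than per document — a direction that is rare in one
  document is still resolvable from the rest of the data. Resolution runs
  *before* cycle detection so a two-cycle born of direction ambivalence is
  not confused with a genuine reaction cycle.
* **Cycles.** A molecule synthesized twice through different pathways
  creates a directed cycle; such graphs are discarded (`cycle`), not
  repaired, because the preferable pathway cannot be established from the
  record alone.
* **Convergence.** Graphs without a common intermediate are discarded.
* **Stereoisomer targets.** Targets are collapsed by their stereo-stripped
  canonical key; a graph left with fewer than two distinct targets is
  discarded (`stereoisomer_targets`).
* **Duplicates.** Graph identity is the sorted canonical edge list; later
  copies are discarded (`duplicate`).

Every discard is counted by reason, and `route_stats()` reports per-route
statistics (targets, common intermediates, building blocks, molecules,
reactions, reactants per reaction). Because no authority defines whether a
route's "depth" is the maximum or the mean over targets of the longest path
length, the table reports both (`depth_max`, `depth_mean`).

## The multi-target search

All targets of a library enter one bipartite search graph of molecule nodes
and reaction nodes. A pluggable single-step policy proposes, for a product
$m$, up to $K$ reactant sets $r = \{r_1, \dots, r_j\}$, each with a
probability. Each proposal becomes a reaction node under $m$; duplicate
reactant sets under one parent collapse, so a molecule node has at most $K$
outgoing edges, and a molecule key exists at most once in the whole graph —
proposals that rediscover a known molecule link to the existing node. This
sharing is what makes the search convergent: an intermediate proposed for
several targets accumulates paths from all of them and its score rises
accordingly.

An **end node** $m_i$ is a molecule node with no outgoing edges that is not
in the stock $B$ and whose shortest distance to any target is strictly
below the maximum depth $L$. Its score is

$$
\mathrm{score}(m_i) \;=\;
\frac{1}{|T_{m_i}|}\sum_{t \in T_{m_i}}
\max_{P(t,\,m_i)} \prod_{c \,\in\, P} \mathbb{P}(c),
$$

where $T_{m_i}$ are the targets with at least one path to $m_i$, the max
runs over linear paths, and the product runs over the reaction nodes on the
path. Targets without a path are excluded from the average rather than
contributing zeros — a deliberate reading: the score measures how good the
node is *for the targets it can serve*, while coverage is handled later by
the solvability metrics. Each iteration scores all eligible end nodes,
takes the top $n$, queries the policy for all of them in one batch, and
expands.

Numerical and determinism choices:

* Probabilities accumulate in log space (a depth-8 route multiplies eight
  probabilities; underflow is otherwise plausible) and policies must supply
  strictly positive probabilities.
* Ties everywhere break by (score desc, shortest depth asc, canonical key
  asc), so a deterministic policy yields a byte-reproducible search.
* A proposed reactant is **invalid** when it is unparsable, equal to the
  parent product, or an ancestor of the parent. The ancestor rule is
  deliberately strict — it keeps the search graph a DAG, which is what
  makes the path-product score well defined and computable by dynamic
  programming; admitting back-edges would turn scoring into simple-path
  enumeration in a cyclic graph. An invalid proposal keeps its reaction
  node (childless and flagged) so the beam slot is visibly consumed.
* A node whose expansion produced no valid reaction (or whose policy call
  failed) is marked explored and never re-selected; otherwise a zero-yield
  expansion would be retried forever.
* A target already in the stock is flagged a building block immediately
  and never expanded.

The search stops when no eligible end nodes remain (`all_explored`), when
wall-clock time exceeds `time_per_molecule × |targets|` (`time_limit`), or
when the number of policy batches reaches
`⌊iterations_per_molecule × |targets| / batch_size⌋` (`iteration_limit`) —
whichever trips first. Batching only rescales the iteration budget; the
`n` promising nodes of one iteration always form one policy call.

### Defaults

| Parameter | Default | Meaning |
|---|---|---|
| `K` | 5 | beam proposals used per molecule |
| `n_promising` | 10 | end nodes expanded per iteration |
| `max_depth` (`L`) | 8 | maximum route depth, reaction steps (strict `<`) |
| `time_per_molecule` | 120 s | wall-clock budget per target |
| `iterations_per_molecule` | 300 | iteration budget per target |
| `max_targets` | 300 | library size cap per search |
| `batch_size` | 10 | policy batch width (budget rescaling only) |

## Route extraction and summarization

`prune_unsolvable()` first deletes, to a fixpoint, everything that cannot
be acted on: invalidated reaction nodes, reactions missing any reactant
(a reaction needs *all* of its reactants), non-stock molecule leaves, and
anything no longer reachable from a target. Unsolved targets survive as
bare roots so coverage can be reported honestly; every other leaf of a
pruned graph is stock.

Building blocks are then scored with the same max-path/mean-target rule
(a target that is itself stock scores 1 via the empty product).
`extract_routes()` assembles complete routes greedily: the best-scoring
building block seeds a route; targets that reach the seed are tied to it
through their maximum-probability paths; every remaining unresolved
molecule takes its highest-scoring reaction choice whose sub-route
terminates in stock; and alternative reaction choices per molecule provide
further variants per seed (`max_routes_per_block`, a tunable, since no
authority prescribes the breadth of backtracking). Two choices here are
the package's own:

* A route is restricted to the weakly connected component of its seed.
  Without this the assembly would union disconnected sub-routes into one
  object and "complete solvability" would be trivially overstated.
* A route may cover a subset of the library: its covered targets are
  exactly the targets connected into the chosen reactions. Whether one
  route covers everything is the complete-solvability metric's business.

Routes are ranked by the product of their step probabilities (ties: fewer
reactions, then canonical edge order) and summarized by deleting the
reaction nodes: each product connects directly to each chosen reactant,
the step probability moves onto the edges, and roles are recomputed on the
summarized DAG with the same rules used for reference routes — which is
what makes proposed and reference routes directly comparable.

## Evaluation

Given ranked summarized routes and a reference convergent route per
library:

* **Complete solvability@N** — one single route among the top N covers all
  targets. **Partial@N** — every target appears in at least one top-N
  route. Complete implies partial, and both are monotone in N.
* **Route accuracy@N** — exact edge-set equality with the reference;
  deliberately stringent (one different halogen anywhere fails it).
  **Intermediate accuracy@N** — exact equality of the common-intermediate
  sets.
* **F1** — reaction F1 over edge sets and molecule F1 over node sets with
  all target molecules removed (short routes with many targets would
  otherwise be flattered), combined as the arithmetic mean. Degenerate
  conventions are explicit: no true positives → 0; both sides empty → 1.
* **Reaction name/class accuracy** — a pluggable classifier maps each
  (reactant set, product) pair to a name and a coarser class; comparisons
  are on sets after dropping `Unrecognized`, and an all-unrecognized
  comparison is flagged degenerate rather than silently counted as a
  match. The bundled classifier is a transparent lookup over the synthetic
  universe's reaction templates; commercial classifiers plug in through
  the same two-argument interface.

## The synthetic universe

`generate_universe()` builds libraries with known ground truth. Molecules
are genuine parseable SMILES: unbranched chains over C/N/O, optionally
carrying one cis/trans double bond. A reaction concatenates its reactants'
chains into the product chain, which makes atom maps exact by construction
and keeps every reactant at ≥ 20% of the product's heavy atoms (partner
fragments are sized to preserve the fraction; when two intermediates are
too size-disparate to combine, the smaller one first grows through unary
steps, so realized depths can exceed the nominal range by a step or two).
Documents realize each library's reactions as mapped reaction SMILES,
sprinkled with unmapped spectator reagents and occasional salt fragments
so the standardization and role-splitting code paths are exercised for
real. Decoy molecules used by the oracle policy always contain sulfur,
which the real grammar never emits — a decoy can never collide with a true
molecule or the stock.

What the generator deliberately does **not** emulate: chemically sensible
transformations (templates are labels, not mechanisms), branched or cyclic
skeletons, stereocenters beyond one double bond, yield–structure
correlation, and the scale of patent corpora. Passing tests therefore
demonstrate the correctness of the graph algorithms, bookkeeping and
metrics under realistic *structure*, not chemical plausibility of proposed
routes — the latter is entirely the single-step policy's burden, which is
why the policy interface is the package's main extension point.

`corrupt_documents()` injects defects with known outcomes (a length-3
cycle, a direction flip with or without majority support, a duplicated
document, a stereo-twin target pair), so the extraction filter's discard
accounting can be asserted exactly. `oracle_policy()` controls the true
set's beam position, the decoy count and the decoy probability mass; with
a perfect oracle the whole pipeline reproduces every true route at rank 1,
and raising the decoy mass under a tight budget degrades solvability
monotonically.

## Problem sizes used in the test suite

The shipped tests run, per property: 200 random DAGs (≤ 12 molecule nodes)
against a brute-force all-paths scoring oracle, exact to 1e-12 in log
space; 50 seeded universes round-tripped through extraction, 20 of them
with injected corruptions whose discard reasons must match exactly; 20
libraries (2–10 targets, depth ≤ 6) planned with the perfect oracle and
recovered at rank 1 with F1 = 1; 500 random route pairs against a
set-arithmetic F1 oracle; and a three-point decoy-mass sweep whose mean
complete solvability must not increase. These sizes were chosen so the
full suite documents the package's behavior at convincing scale while
remaining a coffee-break run on a laptop.

## Known limitations

* OpenBabel and RDKit canonicalization can disagree on exotic structures;
  keys from this package should not be mixed with keys canonicalized
  elsewhere.
* The greedy route assembly is complete per emitted route but does not
  enumerate all routes in the graph; with `max_routes_per_block` variants
  per seed it explores alternatives breadth-first by building-block score,
  under a wall-clock budget.
* Scoring excludes targets without a path from an end node's average; two
  end nodes serving different target subsets can therefore tie even though
  one serves more targets. The convergence bias comes from shared nodes
  accumulating paths, not from an explicit coverage term.
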