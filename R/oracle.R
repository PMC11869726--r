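## Oracle single-step policy, controlled document corruptions, and the toy
## reaction classifier for a synthetic universe.

## fresh chain-grammar molecules that avoid a set of known canonical keys
draw_unseen_chain <- function(known, n_atoms, alphabet = c("C", "C", "C", "N", "O"),
                              prefix = "") {
  for (attempt in 1:200) {
    raw <- paste0(prefix, paste(sample(alphabet, n_atoms, replace = TRUE),
                                collapse = ""))
    key <- standardize_molecule(raw)
    if (!key %in% known) return(list(key = key, raw = raw))
  }
  stop("could not draw an unseen molecule")
}

#' Corrupt the documents of a synthetic universe
#'
#' Injects controlled defects whose discard reasons the extraction pipeline
#' must reproduce exactly:
#' \describe{
#'   \item{`add_cycle`}{adds a reaction turning a grandchild back into a
#'     product of its ancestor, creating a length-3 directed cycle
#'     (discard reason `cycle`).}
#'   \item{`flip_direction`}{adds the reverse orientation of one true
#'     reaction so both directions occur once corpus-wide; the tie cannot
#'     be resolved (discard reason `unresolved_direction`).}
#'   \item{`flip_direction_resolved`}{adds the reverse orientation but also
#'     duplicates the true record, giving the true direction majority
#'     support; the graph survives unchanged.}
#'   \item{`duplicate_graph`}{re-emits a whole document under a new
#'     document id (discard reason `duplicate` for the copy).}
#'   \item{`make_stereo_twins`}{replaces a document with a two-target
#'     library whose targets are cis/trans twins of one molecule (discard
#'     reason `stereoisomer_targets`).}
#' }
#'
#' @param universe A `synthetic_universe`.
#' @param ops Character vector of operations (repeats allowed) or a named
#'   integer vector of counts per operation.
#' @param seed Integer seed controlling which documents are hit.
#' @return List with `documents` (the corrupted raw reaction table),
#'   `affected` (named list of document ids per op) and `expected` (tibble
#'   of `document_id`, `reason` for every injected discard).
#' @export
corrupt_documents <- function(universe, ops, seed = 1L) {
  supported <- c("add_cycle", "flip_direction", "flip_direction_resolved",
                 "duplicate_graph", "make_stereo_twins")
  if (is.null(names(ops))) {
    ops_vec <- as.character(ops)
  } else {
    ops_vec <- rep(names(ops), as.integer(ops))
  }
  if (!all(ops_vec %in% supported)) {
    stop("unsupported corruption op(s): ",
         paste(setdiff(ops_vec, supported), collapse = ", "))
  }
  with_seed(seed, {
    documents <- universe$documents
    reactions <- universe$reactions
    known <- universe$molecules$key
    affected <- stats::setNames(vector("list", length(supported)), supported)
    expected <- list()
    free_docs <- names(universe$libraries)
    n_stw <- 0L

    doc_reactions <- function(doc) reactions[reactions$document_id == doc, , drop = FALSE]

    ## documents with a grandparent chain (needed for a genuine 3-cycle)
    cycle_candidates <- function(doc) {
      sub <- doc_reactions(doc)
      for (i in seq_len(nrow(sub))) {
        for (ci in seq_along(sub$children[[i]])) {
          a <- sub$children[[i]][ci]
          j <- which(sub$product == a)
          if (!length(j)) next
          for (cj in seq_along(sub$children[[j[1]]])) {
            cc <- sub$children[[j[1]]][cj]
            if (cc %in% sub$children[[i]]) next  # avoid a direct 2-cycle
            return(list(r1 = sub[i, ], a_idx = ci, r2 = sub[j[1], ], c_idx = cj))
          }
        }
      }
      NULL
    }

    for (op in ops_vec) {
      pickable <- free_docs
      if (op == "add_cycle") {
        pickable <- pickable[vapply(pickable, function(d)
          !is.null(cycle_candidates(d)), logical(1))]
      }
      if (op != "make_stereo_twins" && !length(pickable)) {
        stop("no eligible document left for op ", op)
      }
      doc <- if (length(pickable)) sample(pickable, 1L) else NA_character_
      free_docs <- setdiff(free_docs, doc)
      yield <- round(stats::runif(1, 5, 95), 1)

      if (op == "add_cycle") {
        cand <- cycle_candidates(doc)
        p_raw <- cand$r1$product_raw
        off <- cand$r1$offsets[[1]][cand$a_idx] + cand$r2$offsets[[1]][cand$c_idx]
        c_raw <- cand$r2$children_raws[[1]][cand$c_idx]
        h_c <- length(chain_tokens(c_raw)$atoms)
        h_p <- length(chain_tokens(p_raw)$atoms)
        left_maps <- rep(NA_integer_, h_p)
        left_maps[(off + 1L):(off + h_c)] <- seq_len(h_c)
        smiles <- paste0(mapped_chain(p_raw, left_maps), ">>",
                         mapped_chain(c_raw, seq_len(h_c)))
        documents <- rbind(documents, tibble::tibble(
          reaction_smiles = smiles, document_id = doc, yield = yield))
        expected[[length(expected) + 1L]] <- tibble::tibble(
          document_id = doc, reason = "cycle")
      } else if (op %in% c("flip_direction", "flip_direction_resolved")) {
        sub <- doc_reactions(doc)
        r <- sub[1, ]
        a_raw <- r$children_raws[[1]][1]
        off <- r$offsets[[1]][1]
        h_a <- length(chain_tokens(a_raw)$atoms)
        h_p <- length(chain_tokens(r$product_raw)$atoms)
        left_maps <- rep(NA_integer_, h_p)
        left_maps[(off + 1L):(off + h_a)] <- seq_len(h_a)
        rev_smiles <- paste0(mapped_chain(r$product_raw, left_maps), ">>",
                             mapped_chain(a_raw, seq_len(h_a)))
        documents <- rbind(documents, tibble::tibble(
          reaction_smiles = rev_smiles, document_id = doc, yield = yield))
        if (op == "flip_direction_resolved") {
          documents <- rbind(documents, tibble::tibble(
            reaction_smiles = r$reaction_smiles, document_id = doc,
            yield = r$yield))
        } else {
          expected[[length(expected) + 1L]] <- tibble::tibble(
            document_id = doc, reason = "unresolved_direction")
        }
      } else if (op == "duplicate_graph") {
        sub <- documents[documents$document_id == doc, , drop = FALSE]
        sub$document_id <- paste0(doc, "-DUP")
        documents <- rbind(documents, sub)
        expected[[length(expected) + 1L]] <- tibble::tibble(
          document_id = paste0(doc, "-DUP"), reason = "duplicate")
      } else if (op == "make_stereo_twins") {
        n_stw <- n_stw + 1L
        twin_doc <- if (is.na(doc)) sprintf("STW-%02d", n_stw) else doc
        documents <- documents[documents$document_id != twin_doc, , drop = FALSE]
        i_mol <- draw_unseen_chain(known, 4L)
        known <- c(known, i_mol$key)
        b_mol <- draw_unseen_chain(known, 4L)
        known <- c(known, b_mol$key)
        h_i <- length(chain_tokens(i_mol$raw)$atoms)
        h_b <- length(chain_tokens(b_mol$raw)$atoms)
        twin_record <- function(prefix) {
          t_raw <- paste0(prefix, i_mol$raw, b_mol$raw)
          h_t <- length(chain_tokens(t_raw)$atoms)
          pre <- h_t - h_i - h_b
          prod_maps <- rep(NA_integer_, h_t)
          prod_maps[(pre + 1L):h_t] <- (pre + 1L):h_t
          paste0(mapped_chain(i_mol$raw, (pre + 1L):(pre + h_i)), ".",
                 mapped_chain(b_mol$raw, (pre + h_i + 1L):(pre + h_i + h_b)),
                 ">>", mapped_chain(t_raw, prod_maps))
        }
        documents <- rbind(documents,
          tibble::tibble(reaction_smiles = twin_record("C/C=C/"),
                         document_id = twin_doc, yield = yield),
          tibble::tibble(reaction_smiles = twin_record("C/C=C\\"),
                         document_id = twin_doc,
                         yield = round(stats::runif(1, 5, 95), 1)))
        expected[[length(expected) + 1L]] <- tibble::tibble(
          document_id = twin_doc, reason = "stereoisomer_targets")
        doc <- twin_doc
      }
      affected[[op]] <- c(affected[[op]], doc)
    }
    list(documents = documents,
         affected = affected[!vapply(affected, is.null, logical(1))],
         expected = if (length(expected)) do.call(rbind, expected)
                    else tibble::tibble(document_id = character(0),
                                        reason = character(0)))
  })
}

#' Oracle single-step policy over a synthetic universe
#'
#' For any product that occurs in a true route, the returned beam contains
#' the true reactant set (probability `top1_prob`) at a configurable beam
#' position, surrounded by decoy proposals of dead-end sulfur molecules
#' that are never in stock. Unknown products receive decoys only. The
#' policy is deterministic given the seed.
#'
#' @param universe A `synthetic_universe`.
#' @param top1_prob Probability attached to the true reactant set.
#' @param decoy_count Number of decoy proposals per product.
#' @param decoy_prob Probability scale of the decoy proposals (their
#'   probability mass); raise it to make the oracle noisier.
#' @param true_position Beam position (1-based) at which the true set
#'   appears.
#' @param seed Seed for the decoy pool.
#' @param omit_products Canonical keys the oracle pretends not to know.
#' @return A policy function `(products) -> list of proposal lists`
#'   satisfying the planner contract.
#' @export
oracle_policy <- function(universe, top1_prob = universe$config$oracle_top1_prob,
                          decoy_count = universe$config$decoy_count,
                          decoy_prob = 0.3, true_position = 1L, seed = 1L,
                          omit_products = character(0)) {
  stopifnot(top1_prob > 0, top1_prob <= 1, decoy_prob > 0, decoy_prob <= 1)
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(universe$reactions))) {
    assign(universe$reactions$product[i], universe$reactions$children[[i]],
           envir = lookup)
  }
  known <- c(universe$molecules$key)
  pool <- with_seed(seed, {
    keys <- character(0)
    while (length(keys) < 30L) {
      m <- draw_unseen_chain(c(known, keys), sample(5:10, 1L),
                             alphabet = c("C", "S", "C", "O", "N"), prefix = "S")
      keys <- c(keys, m$key)
    }
    keys
  })
  n_pool <- length(pool)
  decoy_set <- function(h, j) {
    idx1 <- (h + j * 13L) %% n_pool + 1L
    if ((h + j) %% 3L == 0L) {
      idx2 <- (h + j * 29L) %% n_pool + 1L
      unique(pool[c(idx1, idx2)])
    } else pool[idx1]
  }
  function(products) {
    out <- lapply(products, function(p) {
      h <- sum(utf8ToInt(p)) %% 997L
      true_set <- if (p %in% omit_products) NULL else lookup[[p]]
      beam <- lapply(seq_len(decoy_count), function(j)
        list(reactants = decoy_set(h, j),
             probability = decoy_prob * 0.85^j))
      if (!is.null(true_set)) {
        pos <- min(true_position, decoy_count + 1L)
        beam <- append(beam, list(list(reactants = true_set,
                                       probability = top1_prob)),
                       after = pos - 1L)
      }
      beam
    })
    names(out) <- products
    out
  }
}

#' Toy reaction classifier for a synthetic universe
#'
#' A transparent stand-in for a commercial reaction classifier: every
#' generated reaction carries a template name and class, and the classifier
#' looks proposed (reactant set, product) pairs up against that ledger.
#' Anything else is `Unrecognized`.
#'
#' @param universe A `synthetic_universe`.
#' @return A function `(reactants, product) -> list(name =, class =)`.
#' @export
toy_classifier <- function(universe) {
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(universe$reactions))) {
    key <- paste(universe$reactions$product[i],
                 paste(sort(universe$reactions$children[[i]]), collapse = "+"),
                 sep = " | ")
    assign(key, c(universe$reactions$template_name[i],
                  universe$reactions$template_class[i]), envir = lookup)
  }
  function(reactants, product) {
    hit <- lookup[[paste(product, paste(sort(reactants), collapse = "+"),
                         sep = " | ")]]
    if (is.null(hit)) list(name = "Unrecognized", class = "Unrecognized")
    else list(name = hit[1], class = hit[2])
  }
}

#' Plan every library of a synthetic universe
#'
#' Convenience pipeline: runs the multi-target search per library with the
#' given policy and extracts ranked summarized routes.
#'
#' @param universe A `synthetic_universe`.
#' @param policy A single-step policy (default: the perfect oracle).
#' @param config A [search_config()].
#' @param extract_budget Extraction budget in seconds per library.
#' @param max_routes_per_block Route variants per seed building block.
#' @return List with `predictions` (named list of ranked `route_summary`
#'   lists) and `logs` (per-library search logs).
#' @export
plan_libraries <- function(universe, policy = oracle_policy(universe),
                           config = search_config(), extract_budget = 30,
                           max_routes_per_block = 3L) {
  predictions <- list()
  logs <- list()
  for (doc in names(universe$libraries)) {
    res <- run_search(universe$libraries[[doc]], policy, universe$stock, config)
    predictions[[doc]] <- extract_routes(res$graph, budget = extract_budget,
                                         max_routes_per_block = max_routes_per_block)
    logs[[doc]] <- res$log
  }
  list(predictions = predictions, logs = logs)
}
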