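## Synthetic toy-chemistry universes with known convergent ground truth.
##
## Molecules are genuine, parseable SMILES assembled from a linear-chain
## fragment grammar over C/N/O (optionally with one cis/trans double bond),
## so the canonicalization, salt and atom-map code paths run for real. A
## reaction concatenates its reactants' chains into the product chain,
## which makes atom maps exact by construction and guarantees that every
## reactant passes the heavy-atom contribution rule. Decoy molecules used
## by the oracle policy always contain sulfur, which the real grammar never
## emits, so decoys can never collide with true molecules or stock.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## tokenize a chain-grammar SMILES into atoms and inter-atom bonds
chain_tokens <- function(raw) {
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  atoms <- character(0)
  bonds <- character(0)  # bond preceding each atom ("" for the first)
  pending <- ""
  for (ch in chars) {
    if (ch %in% c("C", "N", "O", "S")) {
      atoms <- c(atoms, ch)
      bonds <- c(bonds, pending)
      pending <- ""
    } else if (ch %in% c("=", "/", "\\")) {
      pending <- ch
    } else {
      stop("token '", ch, "' outside the chain grammar in: ", raw)
    }
  }
  list(atoms = atoms, bonds = bonds)
}

## emit a chain-grammar SMILES with atom maps on selected atoms
mapped_chain <- function(raw, maps) {
  tok <- chain_tokens(raw)
  n <- length(tok$atoms)
  stopifnot(length(maps) == n)
  valence <- c(C = 4L, N = 3L, O = 2L, S = 2L)
  order_of <- function(b) if (b == "=") 2L else if (b == "") 0L else 1L
  out <- character(n)
  for (i in seq_len(n)) {
    prev <- if (i == 1L) 0L else max(1L, order_of(tok$bonds[i]))
    nxt <- if (i == n) 0L else max(1L, order_of(tok$bonds[i + 1L]))
    h <- valence[[tok$atoms[i]]] - prev - nxt
    atom <- if (is.na(maps[i])) tok$atoms[i] else {
      hpart <- if (h <= 0L) "" else if (h == 1L) "H" else paste0("H", h)
      paste0("[", tok$atoms[i], hpart, ":", maps[i], "]")
    }
    out[i] <- paste0(tok$bonds[i], atom)
  }
  paste(out, collapse = "")
}

## assemble the atom-mapped reaction SMILES of one generated reaction
mapped_reaction_smiles <- function(product_raw, children_raws, offsets,
                                   reagent = NULL) {
  n <- length(chain_tokens(product_raw)$atoms)
  prod_maps <- rep(NA_integer_, n)
  left <- character(length(children_raws))
  for (i in seq_along(children_raws)) {
    h <- length(chain_tokens(children_raws[[i]])$atoms)
    idx <- (offsets[i] + 1L):(offsets[i] + h)
    prod_maps[idx] <- idx
    left[i] <- mapped_chain(children_raws[[i]], idx)
  }
  if (!is.null(reagent)) left <- c(left, reagent)
  paste0(paste(left, collapse = "."), ">>", mapped_chain(product_raw, prod_maps))
}

.toy_templates <- list(
  c("Amide coupling", "Acylation"),
  c("N-alkylation", "Alkylation"),
  c("Ester condensation", "Acylation"),
  c("Williamson ether synthesis", "Substitution"),
  c("Reductive amination", "Amination"),
  c("Suzuki coupling", "C-C bond formation"))

.spectator_reagents <- c("CS(C)=O", "ClCCl", "CC(=O)O", "[Na+].[OH-]")

#' Configuration for a synthetic reaction universe
#'
#' Ranges are inclusive `(min, max)` pairs sampled per library; defaults
#' describe small but structurally representative convergent libraries
#' (a handful of targets, routes a few reaction steps deep, one or two
#' common intermediates, one to three reactants per reaction).
#'
#' @param n_libraries Number of compound libraries (one document each).
#' @param targets_per_library Range of targets per library (2 to 300).
#' @param depth Range of route depths in reaction steps (1 to 8).
#' @param n_common_intermediates Range of common intermediates per library.
#' @param branching Range of reactants per reaction (1 to 3).
#' @param stock_size Number of extra purchasable molecules beyond the true
#'   building blocks.
#' @param oracle_top1_prob Probability value the oracle assigns to the true
#'   reactant set.
#' @param decoy_count Decoy proposals per product (at most 4, so the beam
#'   fits the default beam size of 5).
#' @param seed Integer seed; the universe is byte-identical under the same
#'   configuration.
#' @return A list of class `universe_config`.
#' @export
universe_config <- function(n_libraries = 10L, targets_per_library = c(2L, 6L),
                            depth = c(1L, 4L), n_common_intermediates = c(1L, 2L),
                            branching = c(1L, 3L), stock_size = 10L,
                            oracle_top1_prob = 0.9, decoy_count = 2L,
                            seed = 42L) {
  rng <- function(x) sort(as.integer(rep(x, length.out = 2L)))
  cfg <- list(n_libraries = as.integer(n_libraries),
              targets_per_library = rng(targets_per_library),
              depth = rng(depth),
              n_common_intermediates = rng(n_common_intermediates),
              branching = rng(branching), stock_size = as.integer(stock_size),
              oracle_top1_prob = as.numeric(oracle_top1_prob),
              decoy_count = as.integer(decoy_count), seed = as.integer(seed))
  if (cfg$n_libraries < 1L) stop("n_libraries must be positive")
  if (cfg$targets_per_library[1] < 2L || cfg$targets_per_library[2] > 300L)
    stop("targets_per_library must lie within [2, 300]")
  if (cfg$depth[1] < 1L || cfg$depth[2] > 8L)
    stop("depth must lie within [1, 8]")
  if (cfg$n_common_intermediates[1] < 1L)
    stop("at least one common intermediate is required")
  if (cfg$branching[1] < 1L || cfg$branching[2] > 3L)
    stop("branching must lie within [1, 3]")
  if (cfg$oracle_top1_prob <= 0 || cfg$oracle_top1_prob > 1)
    stop("oracle_top1_prob must lie in (0, 1]")
  if (cfg$decoy_count < 0L || cfg$decoy_count > 4L)
    stop("decoy_count must lie within [0, 4]")
  structure(cfg, class = "universe_config")
}

## molecule registry: guarantees global uniqueness of canonical keys,
## including after stereo stripping (so no two molecules are stereo twins
## unless deliberately constructed to be)
new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$keys <- new.env(parent = emptyenv())
  reg$stereo_free <- new.env(parent = emptyenv())
  reg$raw_of <- new.env(parent = emptyenv())
  reg
}

register_molecule <- function(reg, raw, allow_stereo_twin = FALSE) {
  key <- standardize_molecule(raw)
  sf <- standardize_stereo_free(raw)
  if (!is.null(reg$keys[[key]])) return(NULL)
  if (!allow_stereo_twin && !is.null(reg$stereo_free[[sf]])) return(NULL)
  assign(key, TRUE, envir = reg$keys)
  assign(sf, TRUE, envir = reg$stereo_free)
  assign(key, raw, envir = reg$raw_of)
  key
}

random_chain <- function(n_atoms, stereo_prob = 0) {
  stereo <- stats::runif(1) < stereo_prob
  body_n <- max(1L, n_atoms - if (stereo) 3L else 0L)
  ## oxygen never adjacent to another oxygen is not enforced; the chain
  ## grammar only needs to be parseable, not drug-like
  body <- paste(sample(c("C", "C", "C", "N", "O"), body_n, replace = TRUE),
                collapse = "")
  if (stereo) paste0(sample(c("C/C=C/", "C/C=C\\"), 1L), body) else body
}

fresh_molecule <- function(reg, n_atoms, stereo_prob = 0) {
  for (attempt in 1:200) {
    ## grow the chain when the small-molecule space gets crowded
    raw <- random_chain(n_atoms + sample(0:1, 1L) + attempt %/% 10, stereo_prob)
    key <- register_molecule(reg, raw)
    if (!is.null(key)) return(list(key = key, raw = raw,
                                   heavy = length(chain_tokens(raw)$atoms)))
  }
  stop("could not draw a fresh unique molecule; universe too crowded")
}

#' Generate a synthetic reaction universe with known convergent routes
#'
#' Builds, per library, a convergent synthesis graph (targets joined
#' through shared common intermediates down to building blocks), realizes
#' every reaction as an atom-mapped reaction SMILES in one document per
#' library, and returns the ground truth alongside the raw documents.
#'
#' @param config A [universe_config()].
#' @return An object of class `synthetic_universe`: `config`, `molecules`
#'   (tibble of canonical keys and raw chains), `true_routes` (named list
#'   of role-assigned `synthesis_graph`s), `libraries` (named list of
#'   target keys), `stock`, `documents` (raw reaction table with columns
#'   `reaction_smiles`, `document_id`, `yield`) and `reactions` (the
#'   generated reaction ledger, including template labels).
#' @export
generate_universe <- function(config = universe_config()) {
  stopifnot(inherits(config, "universe_config"))
  with_seed(config$seed, {
    reg <- new_registry()
    reaction_rows <- list()
    doc_rows <- list()
    libraries <- list()
    true_routes <- list()

    sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

    add_reaction <- function(doc, product, children, n_modifier, smiles) {
      tmpl <- .toy_templates[[sample.int(length(.toy_templates), 1L)]]
      yield <- round(stats::runif(1, 5, 95), 1)
      child_keys <- vapply(children, `[[`, character(1), "key")
      child_raws <- vapply(children, `[[`, character(1), "raw")
      child_heavy <- vapply(children, `[[`, numeric(1), "heavy")
      p_key <- product$key
      p_raw <- product$raw
      reaction_rows[[length(reaction_rows) + 1L]] <<- tibble::tibble(
        document_id = doc, product = p_key, product_raw = p_raw,
        children = list(child_keys), children_raws = list(child_raws),
        offsets = list(cumsum(c(0L, utils::head(child_heavy, -1L)))),
        n_modifier = n_modifier, template_name = tmpl[1],
        template_class = tmpl[2], reaction_smiles = smiles, yield = yield)
      doc_rows[[length(doc_rows) + 1L]] <<- tibble::tibble(
        reaction_smiles = smiles, document_id = doc, yield = yield)
    }

    ## every reactant must contribute at least 20% of the product's heavy
    ## atoms, or the reactant/reagent split would demote it to a reagent
    fractions_ok <- function(children) {
      h <- vapply(children, `[[`, numeric(1), "heavy")
      min(h) / sum(h) >= 0.2
    }

    ## one reaction step: product = concatenation of children (+ modifier
    ## atoms for unary steps); resampled partners keep canonical keys unique
    make_step <- function(doc, main, n_partners) {
      for (attempt in 1:50) {
        if (attempt > 25L) n_partners <- min(n_partners, 1L)
        partners <- if (n_partners > 0L) {
          lapply(seq_len(n_partners), function(i)
            fresh_molecule(reg, max(3L, ceiling(main$heavy / 2)),
                           stereo_prob = 0.08))
        } else list()
        children <- c(list(main), partners)
        if (length(children) > 1L && !fractions_ok(children)) next
        modifier <- if (n_partners == 0L)
          paste(sample(c("C", "O", "N"), sample(1:2, 1L), replace = TRUE),
                collapse = "") else ""
        product_raw <- paste0(paste(vapply(children, `[[`, character(1), "raw"),
                                    collapse = ""), modifier)
        key <- register_molecule(reg, product_raw)
        if (is.null(key)) next
        product <- list(key = key, raw = product_raw,
                        heavy = length(chain_tokens(product_raw)$atoms))
        reagent <- if (stats::runif(1) < 0.3)
          sample(.spectator_reagents, 1L) else NULL
        offsets <- cumsum(c(0L, utils::head(vapply(children, `[[`, numeric(1),
                                                   "heavy"), -1L)))
        smiles <- mapped_reaction_smiles(product_raw,
                                         lapply(children, `[[`, "raw"),
                                         offsets, reagent = reagent)
        if (stats::runif(1) < 0.1) smiles <- paste0(smiles, ".Cl")
        add_reaction(doc, product, children,
                     n_modifier = if (n_partners == 0L)
                       length(chain_tokens(modifier)$atoms) else 0L,
                     smiles = smiles)
        return(product)
      }
      stop("could not realize a unique product molecule")
    }

    ## one target chain: from its common intermediates up to the target
    build_target <- function(doc, cis, depth_goal) {
      first_n_react <- max(length(cis), sample_range(config$branching))
      extra <- min(first_n_react - length(cis), 3L - length(cis))
      main <- cis[[1]]
      ## size-disparate intermediates are grown by unary steps until the
      ## smallest keeps >= 20% of the combined product
      while (length(cis) > 1L && !fractions_ok(cis)) {
        smallest <- which.min(vapply(cis, `[[`, numeric(1), "heavy"))
        cis[[smallest]] <- make_step(doc, cis[[smallest]], 0L)
      }
      cur <- if (length(cis) > 1L || extra > 0L) {
        ## combine the common intermediates (+ optional partner) first; a
        ## partner is only admitted while every reactant keeps >= 20% of
        ## the product's heavy atoms
        for (attempt in 1:50) {
          if (attempt > 25L) extra <- 0L
          partners <- if (extra > 0L) lapply(seq_len(extra), function(i)
            fresh_molecule(reg, max(3L, ceiling(main$heavy / 2)),
                           stereo_prob = 0.08)) else list()
          children <- c(cis, partners)
          if (!fractions_ok(children) && extra > 0L) next
          product_raw <- paste(vapply(children, `[[`, character(1), "raw"),
                               collapse = "")
          key <- register_molecule(reg, product_raw)
          if (is.null(key)) {
            if (extra == 0L) {
              ## fixed children collide with a registered molecule (possibly
              ## only after stereo stripping): grow one to change the product
              smallest <- which.min(vapply(cis, `[[`, numeric(1), "heavy"))
              cis[[smallest]] <- make_step(doc, cis[[smallest]], 0L)
            }
            next
          }
          product <- list(key = key, raw = product_raw,
                          heavy = length(chain_tokens(product_raw)$atoms))
          offsets <- cumsum(c(0L, utils::head(vapply(children, `[[`,
            numeric(1), "heavy"), -1L)))
          add_reaction(doc, product, children, 0L,
                       mapped_reaction_smiles(product_raw,
                                              lapply(children, `[[`, "raw"),
                                              offsets))
          break
        }
        product
      } else {
        make_step(doc, main, sample_range(config$branching) - 1L)
      }
      steps_done <- 1L
      while (steps_done < depth_goal) {
        cur <- make_step(doc, cur, sample_range(config$branching) - 1L)
        steps_done <- steps_done + 1L
      }
      cur
    }

    for (lib in seq_len(config$n_libraries)) {
      doc <- sprintf("LIB-%03d", lib)
      k <- sample_range(config$targets_per_library)
      n_ci <- min(sample_range(config$n_common_intermediates), k - 1L)
      cis <- lapply(seq_len(n_ci), function(i) {
        if (stats::runif(1) < 0.5) {
          fresh_molecule(reg, sample(4:6, 1L), stereo_prob = 0.1)
        } else {
          a <- fresh_molecule(reg, sample(3:5, 1L), stereo_prob = 0.1)
          make_step(doc, a, 1L)
        }
      })
      ci_depth <- vapply(cis, function(ci)
        as.integer(any(vapply(reaction_rows, function(r)
          r$product == ci$key, logical(1)))), integer(1))
      ## chained assignment keeps the document weakly connected:
      ## CI_j bridges targets j and j+1
      targets <- character(k)
      for (j in seq_len(k)) {
        my_cis <- if (j <= n_ci + 1L) {
          idx <- unique(pmin(pmax(c(j - 1L, j), 1L), n_ci))
          cis[idx]
        } else {
          cis[sample.int(n_ci, 1L)]
        }
        base_depth <- max(ci_depth[vapply(my_cis, function(ci)
          which(vapply(cis, function(x) x$key == ci$key, logical(1)))[1],
          integer(1))])
        d <- max(base_depth + 1L, sample_range(config$depth))
        tgt <- build_target(doc, my_cis, depth_goal = d - base_depth)
        targets[j] <- tgt$key
      }
      libraries[[doc]] <- sort(targets)
    }

    reactions <- do.call(rbind, reaction_rows)
    documents <- do.call(rbind, doc_rows)

    for (doc in names(libraries)) {
      sub <- reactions[reactions$document_id == doc, , drop = FALSE]
      edges <- data.frame(
        parent = rep(sub$product, lengths(sub$children)),
        child = unlist(sub$children), stringsAsFactors = FALSE)
      graph <- assign_roles(synthesis_graph(edges, document_ids = doc, id = doc))
      true_routes[[doc]] <- graph
    }

    leaves <- setdiff(unlist(reactions$children), reactions$product)
    extra_stock <- vapply(seq_len(config$stock_size), function(i)
      fresh_molecule(reg, sample(3:6, 1L))$key, character(1))
    molecules <- tibble::tibble(key = ls(reg$raw_of),
                                raw = vapply(ls(reg$raw_of), function(k)
                                  reg$raw_of[[k]], character(1)))
    structure(list(config = config, molecules = molecules,
                   true_routes = true_routes, libraries = libraries,
                   stock = sort(unique(c(leaves, extra_stock))),
                   documents = documents, reactions = reactions),
              class = "synthetic_universe")
  })
}

#' @export
print.synthetic_universe <- function(x, ...) {
  cat("<synthetic_universe: ", length(x$libraries), " libraries, ",
      nrow(x$reactions), " reactions, ", length(x$stock),
      " stock molecules>\n", sep = "")
  invisible(x)
}
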