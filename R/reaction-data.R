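## Parsing and standardization of atom-mapped reaction records.
##
## A raw reaction arrives as `reactants>reagents>product` (or
## `reactants>>product`) SMILES with atom maps on the product side. The
## atom-map overlap between each left-side compound and the product decides
## whether that compound is a reactant (it contributes a substantial part of
## the product skeleton) or a reagent.

reaction_reject <- function(reason, detail = NULL) {
  structure(
    class = c("reaction_reject", "error", "condition"),
    list(message = paste0("reaction rejected [", reason, "]",
                          if (!is.null(detail)) paste0(": ", detail) else ""),
         call = NULL, reason = reason)
  )
}

#' Construct a raw atom-mapped reaction record
#'
#' @param reaction_smiles Reaction SMILES, `reactants>reagents>product` or
#'   `reactants>>product`, with atom maps on the product side.
#' @param document_id Opaque document (patent / notebook) identifier.
#' @param yield_pct Reported yield percentage in `[0, 100]`, or `NA`.
#' @return A list of class `raw_reaction`.
#' @export
raw_reaction <- function(reaction_smiles, document_id, yield_pct = NA_real_) {
  stopifnot(is.character(reaction_smiles), length(reaction_smiles) == 1L)
  structure(list(reaction_smiles = reaction_smiles,
                 document_id = as.character(document_id),
                 yield_pct = as.numeric(yield_pct)),
            class = "raw_reaction")
}

#' Split a reaction SMILES into its three sides
#'
#' @param reaction_smiles A reaction SMILES string.
#' @return A list with character vectors `left`, `agents`, `product_side`,
#'   each holding the dot-separated compounds of that side.
#' @keywords internal
parse_reaction_smiles <- function(reaction_smiles) {
  parts <- strsplit(reaction_smiles, ">", fixed = TRUE)[[1]]
  if (length(parts) == 2L) parts <- c(parts[1], "", parts[2])
  if (length(parts) != 3L) {
    stop(reaction_reject("malformed", reaction_smiles))
  }
  split_side <- function(s) {
    f <- strsplit(s, ".", fixed = TRUE)[[1]]
    f[nzchar(f)]
  }
  list(left = split_side(parts[1]),
       agents = split_side(parts[2]),
       product_side = split_side(parts[3]))
}

#' Partition the left side of a reaction into reactants and reagents
#'
#' A left-side compound is a reactant when its mapped heavy atoms account
#' for at least `threshold` of the product's heavy atoms (the boundary is
#' inclusive); everything else is retained as a reagent. Compounds in the
#' agents segment of the reaction SMILES are reagents by construction.
#'
#' @param raw A `raw_reaction` (see [raw_reaction()]).
#' @param threshold Minimum fraction of the product's heavy atoms a compound
#'   must contribute to count as a reactant. Default `0.20`.
#' @return A list of class `reaction_record` with fields `document_id`,
#'   `product`, `reactants`, `reagents` (canonical molecule keys) and
#'   `source_yield`.
#' @details Records are rejected (classed condition `reaction_reject`) when
#'   the product carries no atom maps, when more than one product-side
#'   fragment is mapped (multi-product reaction), or when no reactant
#'   survives the partition.
#' @export
split_reactants_reagents <- function(raw, threshold = 0.20) {
  p <- parse_reaction_smiles(raw$reaction_smiles)
  if (!length(p$product_side)) stop(reaction_reject("no_product", raw$reaction_smiles))
  prod_maps <- lapply(p$product_side, map_indices)
  mapped <- which(vapply(prod_maps, length, integer(1)) > 0L)
  if (length(mapped) == 0L) stop(reaction_reject("unmapped_product", raw$reaction_smiles))
  if (length(mapped) > 1L) stop(reaction_reject("multiple_products", raw$reaction_smiles))
  prod_frag <- p$product_side[mapped]
  prod_map_set <- prod_maps[[mapped]]
  n_heavy <- heavy_atom_count(prod_frag)

  product_key <- standardize_molecule(prod_frag)
  is_reactant <- vapply(p$left, function(cmp) {
    ov <- length(intersect(map_indices(cmp), prod_map_set))
    ov / n_heavy >= threshold
  }, logical(1))

  reactant_keys <- unique(standardize_molecule(p$left[is_reactant]))
  reagent_raw <- c(p$left[!is_reactant], p$agents)
  reagent_keys <- if (length(reagent_raw)) unique(standardize_molecule(reagent_raw)) else character(0)

  ## a left compound identical to the product adds no retrosynthetic step
  reactant_keys <- setdiff(reactant_keys, product_key)
  reagent_keys <- setdiff(reagent_keys, reactant_keys)
  if (length(reactant_keys) == 0L) stop(reaction_reject("no_reactants", raw$reaction_smiles))

  structure(list(document_id = raw$document_id,
                 product = product_key,
                 reactants = reactant_keys,
                 reagents = reagent_keys,
                 source_yield = raw$yield_pct),
            class = "reaction_record")
}

#' Process a table of raw reactions into a reaction corpus
#'
#' @param raw_table A data.frame with columns `reaction_smiles`,
#'   `document_id` and optionally `yield`.
#' @param min_yield Minimum yield percentage to retain a record, or `NULL`
#'   to keep everything. When a threshold is given, records without a
#'   reported yield are dropped.
#' @param threshold Reactant/reagent split threshold, see
#'   [split_reactants_reagents()].
#' @return A tibble of class `reaction_corpus` with one row per surviving
#'   record: `document_id`, `product`, `reactants` and `reagents`
#'   (list-columns of canonical keys) and `yield`. Records are grouped by
#'   (sorted on) `document_id` but deliberately not deduplicated across
#'   documents. Rejected records are tallied in `attr(, "rejects")`.
#' @export
process_raw_reactions <- function(raw_table, min_yield = NULL, threshold = 0.20) {
  for (col in c("reaction_smiles", "document_id")) {
    if (!col %in% names(raw_table)) {
      stop("reaction table is missing required column '", col, "'")
    }
  }
  has_yield <- "yield" %in% names(raw_table)
  if (!is.null(min_yield)) {
    if (!has_yield) stop("reaction table is missing required column 'yield'")
    keep <- !is.na(raw_table$yield) & raw_table$yield >= min_yield
    raw_table <- raw_table[keep, , drop = FALSE]
  }
  rejects <- character(0)
  rows <- vector("list", nrow(raw_table))
  for (i in seq_len(nrow(raw_table))) {
    rec <- tryCatch(
      split_reactants_reagents(
        raw_reaction(raw_table$reaction_smiles[i], raw_table$document_id[i],
                     if (has_yield) raw_table$yield[i] else NA_real_),
        threshold = threshold),
      reaction_reject = function(e) e)
    if (inherits(rec, "reaction_reject")) {
      rejects <- c(rejects, rec$reason)
    } else {
      rows[[i]] <- rec
    }
  }
  rows <- Filter(Negate(is.null), rows)
  corpus <- tibble::tibble(
    document_id = vapply(rows, `[[`, character(1), "document_id"),
    product = vapply(rows, `[[`, character(1), "product"),
    reactants = lapply(rows, `[[`, "reactants"),
    reagents = lapply(rows, `[[`, "reagents"),
    yield = vapply(rows, `[[`, numeric(1), "source_yield")
  )
  corpus <- corpus[order(corpus$document_id), , drop = FALSE]
  reject_tab <- if (length(rejects)) {
    as.data.frame(table(reason = rejects), stringsAsFactors = FALSE)
  } else {
    data.frame(reason = character(0), Freq = integer(0))
  }
  names(reject_tab) <- c("reason", "n")
  attr(corpus, "rejects") <- tibble::as_tibble(reject_tab)
  class(corpus) <- c("reaction_corpus", class(corpus))
  corpus
}

#' Load an atom-mapped reaction corpus from a delimited file
#'
#' Reads a tab- or comma-separated table with header columns
#' `reaction_smiles`, `document_id` and (optionally) `yield`, and processes
#' it into a standardized reaction corpus grouped by document.
#'
#' @param path Path to the reaction table.
#' @inheritParams process_raw_reactions
#' @return See [process_raw_reactions()]. An empty file yields an empty
#'   corpus without error.
#' @export
load_corpus <- function(path, min_yield = NULL, threshold = 0.20) {
  if (!file.exists(path)) stop("reaction file not found: ", path)
  if (file.size(path) == 0L) {
    return(process_raw_reactions(
      data.frame(reaction_smiles = character(0), document_id = character(0),
                 yield = numeric(0))))
  }
  tab <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  if ("document_id" %in% names(tab)) {
    tab$document_id <- as.character(tab$document_id)
  }
  process_raw_reactions(tab, min_yield = min_yield, threshold = threshold)
}

#' Serialize a reaction corpus to a delimited file
#'
#' Writes columns `document_id`, `product`, `reactants` and `reagents`, the
#' latter two dot-joined.
#'
#' @param corpus A `reaction_corpus`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, sep = "\t") {
  out <- data.frame(
    document_id = corpus$document_id,
    product = corpus$product,
    reactants = vapply(corpus$reactants, paste, character(1), collapse = "."),
    reagents = vapply(corpus$reagents, paste, character(1), collapse = "."),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
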