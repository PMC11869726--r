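## SMILES utilities: tokenizing, atom-map handling, canonicalization.
## Canonical forms come from OpenBabel (via ChemmineOB); everything that
## touches atom maps is done here, since maps carry the reactant/reagent
## information and must be read before canonicalization discards them.

.can_cache <- new.env(parent = emptyenv())

#' Tokenize the atoms of a SMILES string
#'
#' Splits a SMILES string into its atom tokens, keeping track of bracket
#' content and atom-map indices. Ring-bond digits, bond symbols, branches and
#' fragment separators are skipped. Hydrogens written as explicit bracket
#' atoms (`[H]`, isotopes included) are not counted as heavy atoms.
#'
#' @param smiles A single SMILES string.
#' @return A data.frame with one row per atom token: `symbol` (element),
#'   `aromatic` (logical), `map` (integer atom-map index or `NA`), and
#'   `heavy` (logical; `FALSE` only for explicit hydrogen atoms).
#' @keywords internal
smiles_atoms <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  sym <- character(0); arom <- logical(0); map <- integer(0)
  i <- 1L
  two_letter <- c("Cl", "Br", "Si", "Se", "As")
  organic <- c("B", "C", "N", "O", "P", "S", "F", "I")
  aromatic_organic <- c("b", "c", "n", "o", "p", "s")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced bracket in SMILES: ", smiles)
      content <- substr(smiles, i + 1L, j - 1L)
      m <- regmatches(content, regexec("^([0-9]*)([A-Za-z][a-z]?|\\*)", content))[[1]]
      if (length(m) == 0L) stop("cannot parse bracket atom [", content, "] in ", smiles)
      el <- m[3]
      mp <- regmatches(content, regexec(":([0-9]+)$", content))[[1]]
      sym <- c(sym, el)
      arom <- c(arom, el %in% aromatic_organic)
      map <- c(map, if (length(mp)) as.integer(mp[2]) else NA_integer_)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% two_letter) {
      sym <- c(sym, paste0(ch, chars[i + 1L]))
      arom <- c(arom, FALSE); map <- c(map, NA_integer_)
      i <- i + 2L
    } else if (ch %in% organic) {
      sym <- c(sym, ch); arom <- c(arom, FALSE); map <- c(map, NA_integer_)
      i <- i + 1L
    } else if (ch %in% aromatic_organic) {
      sym <- c(sym, ch); arom <- c(arom, TRUE); map <- c(map, NA_integer_)
      i <- i + 1L
    } else {
      ## bond orders, ring closures, branches, charges, separators
      i <- i + 1L
    }
  }
  el_norm <- ifelse(nchar(sym) == 1L, toupper(sym), sym)
  data.frame(symbol = el_norm, aromatic = arom, map = map,
             heavy = el_norm != "H", stringsAsFactors = FALSE)
}

#' Count heavy (non-hydrogen) atoms in a SMILES string
#'
#' @param smiles Character vector of SMILES strings.
#' @return Integer vector of heavy-atom counts.
#' @export
heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) sum(smiles_atoms(s)$heavy), integer(1),
         USE.NAMES = FALSE)
}

#' Atom-map indices present on the heavy atoms of a SMILES string
#'
#' @param smiles A single SMILES string.
#' @return Integer vector of map indices (unmapped atoms are omitted).
#' @export
map_indices <- function(smiles) {
  at <- smiles_atoms(smiles)
  at$map[at$heavy & !is.na(at$map)]
}

#' Remove atom-map indices from a SMILES string
#'
#' @param smiles Character vector of SMILES strings.
#' @return The strings with all `:n` atom-map suffixes removed.
#' @export
strip_atom_maps <- function(smiles) {
  gsub(":[0-9]+\\]", "]", smiles)
}

#' Remove stereochemistry descriptors from a SMILES string
#'
#' Drops cis/trans bond markers and tetrahedral chirality tags. Used to
#' detect targets that are mere stereoisomers of one another.
#'
#' @param smiles Character vector of SMILES strings.
#' @return The strings with `/`, `\\` and `@` descriptors removed.
#' @export
strip_stereo <- function(smiles) {
  gsub("@{1,2}", "", gsub("[/\\\\]", "", smiles))
}

## Canonicalize a vector of (map-free) SMILES through OpenBabel, with a
## process-level cache. Returns NA for unparsable entries.
.canonicalize <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  key <- smiles
  hit <- vapply(key, function(k) !is.null(.can_cache[[k]]), logical(1))
  out[hit] <- vapply(key[hit], function(k) .can_cache[[k]], character(1))
  todo <- which(!hit)
  if (length(todo)) {
    batch <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN",
                                                 paste(smiles[todo], collapse = "\n"))),
      error = function(e) NULL)
    lines <- if (is.null(batch)) character(0) else {
      l <- strsplit(batch, "\n", fixed = TRUE)[[1]]
      trimws(l[nzchar(trimws(l))])
    }
    if (length(lines) == length(todo)) {
      out[todo] <- lines
    } else {
      ## a parse failure truncates OpenBabel's batch output; retry singly
      for (i in todo) {
        one <- tryCatch(
          suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles[i])),
          error = function(e) "")
        one <- trimws(one)
        out[i] <- if (nzchar(one)) one else NA_character_
      }
    }
    for (i in todo) if (!is.na(out[i])) assign(key[i], out[i], envir = .can_cache)
  }
  out
}

#' Standardize a molecule to its canonical key
#'
#' Produces the canonical, salt-stripped molecule key used throughout the
#' package: atom maps are removed, the SMILES is split on fragment
#' separators, every fragment is canonicalized, and the largest fragment by
#' heavy-atom count is kept (ties broken by lexicographic order of the
#' canonical form). Reported stereochemistry is preserved. The operation is
#' idempotent.
#'
#' @param smiles Character vector of SMILES strings (atom maps allowed).
#' @return Character vector of canonical molecule keys.
#' @examples
#' \dontrun{
#' standardize_molecule("C1=CC=CC=C1")  # same key as "c1ccccc1"
#' standardize_molecule("CCN.Cl")       # salt stripped: key of "CCN"
#' }
#' @export
standardize_molecule <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) stop("cannot standardize empty structure")
    frags <- strsplit(strip_atom_maps(s), ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    if (!length(frags)) stop("cannot standardize empty structure: '", s, "'")
    can <- .canonicalize(frags)
    if (anyNA(can)) {
      stop("unparsable structure: '", frags[which(is.na(can))[1]], "' in '", s, "'")
    }
    hv <- heavy_atom_count(can)
    best <- which(hv == max(hv))
    if (length(best) > 1L) best <- best[order(can[best])][1]
    can[best]
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical key with stereochemistry removed
#'
#' Convenience wrapper: standardizes a molecule after deleting all stereo
#' descriptors, so that stereoisomers collapse to one key.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of stereo-free canonical keys.
#' @export
standardize_stereo_free <- function(smiles) {
  standardize_molecule(strip_stereo(smiles))
}
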