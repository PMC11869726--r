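## Route evaluation against experimentally validated convergent routes:
## solvability, exact-match accuracies, combined F1, and reaction
## name / class accuracy through a pluggable classifier.

edge_set <- function(x) {
  if (inherits(x, "route_summary")) {
    paste(x$edges$parent, x$edges$child, sep = ">")
  } else if (inherits(x, "synthesis_graph")) {
    paste(x$edges$parent, x$edges$child, sep = ">")
  } else stop("expected a route_summary or synthesis_graph")
}

node_set <- function(x) {
  if (inherits(x, "route_summary")) x$nodes
  else if (inherits(x, "synthesis_graph")) x$nodes
  else stop("expected a route_summary or synthesis_graph")
}

role_targets <- function(x) {
  if (inherits(x, "route_summary")) x$targets
  else graph_targets(x)
}

role_common_intermediates <- function(x) {
  if (inherits(x, "route_summary")) {
    names(x$roles)[vapply(x$roles, function(r) "common_intermediate" %in% r,
                          logical(1))]
  } else graph_common_intermediates(x)
}

## reactions of a route or reference as list(product =, reactants =)
reaction_list <- function(x) {
  if (inherits(x, "route_summary")) {
    lapply(names(x$reactions), function(p)
      list(product = p, reactants = sort(x$reactions[[p]]$reactants)))
  } else {
    parents <- unique(x$edges$parent)
    lapply(parents, function(p)
      list(product = p, reactants = sort(x$edges$child[x$edges$parent == p])))
  }
}

#' Complete solvability of a ranked route list
#'
#' `TRUE` when some single route among the top `N` jointly covers all the
#' library's target molecules (and, being a complete route, terminates in
#' purchasable building blocks).
#'
#' @param routes Ranked list of `route_summary` objects.
#' @param targets Character vector of target keys.
#' @param N Top-N cutoff.
#' @return Logical.
#' @export
complete_solvability <- function(routes, targets, N) {
  top <- utils::head(routes, N)
  any(vapply(top, function(r) all(targets %in% r$targets), logical(1)))
}

#' Partial solvability of a ranked route list
#'
#' `TRUE` when every target appears in at least one route among the top
#' `N`, irrespective of whether the targets are synthesized conjointly.
#'
#' @inheritParams complete_solvability
#' @return Logical.
#' @export
partial_solvability <- function(routes, targets, N) {
  top <- utils::head(routes, N)
  covered <- unique(unlist(lapply(top, `[[`, "targets")))
  all(targets %in% covered)
}

#' Exact route accuracy
#'
#' `TRUE` when the proposed summarized route and the reference route have
#' identical edge sets (order-free). Deliberately stringent: one different
#' molecule anywhere makes the route inaccurate.
#'
#' @param route A `route_summary`.
#' @param reference A role-assigned `synthesis_graph`.
#' @return Logical.
#' @export
route_accuracy <- function(route, reference) {
  setequal(edge_set(route), edge_set(reference))
}

#' Common-intermediate accuracy
#'
#' `TRUE` when the sets of common-intermediate molecule keys of the
#' proposed and reference routes match exactly.
#'
#' @inheritParams route_accuracy
#' @return Logical.
#' @export
intermediate_accuracy <- function(route, reference) {
  ref_ci <- role_common_intermediates(reference)
  if (length(ref_ci) == 0L) {
    stop("reference route has no common intermediates (not convergent)")
  }
  setequal(role_common_intermediates(route), ref_ci)
}

f1_from_sets <- function(proposed, reference) {
  tp <- length(intersect(proposed, reference))
  if (tp == 0L) {
    if (length(proposed) == 0L && length(reference) == 0L) return(1)
    return(0)
  }
  precision <- tp / length(proposed)
  recall <- tp / length(reference)
  2 * precision * recall / (precision + recall)
}

#' Route F1 score
#'
#' Reaction F1 over the summarized edge sets and molecule F1 over the node
#' sets with all target molecules removed from both sides (to avoid
#' skewing toward short routes with many targets); the combined score is
#' their arithmetic mean. Conventions: F1 is 0 when there are no true
#' positives, and 1 when both compared sets are empty.
#'
#' @inheritParams route_accuracy
#' @return List with `reaction_f1`, `molecule_f1` and `combined`.
#' @export
f1_score <- function(route, reference) {
  targets <- union(role_targets(route), role_targets(reference))
  reaction_f1 <- f1_from_sets(edge_set(route), edge_set(reference))
  molecule_f1 <- f1_from_sets(setdiff(node_set(route), targets),
                              setdiff(node_set(reference), targets))
  list(reaction_f1 = reaction_f1, molecule_f1 = molecule_f1,
       combined = (reaction_f1 + molecule_f1) / 2)
}

#' Reaction name and class accuracy
#'
#' Classifies every reaction of both routes with the supplied classifier,
#' drops `Unrecognized` assignments, and compares the resulting name sets
#' and class sets.
#'
#' @inheritParams route_accuracy
#' @param classifier Function `(reactants, product) -> list(name =, class =)`;
#'   unrecognized reactions return name `"Unrecognized"`. A classifier
#'   failure is treated as `Unrecognized`.
#' @return List with logicals `name_match` and `class_match`, and
#'   `degenerate` flagging the vacuous all-Unrecognized case.
#' @export
reaction_type_accuracy <- function(route, reference, classifier) {
  classify_all <- function(x) {
    out <- lapply(reaction_list(x), function(r) {
      res <- tryCatch(classifier(r$reactants, r$product),
                      error = function(e) list(name = "Unrecognized",
                                               class = "Unrecognized"))
      res
    })
    names <- vapply(out, `[[`, character(1), "name")
    classes <- vapply(out, `[[`, character(1), "class")
    keep <- names != "Unrecognized"
    list(names = unique(names[keep]), classes = unique(classes[keep]))
  }
  a <- classify_all(route)
  b <- classify_all(reference)
  list(name_match = setequal(a$names, b$names),
       class_match = setequal(a$classes, b$classes),
       degenerate = length(a$names) == 0L && length(b$names) == 0L)
}

#' Evaluate predicted routes against a convergent reference set
#'
#' Computes, per library and per top-N cutoff, complete and partial
#' solvability, route and intermediate accuracy, and the best combined F1
#' (with its components), plus reaction name/class accuracy of the
#' highest-ranked route when a classifier is given. Aggregates are the
#' fraction of libraries satisfying each boolean metric and distribution
#' summaries for F1. A missing prediction counts as unsolved.
#'
#' @param predictions Named list (by library id) of ranked `route_summary`
#'   lists.
#' @param references Named list (by library id) of role-assigned
#'   `synthesis_graph` references.
#' @param Ns Integer vector of top-N cutoffs.
#' @param classifier Optional reaction classifier, see
#'   [reaction_type_accuracy()].
#' @return List of class `evaluation_report` with `per_library` (tibble),
#'   `aggregate` (tibble keyed by metric and N) and `per_compound`
#'   (individual target solvability at the largest N).
#' @export
evaluate_testset <- function(predictions, references, Ns = c(1L, 5L, 10L, 100L),
                             classifier = NULL) {
  Ns <- sort(unique(as.integer(Ns)))
  rows <- list()
  compound_rows <- list()
  for (lib in names(references)) {
    ref <- references[[lib]]
    targets <- graph_targets(ref)
    routes <- predictions[[lib]]
    if (is.null(routes)) routes <- list()
    for (N in Ns) {
      top <- utils::head(routes, N)
      f1s <- lapply(top, f1_score, reference = ref)
      best_f1 <- if (length(f1s)) {
        f1s[[which.max(vapply(f1s, `[[`, numeric(1), "combined"))]]
      } else list(reaction_f1 = 0, molecule_f1 = 0, combined = 0)
      type_acc <- if (!is.null(classifier) && length(top)) {
        reaction_type_accuracy(top[[1]], ref, classifier)
      } else list(name_match = NA, class_match = NA)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        library = lib, N = N,
        complete_solved = complete_solvability(routes, targets, N),
        partial_solved = partial_solvability(routes, targets, N),
        route_accuracy = any(vapply(top, route_accuracy, logical(1),
                                    reference = ref)),
        intermediate_accuracy = any(vapply(top, intermediate_accuracy,
                                           logical(1), reference = ref)),
        f1_best = best_f1$combined,
        reaction_f1 = best_f1$reaction_f1,
        molecule_f1 = best_f1$molecule_f1,
        reaction_name_accuracy = type_acc$name_match,
        reaction_class_accuracy = type_acc$class_match)
    }
    n_max <- max(Ns)
    covered <- unique(unlist(lapply(utils::head(routes, n_max), `[[`, "targets")))
    compound_rows[[length(compound_rows) + 1L]] <- tibble::tibble(
      library = lib, target = targets,
      solved = targets %in% covered)
  }
  per_library <- do.call(rbind, rows)
  bool_cols <- c("complete_solved", "partial_solved", "route_accuracy",
                 "intermediate_accuracy", "reaction_name_accuracy",
                 "reaction_class_accuracy")
  agg_rows <- lapply(Ns, function(N) {
    sub <- per_library[per_library$N == N, , drop = FALSE]
    tibble::tibble(
      N = N,
      metric = c(bool_cols, "f1_median", "f1_over_0.5", "f1_over_0.75"),
      value = unname(c(vapply(bool_cols, function(col)
                         mean(sub[[col]], na.rm = TRUE), numeric(1)),
                       stats::median(sub$f1_best),
                       mean(sub$f1_best > 0.5),
                       mean(sub$f1_best > 0.75))))
  })
  structure(list(per_library = per_library,
                 aggregate = do.call(rbind, agg_rows),
                 per_compound = do.call(rbind, compound_rows),
                 Ns = Ns),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report: ", length(unique(x$per_library$library)),
      " libraries, N = ", paste(x$Ns, collapse = ","), ">\n", sep = "")
  agg <- x$aggregate[x$aggregate$metric %in%
                       c("complete_solved", "partial_solved",
                         "route_accuracy", "f1_median"), , drop = FALSE]
  print(as.data.frame(agg), row.names = FALSE)
  invisible(x)
}

#' Write a per-library evaluation report to TSV and the aggregate to JSON
#'
#' @param report An `evaluation_report`.
#' @param tsv_path Path for the per-library TSV.
#' @param json_path Path for the aggregate JSON.
#' @return `tsv_path`, invisibly.
#' @export
write_evaluation_report <- function(report, tsv_path, json_path) {
  utils::write.table(as.data.frame(report$per_library), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  agg <- report$aggregate
  payload <- split(stats::setNames(agg$value, agg$metric), agg$N)
  jsonlite::write_json(lapply(payload, as.list), json_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(tsv_path)
}
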