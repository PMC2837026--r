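#' Search ontologies for a term
#'
#' Substring search over preferred names and synonyms (after
#' normalization), the batch equivalent of an ontology browser's search
#' box.  Hits whose name or synonym equals the query exactly come first,
#' then hits sorted by name.
#'
#' @param query search string; must be non-empty after normalization.
#' @param ontologies an [ontology()] or list of them.
#' @param policy normalization applied to both query and labels.
#' @return data frame with columns `ncbo_id`, `term_id`, `name`,
#'   `matched_on` (`"name"`/`"synonym"`) and a list-column `path` holding
#'   each hit's [path_to_root()].
#' @examples
#' ont <- parse_obo(text = c("[Term]", "id: CL:0000031", "name: neuroblast"))
#' search_terms("neuro", ont)
#' @export
search_terms <- function(query, ontologies, policy = norm_policy()) {
  if (inherits(ontologies, "ontology")) ontologies <- list(ontologies)
  q <- normalize_surface(query, policy)
  if (!length(q) || !nzchar(q))
    stop("query is empty after normalization", call. = FALSE)
  rows <- list()
  for (ont in ontologies) {
    for (tm in ont$terms) {
      if (tm$obsolete) next
      labels <- c(tm$name, unname(tm$synonyms))
      kinds <- c("name", rep("synonym", length(tm$synonyms)))
      norm <- normalize_surface(labels, policy)
      hit <- which(grepl(q, norm, fixed = TRUE))[1]
      if (is.na(hit)) next
      rows[[length(rows) + 1L]] <- list(
        ncbo_id = ont$ncbo_id, term_id = tm$term_id, name = tm$name,
        matched_on = kinds[hit], exact = any(norm == q),
        path = path_to_root(tm$term_id, ont))
    }
  }
  if (!length(rows)) {
    out <- data.frame(ncbo_id = character(), term_id = character(),
                      name = character(), matched_on = character(),
                      stringsAsFactors = FALSE)
    out$path <- list()
    return(out)
  }
  out <- data.frame(
    ncbo_id = vapply(rows, `[[`, character(1), "ncbo_id"),
    term_id = vapply(rows, `[[`, character(1), "term_id"),
    name = vapply(rows, `[[`, character(1), "name"),
    matched_on = vapply(rows, `[[`, character(1), "matched_on"),
    stringsAsFactors = FALSE)
  out$path <- lapply(rows, `[[`, "path")
  exact <- vapply(rows, `[[`, logical(1), "exact")
  ord <- order(!exact, out$name)
  out[ord, , drop = FALSE]
}

#' Path from a term to its root
#'
#' Follows `is_a` links upward, one parent per level, until a parentless
#' term is reached.  Hierarchy display is single-parent: for a term with
#' multiple parents the lexicographically smallest resolvable parent
#' `term_id` is followed (a documented display rule, not ontology
#' semantics).
#'
#' @param term_id starting term.
#' @param ont an [ontology()]; its `is_a` graph must be acyclic (see
#'   [validate_ontology()]).
#' @return character vector of `term_id`s from the term to the root.
#' @export
path_to_root <- function(term_id, ont) {
  stopifnot(inherits(ont, "ontology"))
  if (is.null(ont$terms[[term_id]]))
    stop("unknown term_id: ", term_id, call. = FALSE)
  path <- term_id
  seen <- term_id
  current <- term_id
  repeat {
    parents <- ont$terms[[current]]$parents
    parents <- parents[parents %in% names(ont$terms)]
    if (!length(parents)) break
    nxt <- sort(parents)[1]
    if (nxt %in% seen)
      stop("is_a cycle encountered at ", nxt,
           "; run validate_ontology() on this ontology", call. = FALSE)
    path <- c(path, nxt)
    seen <- c(seen, nxt)
    current <- nxt
  }
  path
}

#' Children of a term
#'
#' All terms that list `term_id` among their `is_a` parents, sorted by
#' `term_id`.
#'
#' @param term_id parent term.
#' @param ont an [ontology()].
#' @return character vector of child `term_id`s (empty for a leaf).
#' @export
children <- function(term_id, ont) {
  stopifnot(inherits(ont, "ontology"))
  if (is.null(ont$terms[[term_id]]))
    stop("unknown term_id: ", term_id, call. = FALSE)
  kids <- vapply(ont$terms,
                 function(tm) term_id %in% tm$parents, logical(1))
  sort(names(ont$terms)[kids])
}

#' Print an indented hierarchy under a term
#'
#' @param term_id subtree root.
#' @param ont an [ontology()].
#' @param max_depth maximum depth to descend.
#' @return invisibly, the lines printed.
#' @export
print_tree <- function(term_id, ont, max_depth = 10L) {
  lines <- character()
  walk <- function(id, depth) {
    tm <- ont$terms[[id]]
    lines <<- c(lines, paste0(strrep("  ", depth), id, " ", tm$name))
    if (depth >= max_depth) return()
    for (k in children(id, ont)) walk(k, depth + 1L)
  }
  walk(term_id, 0L)
  cat(lines, sep = "\n")
  cat("\n")
  invisible(lines)
}
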