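#' Construct an ontology term
#'
#' One concept of a controlled vocabulary: a CURIE identifier of the form
#' `prefix:local`, a preferred name, zero or more synonyms (each with an
#' optional scope label, EXACT/BROAD/NARROW/RELATED), and `is_a` parents.
#'
#' @param term_id CURIE string containing exactly one `:` with non-empty
#'   prefix and local parts, e.g. `"CL:0000031"`.
#' @param name preferred label; must be non-empty unless `obsolete`.
#' @param synonyms character vector of synonym strings; the `names()`
#'   attribute, when present, carries scope labels.  Duplicates (after
#'   trimming) are dropped.
#' @param parents character vector of parent `term_id`s (`is_a` targets).
#' @param obsolete logical flag.
#' @param definition optional definition string.
#' @return An object of class `"ontology_term"`.
#' @examples
#' ontology_term("CL:0000031", "neuroblast",
#'               synonyms = c(EXACT = "neural progenitor"))
#' @export
ontology_term <- function(term_id, name = "", synonyms = character(),
                          parents = character(), obsolete = FALSE,
                          definition = NA_character_) {
  term_id <- as.character(term_id)
  if (length(term_id) != 1L || !nzchar(term_id) ||
      !grepl("^[^:]+:[^:]+$", term_id)) {
    stop("term_id must be a CURIE 'prefix:local' with exactly one ':', got ",
         deparse(term_id), call. = FALSE)
  }
  # an empty name on a non-obsolete term is tolerated here so that parsing
  # never fails on it; validate_ontology() reports it and marks the
  # ontology unusable
  name <- as.character(name)
  if (length(name) != 1L) name <- if (length(name)) name[[1]] else ""
  syn_names <- names(synonyms)
  synonyms <- as.character(synonyms)
  names(synonyms) <- syn_names
  if (anyDuplicated(trimws(synonyms))) {
    keep <- !duplicated(trimws(synonyms))
    synonyms <- synonyms[keep]
  }
  structure(
    list(term_id = term_id, name = name, synonyms = synonyms,
         parents = unique(as.character(parents)),
         obsolete = isTRUE(obsolete), definition = definition),
    class = "ontology_term"
  )
}

#' @export
print.ontology_term <- function(x, ...) {
  cat("<ontology_term> ", x$term_id, " \"", x$name, "\"", sep = "")
  if (x$obsolete) cat(" [obsolete]")
  cat("\n")
  if (length(x$synonyms))
    cat("  synonyms: ", paste(x$synonyms, collapse = "; "), "\n", sep = "")
  if (length(x$parents))
    cat("  is_a: ", paste(x$parents, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Construct an ontology
#'
#' A set of terms plus registry metadata.  The registry fields (`ncbo_id`,
#' `label`, `url_template`) are not part of the OBO format; they identify
#' the ontology in an external registry (e.g. NCBO BioPortal) and supply
#' the browse URL used in emitted mark-up.  They default to empty and are
#' normally filled from the run configuration.
#'
#' @param terms list of [ontology_term()] objects.
#' @param ncbo_id registry identifier string (may be empty).
#' @param label human-readable ontology name.
#' @param url_template browse-URL for terms of this ontology; a literal
#'   URL, optionally containing `{term_id}` which is substituted per term.
#'   Empty means "no URL".
#' @param source provenance string (file path) for messages.
#' @return An object of class `"ontology"`; `$terms` is a named list keyed
#'   by `term_id`.
#' @export
ontology <- function(terms = list(), ncbo_id = "", label = "",
                     url_template = "", source = "") {
  if (length(terms)) {
    ok <- vapply(terms, inherits, logical(1), "ontology_term")
    if (!all(ok)) stop("terms must all be ontology_term objects", call. = FALSE)
    ids <- vapply(terms, `[[`, character(1), "term_id")
    if (anyDuplicated(ids)) {
      stop("duplicate term_id: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           call. = FALSE)
    }
    names(terms) <- ids
  }
  structure(
    list(ncbo_id = as.character(ncbo_id), label = as.character(label),
         url_template = as.character(url_template), terms = terms,
         source = as.character(source)),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> ", if (nzchar(x$label)) x$label else "(unlabelled)",
      if (nzchar(x$ncbo_id)) paste0(" [ncbo_id=", x$ncbo_id, "]") else "",
      ": ", length(x$terms), " terms\n", sep = "")
  invisible(x)
}

#' @export
length.ontology <- function(x) length(x$terms)

# extract the first quoted string of an OBO tag value, honouring \" escapes;
# returns NA if the value does not start with a quote
obo_quoted <- function(value) {
  m <- regmatches(value, regexpr('^"(?:[^"\\\\]|\\\\.)*"', value, perl = TRUE))
  if (!length(m)) return(list(text = NA_character_, rest = value))
  inner <- substr(m, 2L, nchar(m) - 1L)
  inner <- gsub('\\\\(.)', "\\1", inner)
  list(text = inner, rest = trimws(substring(value, nchar(m) + 1L)))
}

#' Parse an OBO 1.2 document
#'
#' Reads the subset of the OBO flat-file format needed for term
#' recognition and hierarchy navigation: `[Term]` stanzas with the tags
#' `id`, `name`, `synonym`, `is_a`, `is_obsolete` and `def`.  All other
#' tags and stanza types (e.g. `[Typedef]`) are ignored without error.
#' Trailing `! comment` text on `is_a` values is stripped; synonym scope
#' labels (EXACT/BROAD/NARROW/RELATED) are kept as the `names()` of the
#' synonym vector.
#'
#' @param file path to an OBO file (UTF-8), or a connection.
#' @param text alternatively, the OBO document as a single string or a
#'   character vector of lines (overrides `file`).
#' @param ncbo_id,label,url_template registry metadata to attach, see
#'   [ontology()].
#' @return An [ontology()].
#' @section Errors: a `[Term]` stanza without an `id` tag, or a duplicated
#'   `term_id`, is a parse error naming the offending line; an unreadable
#'   `file` is an I/O error.
#' @examples
#' ont <- parse_obo(text = c("format-version: 1.2", "", "[Term]",
#'                           "id: CL:0000031", "name: neuroblast"))
#' ont$terms[["CL:0000031"]]$name
#' @export
parse_obo <- function(file = NULL, text = NULL, ncbo_id = "", label = "",
                      url_template = "") {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'file' or 'text'", call. = FALSE)
    lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
    src <- if (is.character(file)) file else "connection"
  } else {
    lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
      strsplit(text, "\n", fixed = TRUE)[[1]]
    } else as.character(text)
    src <- "text"
  }

  terms <- list()
  stanza <- NULL        # accumulating fields of the current [Term] stanza
  stanza_line <- 0L
  in_term <- FALSE

  flush_stanza <- function() {
    if (is.null(stanza)) return()
    if (is.null(stanza$id)) {
      stop("OBO parse error: [Term] stanza starting at line ", stanza_line,
           " has no id tag", call. = FALSE)
    }
    if (!is.null(terms[[stanza$id]])) {
      stop("OBO parse error: duplicate term_id '", stanza$id,
           "' at line ", stanza_line, call. = FALSE)
    }
    terms[[stanza$id]] <<- ontology_term(
      term_id = stanza$id,
      name = stanza$name %||% "",
      synonyms = stanza$synonyms %||% character(),
      parents = stanza$parents %||% character(),
      obsolete = isTRUE(stanza$obsolete),
      definition = stanza$def %||% NA_character_
    )
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    trimmed <- trimws(line)
    if (grepl("^\\[.+\\]$", trimmed)) {
      if (in_term) flush_stanza()
      stanza <- NULL
      in_term <- identical(trimmed, "[Term]")
      if (in_term) { stanza <- list(); stanza_line <- i }
      next
    }
    if (!in_term || !nzchar(trimmed)) next
    colon <- regexpr(":", trimmed, fixed = TRUE)
    if (colon < 0L) next                       # not tag:value; ignore
    tag <- substr(trimmed, 1L, colon - 1L)
    value <- trimws(substring(trimmed, colon + 1L))
    switch(tag,
      id = { stanza$id <- value },
      name = { stanza$name <- value },
      is_obsolete = { stanza$obsolete <- identical(tolower(value), "true") },
      is_a = {
        target <- trimws(sub("!.*$", "", value))
        if (nzchar(target))
          stanza$parents <- c(stanza$parents, target)
      },
      synonym = {
        q <- obo_quoted(value)
        if (!is.na(q$text)) {
          scope <- regmatches(
            q$rest, regexpr("^(EXACT|BROAD|NARROW|RELATED)\\b", q$rest))
          syn <- q$text
          names(syn) <- if (length(scope)) scope else ""
          stanza$synonyms <- c(stanza$synonyms, syn)
        }
      },
      def = {
        q <- obo_quoted(value)
        if (!is.na(q$text)) stanza$def <- q$text
      },
      NULL                                     # unsupported tag: ignore
    )
  }
  if (in_term) flush_stanza()

  ontology(terms, ncbo_id = ncbo_id, label = label,
           url_template = url_template, source = src)
}

#' Serialize an ontology to OBO text
#'
#' Writes the supported tag subset (`format-version`, `[Term]`, `id`,
#' `name`, `synonym`, `is_a`, `is_obsolete`, `def`) so that
#' `parse_obo(text = write_obo(ont))` reproduces `ont` field for field.
#'
#' @param ont an [ontology()].
#' @param file optional path; when given the text is also written there.
#' @return The OBO document as a single string (invisibly when `file` is
#'   given).
#' @export
write_obo <- function(ont, file = NULL) {
  stopifnot(inherits(ont, "ontology"))
  esc <- function(x) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))
  out <- c("format-version: 1.2", "")
  for (tm in ont$terms) {
    out <- c(out, "[Term]", paste0("id: ", tm$term_id))
    if (nzchar(tm$name)) out <- c(out, paste0("name: ", tm$name))
    if (!is.na(tm$definition))
      out <- c(out, paste0('def: "', esc(tm$definition), '" []'))
    if (length(tm$synonyms)) {
      scopes <- names(tm$synonyms) %||% rep("", length(tm$synonyms))
      out <- c(out, paste0(
        'synonym: "', esc(unname(tm$synonyms)), '"',
        ifelse(nzchar(scopes), paste0(" ", scopes), ""), " []"))
    }
    if (length(tm$parents)) out <- c(out, paste0("is_a: ", tm$parents))
    if (tm$obsolete) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Validate an ontology for use in recognition and navigation
#'
#' Reports dangling `is_a` targets, cycles in the `is_a` graph, obsolete
#' terms, and non-obsolete terms with empty names.  An ontology is usable
#' for recognition and hierarchy display iff it has no cycles and no
#' empty-name non-obsolete terms (dangling parents and obsolete terms are
#' tolerated and merely reported).
#'
#' @param ont an [ontology()].
#' @return A data frame of class `"obo_validation"` with columns `issue`
#'   (`"dangling"`, `"cycle"`, `"obsolete"`, `"empty_name"`), `term_id`
#'   and `detail`, plus attribute `usable` (logical).
#' @examples
#' ont <- parse_obo(text = c("[Term]", "id: A:1", "name: a", "is_a: B:9"))
#' validate_ontology(ont)
#' @export
validate_ontology <- function(ont) {
  stopifnot(inherits(ont, "ontology"))
  issue <- character(); tid <- character(); detail <- character()
  add <- function(i, t, d) {
    issue <<- c(issue, i); tid <<- c(tid, t); detail <<- c(detail, d)
  }
  ids <- names(ont$terms) %||% character()

  for (tm in ont$terms) {
    if (tm$obsolete) add("obsolete", tm$term_id, "term is obsolete")
    if (!tm$obsolete && !nzchar(tm$name))
      add("empty_name", tm$term_id, "non-obsolete term with empty name")
    for (p in tm$parents) {
      if (!(p %in% ids))
        add("dangling", tm$term_id, paste0("is_a target ", p, " not in ontology"))
    }
  }

  # cycle detection: iterative colouring DFS over the is_a graph
  colour <- setNames(rep(0L, length(ids)), ids)  # 0 white, 1 grey, 2 black
  cyclic <- character()
  for (root in ids) {
    if (colour[[root]] != 0L) next
    stack <- list(list(id = root, next_parent = 1L))
    colour[[root]] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      parents <- ont$terms[[top$id]]$parents
      parents <- parents[parents %in% ids]
      if (top$next_parent > length(parents)) {
        colour[[top$id]] <- 2L
        stack[[length(stack)]] <- NULL
        next
      }
      stack[[length(stack)]]$next_parent <- top$next_parent + 1L
      p <- parents[[top$next_parent]]
      if (colour[[p]] == 1L) {
        cyclic <- c(cyclic, p)
      } else if (colour[[p]] == 0L) {
        colour[[p]] <- 1L
        stack[[length(stack) + 1L]] <- list(id = p, next_parent = 1L)
      }
    }
  }
  for (p in unique(cyclic))
    add("cycle", p, "term participates in an is_a cycle")

  rep <- data.frame(issue = issue, term_id = tid, detail = detail,
                    stringsAsFactors = FALSE)
  attr(rep, "usable") <-
    !any(rep$issue %in% c("cycle", "empty_name"))
  class(rep) <- c("obo_validation", "data.frame")
  rep
}

#' @export
print.obo_validation <- function(x, ...) {
  cat("<obo_validation> ", nrow(x), " issue(s); usable=",
      attr(x, "usable"), "\n", sep = "")
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Is a validated ontology usable?
#'
#' @param report an `"obo_validation"` report from [validate_ontology()].
#' @return `TRUE` iff the report shows no cycles and no empty-name
#'   non-obsolete terms.
#' @export
is_usable <- function(report) isTRUE(attr(report, "usable"))
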