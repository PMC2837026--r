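#' Inline mark-up tags
#'
#' The mark-up dialect uses two NLM/JATS inline elements.  Ontology terms
#' are carried by `named-content` with `content-type="biolit"` and a
#' structured `id` attribute of the form
#' `ncbo_id=X;term_id=Y:Z;term=Q;url=http://H` (the `url` field is
#' optional).  Database identifiers are carried by `ext-link` with
#' `xlink:href` and `ext-link-type` attributes.  Any other element found
#' in a document is a foreign tag: it is kept opaque and preserved.
#'
#' @param ncbo_id registry id of the ontology (string, may be empty).
#' @param term_id CURIE of the term.
#' @param term preferred name of the term.
#' @param url optional browse URL; stored without the `http://` prefix
#'   when the configured value carries no scheme (emission prepends
#'   `http://`), or verbatim when it already has a scheme.
#' @param surface text enclosed by the element; defaults to `term`.
#'   Manual mark-up keeps the manuscript wording here even when it
#'   differs from `term`.
#' @return An object of class `"term_tag"`.
#' @examples
#' emit_term_tag(term_tag("38436", "CL:0000031", "neuroblast",
#'               url = "bioportal.bioontology.org/visualize/39004"))
#' @export
term_tag <- function(ncbo_id, term_id, term, url = NULL, surface = term) {
  if (!is.null(url) && (is.na(url) || !nzchar(url))) url <- NULL
  structure(list(ncbo_id = as.character(ncbo_id),
                 term_id = as.character(term_id),
                 term = as.character(term),
                 url = if (is.null(url)) NULL else as.character(url),
                 surface = as.character(surface)),
            class = "term_tag")
}

#' @rdname term_tag
#' @param href full link URL for the identifier.
#' @param ext_link_type database label (e.g. `"pdb"`).
#' @param id_text the identifier as it appears in the text.
#' @return `extlink_tag()`: an object of class `"extlink_tag"`.
#' @export
extlink_tag <- function(href, ext_link_type, id_text) {
  structure(list(href = as.character(href),
                 ext_link_type = as.character(ext_link_type),
                 id_text = as.character(id_text)),
            class = "extlink_tag")
}

#' @rdname term_tag
#' @param raw the element's serialized bytes, kept verbatim.
#' @param text the element's inner text (all descendants).
#' @return `foreign_tag()`: an object of class `"foreign_tag"`.
#' @export
foreign_tag <- function(raw, text) {
  structure(list(raw = as.character(raw), text = as.character(text)),
            class = "foreign_tag")
}

# full URL as emitted in the id attribute: prepend http:// unless the
# stored value already carries a scheme
full_url <- function(url) {
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", url)) url else paste0("http://", url)
}

#' Serialize a term tag
#'
#' Produces the canonical element, e.g.
#' `<named-content content-type="biolit"
#' id="ncbo_id=38436;term_id=CL:0000031;term=neuroblast;url=http://bioportal.bioontology.org/visualize/39004">neuroblast</named-content>`.
#' The `id` fields are emitted in the fixed order ncbo_id, term_id, term,
#' url; `url` is omitted when absent.  XML special characters in the term
#' and surface are escaped.
#'
#' @param tag a [term_tag()].
#' @return The serialized element as a single string.
#' @export
emit_term_tag <- function(tag) {
  stopifnot(inherits(tag, "term_tag"))
  if (!nzchar(tag$term_id) || !nzchar(tag$term))
    stop("term_id and term must be non-empty", call. = FALSE)
  id <- paste0("ncbo_id=", tag$ncbo_id, ";term_id=", tag$term_id,
               ";term=", tag$term,
               if (!is.null(tag$url)) paste0(";url=", full_url(tag$url)) else "")
  paste0('<named-content content-type="biolit" id="',
         xml_escape(id, attribute = TRUE), '">',
         xml_escape(tag$surface), "</named-content>")
}

#' Serialize a database identifier tag
#'
#' Produces the canonical element, e.g. for PDB 1MU2:
#' `<ext-link xlink:href="http://www.rcsb.org/pdb/explore/explore.do?structureId=1MU2"
#' ext-link-type="pdb">1MU2</ext-link>`.
#'
#' @param tag an [extlink_tag()].
#' @return The serialized element as a single string.
#' @export
emit_dbid_tag <- function(tag) {
  stopifnot(inherits(tag, "extlink_tag"))
  if (!nzchar(tag$href)) stop("href must be non-empty", call. = FALSE)
  if (!nzchar(tag$id_text)) stop("id_text must be non-empty", call. = FALSE)
  paste0('<ext-link xlink:href="', xml_escape(tag$href, attribute = TRUE),
         '" ext-link-type="', xml_escape(tag$ext_link_type, attribute = TRUE),
         '">', xml_escape(tag$id_text), "</ext-link>")
}

#' A document with inline mark-up spans
#'
#' Holds the plain text of a document together with an ordered,
#' pairwise-disjoint set of marked spans (term tags, ext-link tags, and
#' opaque foreign tags).  Offsets are 0-based half-open into `text`;
#' stripping all tags from the serialization recovers `text` exactly.
#'
#' @param text document text.
#' @param spans list of `list(start, end, tag)` records where `tag` is a
#'   [term_tag()], [extlink_tag()] or [foreign_tag()].
#' @return An object of class `"marked_document"`.
#' @export
marked_document <- function(text, spans = list()) {
  stopifnot(length(text) == 1L)
  n <- nchar(text)
  if (length(spans)) {
    s <- vapply(spans, function(x) as.integer(x$start), integer(1))
    e <- vapply(spans, function(x) as.integer(x$end), integer(1))
    if (any(s < 0L | e <= s | e > n))
      stop("span outside document or empty", call. = FALSE)
    ord <- order(s)
    spans <- spans[ord]; s <- s[ord]; e <- e[ord]
    if (length(s) > 1L && any(s[-1] < e[-length(e)]))
      stop("overlapping spans are not allowed", call. = FALSE)
  }
  structure(list(text = text, spans = spans), class = "marked_document")
}

#' @export
print.marked_document <- function(x, ...) {
  kinds <- vapply(x$spans, function(sp) class(sp$tag)[1], character(1))
  cat("<marked_document> ", nchar(x$text), " chars, ", length(x$spans),
      " span(s)", if (length(kinds)) paste0(" (",
      paste(sprintf("%s=%d", names(table(kinds)), table(kinds)),
            collapse = ", "), ")"), "\n", sep = "")
  invisible(x)
}

#' Serialize a marked document to an XML fragment
#'
#' Plain-text segments are XML-escaped; term and ext-link spans are
#' emitted canonically (with the span's document substring as surface
#' text); foreign spans are written back verbatim.  The result is a
#' fragment without a root element, so emitted elements appear exactly in
#' their canonical form; [parse_markup()] supplies the `xlink` namespace
#' when reading.
#'
#' @param doc a [marked_document()].
#' @return Single string.
#' @export
serialize_markup <- function(doc) {
  stopifnot(inherits(doc, "marked_document"))
  out <- character(); pos <- 0L
  for (sp in doc$spans) {
    if (sp$start > pos)
      out <- c(out, xml_escape(span_text(doc$text, pos, sp$start)))
    surf <- span_text(doc$text, sp$start, sp$end)
    piece <- switch(class(sp$tag)[1],
      term_tag = {
        t <- sp$tag; t$surface <- surf; emit_term_tag(t)
      },
      extlink_tag = {
        t <- sp$tag; t$id_text <- surf; emit_dbid_tag(t)
      },
      foreign_tag = sp$tag$raw,
      stop("unknown tag class: ", class(sp$tag)[1], call. = FALSE))
    out <- c(out, piece)
    pos <- sp$end
  }
  if (pos < nchar(doc$text))
    out <- c(out, xml_escape(span_text(doc$text, pos, nchar(doc$text))))
  paste(out, collapse = "")
}

# parse the biolit id attribute grammar; accepts the canonical field order
# and permutations of ncbo_id/term_id/term, with url (when present)
# consuming the remainder of the string so URLs containing ';' or '='
# survive.  Returns NULL on malformed input.
parse_biolit_id <- function(id) {
  fields <- list()
  rest <- id
  url_at <- regexpr("(?:^|;)url=", rest)
  if (url_at > 0L) {
    url_len <- attr(url_at, "match.length")
    fields$url <- substring(rest, url_at + url_len)
    rest <- substr(rest, 1L, url_at - 1L)
  }
  if (nzchar(rest)) {
    for (part in strsplit(rest, ";", fixed = TRUE)[[1]]) {
      eq <- regexpr("=", part, fixed = TRUE)
      if (eq < 0L) return(NULL)
      key <- substr(part, 1L, eq - 1L)
      if (!key %in% c("ncbo_id", "term_id", "term")) return(NULL)
      if (!is.null(fields[[key]])) return(NULL)
      fields[[key]] <- substring(part, eq + 1L)
    }
  }
  if (is.null(fields$term_id) || is.null(fields$term) ||
      !nzchar(fields$term_id) || !nzchar(fields$term)) return(NULL)
  fields$ncbo_id <- fields$ncbo_id %||% ""
  fields
}

#' Parse a document carrying inline mark-up
#'
#' Recovers the plain text and the mark-up spans from a serialized
#' fragment.  `named-content` elements with `content-type="biolit"` and a
#' well-formed `id` grammar become term tags; `ext-link` elements with an
#' `xlink:href` become ext-link tags; every other element — including a
#' biolit element whose `id` string does not parse, which is demoted with
#' a warning — is kept as an opaque foreign tag.  Input without any `<`
#' is treated as plain text with zero spans.
#'
#' Elements are read at the top level of the fragment only; mark-up
#' nested inside a foreign element stays part of that opaque span.
#'
#' @param x the serialized document (single string).
#' @return A [marked_document()].
#' @section Errors: ill-formed XML raises the underlying parser error,
#'   which carries the position of the problem.
#' @export
parse_markup <- function(x) {
  stopifnot(length(x) == 1L)
  if (!grepl("<", x, fixed = TRUE)) {
    return(marked_document(text = x, spans = list()))
  }
  wrapped <- paste0(
    '<biolit-doc xmlns:xlink="http://www.w3.org/1999/xlink">', x,
    "</biolit-doc>")
  root <- xml2::xml_root(xml2::read_xml(wrapped))
  text <- ""
  spans <- list()
  for (node in xml2::xml_contents(root)) {
    if (xml2::xml_type(node) == "text") {
      text <- paste0(text, xml2::xml_text(node))
      next
    }
    if (xml2::xml_type(node) != "element") next   # comments/PIs dropped
    inner <- xml2::xml_text(node)
    start <- nchar(text)
    tag <- node_to_tag(node, inner)
    text <- paste0(text, inner)
    if (nchar(inner) == 0L) next                  # empty element: no span
    spans <- c(spans, list(list(start = start, end = nchar(text), tag = tag)))
  }
  marked_document(text = text, spans = spans)
}

node_to_tag <- function(node, inner) {
  name <- xml2::xml_name(node)
  if (name == "named-content" &&
      identical(xml2::xml_attr(node, "content-type"), "biolit")) {
    fields <- parse_biolit_id(xml2::xml_attr(node, "id") %||% "")
    if (is.null(fields)) {
      warning("malformed biolit id attribute; element kept as foreign tag: ",
              substr(as.character(node), 1, 80), call. = FALSE)
      return(foreign_tag(raw = as.character(node), text = inner))
    }
    url <- fields$url
    if (!is.null(url)) url <- sub("^http://", "", url)
    return(term_tag(ncbo_id = fields$ncbo_id, term_id = fields$term_id,
                    term = fields$term, url = url, surface = inner))
  }
  if (name == "ext-link") {
    href <- xml2::xml_attr(node, "href")   # namespace-stripped attr name
    if (is.na(href)) href <- xml2::xml_attr(node, "xlink:href")
    type <- xml2::xml_attr(node, "ext-link-type")
    if (!is.na(href) && nzchar(href)) {
      return(extlink_tag(href = href, ext_link_type = type %||% "",
                         id_text = inner))
    }
    warning("ext-link without xlink:href kept as foreign tag", call. = FALSE)
  }
  foreign_tag(raw = as.character(node), text = inner)
}

#' Strip all mark-up from a serialized document
#'
#' @param x serialized document string.
#' @return The plain text (tag-stripped, entities unescaped).
#' @export
strip_markup <- function(x) parse_markup(x)$text

#' Inject resolved annotations into a document
#'
#' Builds a [marked_document()] from plain text plus resolved term
#' annotations and resolved database-identifier matches, on top of the
#' spans already present in `existing` (typically foreign tags and
#' mark-up from an earlier pass).  Overlapping tags are not allowed: a
#' new span that overlaps any existing span is rejected and reported via
#' the `"rejected"` attribute (with a warning); new spans that overlap
#' each other are an error.
#'
#' @param text document text.
#' @param resolved_terms list of resolved [term_annotation()] objects.
#' @param resolved_ids list of resolved [db_id_match()] objects.
#' @param existing a [marked_document()] over the same text, or `NULL`.
#' @return A [marked_document()]; attribute `"rejected"` is a data frame
#'   of skipped spans (columns `start`, `end`, `reason`).
#' @export
inject_markup <- function(text, resolved_terms = list(), resolved_ids = list(),
                          existing = NULL) {
  stopifnot(length(text) == 1L)
  if (!is.null(existing)) {
    stopifnot(inherits(existing, "marked_document"))
    if (!identical(existing$text, text))
      stop("existing mark-up was built over different text", call. = FALSE)
  }
  new_spans <- list()
  for (a in resolved_terms) {
    stopifnot(inherits(a, "term_annotation"))
    if (is.na(a$resolved))
      stop("unresolved term annotation at [", a$start, ",", a$end,
           "); resolve before injection", call. = FALSE)
    ch <- a$candidates[a$resolved, ]
    url <- ch$url
    if (is.na(url) || !nzchar(url)) url <- NULL
    new_spans <- c(new_spans, list(list(
      start = a$start, end = a$end,
      tag = term_tag(ncbo_id = ch$ncbo_id, term_id = ch$term_id,
                     name_or_term(ch), url = url, surface = a$surface))))
  }
  for (m in resolved_ids) {
    stopifnot(inherits(m, "db_id_match"))
    if (is.na(m$resolved))
      stop("unresolved id match \"", m$id_text, "\"; resolve before injection",
           call. = FALSE)
    new_spans <- c(new_spans, list(list(
      start = m$start, end = m$end,
      tag = extlink_tag(href = m$href, ext_link_type = m$resolved,
                        id_text = m$id_text))))
  }
  ns <- vapply(new_spans, function(x) x$start, integer(1))
  ne <- vapply(new_spans, function(x) x$end, integer(1))
  if (length(ns) > 1L) {
    ord <- order(ns, ne)
    ns <- ns[ord]; ne <- ne[ord]; new_spans <- new_spans[ord]
    clash <- which(ns[-1] < ne[-length(ne)])
    if (length(clash))
      stop("overlapping new spans: [", ns[clash[1]], ",", ne[clash[1]],
           ") and [", ns[clash[1] + 1L], ",", ne[clash[1] + 1L], ")",
           call. = FALSE)
  }
  ex_spans <- if (is.null(existing)) list() else existing$spans
  ex_s <- vapply(ex_spans, function(x) as.integer(x$start), integer(1))
  ex_e <- vapply(ex_spans, function(x) as.integer(x$end), integer(1))
  rej <- data.frame(start = integer(), end = integer(), reason = character(),
                    stringsAsFactors = FALSE)
  keep <- logical(length(new_spans))
  for (i in seq_along(new_spans)) {
    if (any(spans_overlap(ns[i], ne[i], ex_s, ex_e))) {
      rej <- rbind(rej, data.frame(start = ns[i], end = ne[i],
                                   reason = "overlaps existing span",
                                   stringsAsFactors = FALSE))
    } else keep[i] <- TRUE
  }
  if (nrow(rej))
    warning(nrow(rej), " span(s) rejected: overlapping tags are not allowed",
            call. = FALSE)
  doc <- marked_document(text, c(ex_spans, new_spans[keep]))
  attr(doc, "rejected") <- rej
  doc
}

name_or_term <- function(cand) {
  if (!is.null(cand$name) && nzchar(cand$name)) cand$name else cand$term_id
}

#' Export a marked document's spans as standoff records
#'
#' One row per span: term tags report `ncbo_id`/`term_id`, ext-link spans
#' report the database label as `db:<label>` in `ncbo_id` and the
#' identifier in `term_id`, foreign spans report `foreign`.
#'
#' @param doc a [marked_document()].
#' @param doc_id value for the `doc_id` column.
#' @param file optional path to write a TSV.
#' @return data frame with columns `doc_id`, `start`, `end`, `surface`,
#'   `ncbo_id`, `term_id`.
#' @export
markup_standoff <- function(doc, doc_id = "doc", file = NULL) {
  stopifnot(inherits(doc, "marked_document"))
  rows <- lapply(doc$spans, function(sp) {
    surf <- span_text(doc$text, sp$start, sp$end)
    ids <- switch(class(sp$tag)[1],
      term_tag = c(sp$tag$ncbo_id, sp$tag$term_id),
      extlink_tag = c(paste0("db:", sp$tag$ext_link_type), sp$tag$id_text),
      foreign_tag = c("foreign", ""))
    data.frame(doc_id = doc_id, start = sp$start, end = sp$end,
               surface = surf, ncbo_id = ids[1], term_id = ids[2],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(doc_id = character(), start = integer(), end = integer(),
               surface = character(), ncbo_id = character(),
               term_id = character(), stringsAsFactors = FALSE)
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
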