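#' Build a term-recognition index from ontologies
#'
#' Collects every distinct normalized preferred name and synonym of every
#' non-obsolete term in the supplied ontologies into a dictionary mapping
#' normalized surface form to candidate terms.  A form shared by several
#' terms (within or across ontologies) maps to all of them, so ambiguous
#' spans carry every candidate.
#'
#' @param ontologies an [ontology()] or list of them; each should pass
#'   [validate_ontology()].
#' @param policy the [norm_policy()] used for the whole run.
#' @param include_obsolete index labels of obsolete terms too?  Default
#'   `FALSE`: obsolete labels would produce misleading mark-up.
#' @return An object of class `"term_index"`: `$entries` is a named list
#'   (normalized form -> data frame of candidates with columns `ncbo_id`,
#'   `term_id`, `name`, `kind` (`"name"`/`"synonym"`), `url`), `$policy`
#'   records the normalization applied.
#' @examples
#' ont <- parse_obo(text = c("[Term]", "id: CL:0000031", "name: neuroblast"),
#'                  ncbo_id = "38436")
#' idx <- build_index(ont)
#' names(idx$entries)
#' @export
build_index <- function(ontologies, policy = norm_policy(),
                        include_obsolete = FALSE) {
  if (inherits(ontologies, "ontology")) ontologies <- list(ontologies)
  stopifnot(all(vapply(ontologies, inherits, logical(1), "ontology")))
  entries <- new.env(parent = emptyenv())
  order_counter <- 0L
  add <- function(form_raw, ncbo_id, term_id, name, kind, url) {
    form <- normalize_surface(form_raw, policy)
    if (!nzchar(form)) {
      warning("label of term ", term_id, " normalizes to the empty string; ",
              "skipped", call. = FALSE)
      return()
    }
    cand <- data.frame(ncbo_id = ncbo_id, term_id = term_id, name = name,
                       kind = kind, url = url, stringsAsFactors = FALSE)
    prev <- entries[[form]]
    if (is.null(prev)) {
      entries[[form]] <- cand
    } else if (!any(prev$ncbo_id == ncbo_id & prev$term_id == term_id)) {
      entries[[form]] <- rbind(prev, cand)
    }
  }
  for (ont in ontologies) {
    for (tm in ont$terms) {
      if (tm$obsolete && !include_obsolete) next
      url <- term_url(ont, tm$term_id)
      if (nzchar(tm$name))
        add(tm$name, ont$ncbo_id, tm$term_id, tm$name, "name", url)
      for (syn in tm$synonyms)
        add(syn, ont$ncbo_id, tm$term_id, tm$name, "synonym", url)
    }
  }
  forms <- sort(ls(entries))
  structure(list(entries = mget(forms, envir = entries), policy = policy),
            class = "term_index")
}

# browse URL for a term: substitute {term_id} when the template has the
# slot, otherwise use the template verbatim; empty template -> NA
term_url <- function(ont, term_id) {
  tpl <- ont$url_template
  if (!length(tpl) || is.na(tpl) || !nzchar(tpl)) return(NA_character_)
  if (grepl("{term_id}", tpl, fixed = TRUE))
    return(gsub("{term_id}", term_id, tpl, fixed = TRUE))
  tpl
}

#' @export
print.term_index <- function(x, ...) {
  n_cand <- sum(vapply(x$entries, nrow, integer(1)))
  cat("<term_index> ", length(x$entries), " surface forms, ",
      n_cand, " candidates\n", sep = "")
  invisible(x)
}

#' An ignore list for term recognition
#'
#' Users can stop recognizing a term everywhere (`terms`) or suppress a
#' single occurrence (`instances`, keyed by document id and span).
#'
#' @param terms character vector of surface forms to ignore everywhere;
#'   normalized with the run's policy at match time.
#' @param instances data frame with columns `doc_id`, `start`, `end`
#'   (0-based half-open character offsets), or `NULL`.
#' @return An object of class `"ignore_list"`.
#' @export
ignore_list <- function(terms = character(), instances = NULL) {
  if (is.null(instances)) {
    instances <- data.frame(doc_id = character(), start = integer(),
                            end = integer(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("doc_id", "start", "end") %in% names(instances)))
  structure(list(terms = as.character(terms), instances = instances),
            class = "ignore_list")
}

#' Construct a term annotation
#'
#' A recognized text span with its candidate ontology terms.  Offsets are
#' 0-based half-open character offsets into the document text, the usual
#' standoff-annotation convention.
#'
#' @param start,end integer offsets, `0 <= start < end <= nchar(text)`.
#' @param surface the exact document substring at `[start, end)`.
#' @param candidates data frame with columns `ncbo_id`, `term_id`, `name`,
#'   `url` (a `kind` column is optional); must have at least one row.
#' @param resolved index (1-based) of the chosen candidate, or `NA`.
#' @return An object of class `"term_annotation"`.
#' @export
term_annotation <- function(start, end, surface, candidates, resolved = NA_integer_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop("invalid span [", start, ",", end, ")", call. = FALSE)
  if (!is.data.frame(candidates) || nrow(candidates) < 1L)
    stop("candidates must be a data frame with at least one row", call. = FALSE)
  if (!is.na(resolved) && (resolved < 1L || resolved > nrow(candidates)))
    stop("resolved index ", resolved, " out of range for ",
         nrow(candidates), " candidate(s)", call. = FALSE)
  structure(list(start = start, end = end, surface = as.character(surface),
                 candidates = candidates, resolved = as.integer(resolved)),
            class = "term_annotation")
}

#' @export
print.term_annotation <- function(x, ...) {
  cat("<term_annotation> [", x$start, ",", x$end, ") \"", x$surface, "\" ",
      nrow(x$candidates), " candidate(s)", sep = "")
  if (!is.na(x$resolved)) {
    ch <- x$candidates[x$resolved, ]
    cat(" -> ", ch$term_id, " \"", ch$name, "\"", sep = "")
  }
  cat("\n")
  invisible(x)
}

# PCRE for one normalized dictionary form: literal tokens joined by a
# whitespace-run matcher (at most one line break), flanked by non-letter /
# non-digit boundaries.  Case-folding comes from the policy.
form_pattern <- function(form, policy) {
  tokens <- strsplit(form, " ", fixed = TRUE)[[1]]
  tokens <- vapply(tokens, rx_escape, character(1))
  gap <- if (policy$collapse_whitespace) {
    "(?:[ \\t\\r]+\\n?|\\n)[ \\t\\r]*"
  } else " "
  body <- paste(tokens, collapse = gap)
  paste0(if (policy$case_insensitive) "(?i)" else "",
         "(?<![\\pL\\pN])", body, "(?![\\pL\\pN])")
}

# raw occurrences of every indexed form: data.frame(start, end, form),
# 0-based half-open
scan_forms <- function(text, index) {
  starts <- integer(); ends <- integer(); forms <- character()
  for (form in names(index$entries)) {
    m <- gregexpr(form_pattern(form, index$policy), text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    starts <- c(starts, as.integer(m) - 1L)
    ends <- c(ends, as.integer(m) - 1L + len)
    forms <- c(forms, rep(form, length(m)))
  }
  data.frame(start = starts, end = ends, form = forms,
             stringsAsFactors = FALSE)
}

# longest-match-wins selection with leftmost tie-break; input/output
# data.frame(start, end, ...)
select_nonoverlapping <- function(occ) {
  if (!nrow(occ)) return(occ)
  ord <- order(-(occ$end - occ$start), occ$start)
  occ <- occ[ord, , drop = FALSE]
  keep <- logical(nrow(occ))
  acc_s <- integer(); acc_e <- integer()
  for (i in seq_len(nrow(occ))) {
    if (!any(spans_overlap(occ$start[i], occ$end[i], acc_s, acc_e))) {
      keep[i] <- TRUE
      acc_s <- c(acc_s, occ$start[i]); acc_e <- c(acc_e, occ$end[i])
    }
  }
  occ <- occ[keep, , drop = FALSE]
  occ[order(occ$start), , drop = FALSE]
}

#' Recognize ontology terms in text
#'
#' Finds all maximal, non-overlapping, boundary-aligned occurrences of the
#' indexed surface forms.  A match must be flanked by start/end of text or
#' by a character that is neither letter nor digit, so `"leukemias"` does
#' not contain a match for `"leukemia"`.  Overlapping occurrences are
#' resolved longest-match-first with ties broken by leftmost start
#' (inline mark-up forbids overlapping tags).  Ignore rules are applied
#' after overlap resolution, so ignoring a form only ever removes
#' annotations.
#'
#' @param text document text (single string).
#' @param index a [build_index()] result.
#' @param ignore an [ignore_list()] or `NULL`.
#' @param doc_id document id used to match `ignore$instances`.
#' @return List of [term_annotation()] objects sorted by `start`; empty
#'   list for empty text or an empty index.
#' @examples
#' ont <- parse_obo(text = c("[Term]", "id: CL:0000031", "name: neuroblast"),
#'                  ncbo_id = "38436")
#' anns <- recognize_terms("the neuroblast divides", build_index(ont))
#' anns[[1]]$surface
#' @export
recognize_terms <- function(text, index, ignore = NULL, doc_id = "doc") {
  stopifnot(inherits(index, "term_index"), length(text) == 1L)
  if (!nzchar(text) || !length(index$entries)) return(list())
  occ <- select_nonoverlapping(scan_forms(text, index))
  if (!is.null(ignore)) {
    stopifnot(inherits(ignore, "ignore_list"))
    ign_forms <- normalize_surface(ignore$terms, index$policy)
    keep <- !(occ$form %in% ign_forms)
    inst <- ignore$instances[ignore$instances$doc_id == doc_id, , drop = FALSE]
    if (nrow(inst)) {
      for (j in seq_len(nrow(inst))) {
        keep <- keep & !(occ$start == inst$start[j] & occ$end == inst$end[j])
      }
    }
    occ <- occ[keep, , drop = FALSE]
  }
  lapply(seq_len(nrow(occ)), function(i) {
    term_annotation(
      start = occ$start[i], end = occ$end[i],
      surface = span_text(text, occ$start[i], occ$end[i]),
      candidates = index$entries[[occ$form[i]]]
    )
  })
}

#' Resolve an ambiguous annotation to one candidate
#'
#' Recognition lists every candidate term for a span; exactly one must be
#' chosen before mark-up is emitted (the author picks the single best
#' term).
#'
#' @param ann a [term_annotation()].
#' @param choice 1-based index into `ann$candidates`.
#' @return The annotation with `resolved` set.
#' @export
resolve_candidate <- function(ann, choice) {
  stopifnot(inherits(ann, "term_annotation"))
  choice <- as.integer(choice)
  if (is.na(choice) || choice < 1L || choice > nrow(ann$candidates))
    stop("choice ", choice, " out of range: annotation has ",
         nrow(ann$candidates), " candidate(s)", call. = FALSE)
  ann$resolved <- choice
  ann
}

#' Apply an ontology term to an arbitrary text span
#'
#' Manual mark-up for spans the dictionary does not recognize: the chosen
#' ontology term is attached while the original wording is kept as the
#' surface text (e.g. applying "Leukemia, T-Cell, HTLV-II-Associated" to
#' the phrase "hairy T cell leukemia").
#'
#' @param text document text.
#' @param start,end 0-based half-open span within `text`.
#' @param ont the [ontology()] the term comes from.
#' @param term_id id of the term to apply; must exist in `ont`.
#' @return A resolved [term_annotation()] with that single candidate.
#' @export
apply_custom_term <- function(text, start, end, ont, term_id) {
  stopifnot(inherits(ont, "ontology"), length(text) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start ||
      end > nchar(text))
    stop("invalid span [", start, ",", end, ") for text of length ",
         nchar(text), call. = FALSE)
  tm <- ont$terms[[term_id]]
  if (is.null(tm))
    stop("term_id '", term_id, "' not found in ontology ",
         if (nzchar(ont$label)) ont$label else ont$ncbo_id, call. = FALSE)
  cand <- data.frame(ncbo_id = ont$ncbo_id, term_id = tm$term_id,
                     name = tm$name, kind = "custom",
                     url = term_url(ont, tm$term_id),
                     stringsAsFactors = FALSE)
  term_annotation(start, end, span_text(text, start, end), cand, resolved = 1L)
}

#' Propagate a resolved annotation to all other occurrences
#'
#' Marks every other boundary-aligned occurrence of the same surface form
#' (under the same normalization) with identical mark-up, skipping
#' occurrences that would overlap an existing annotation so that the
#' result stays non-overlapping.
#'
#' @param text document text.
#' @param resolved a resolved [term_annotation()].
#' @param existing list of current annotations (any objects with `start`
#'   and `end` fields, e.g. term annotations, id matches or foreign
#'   spans).
#' @param policy normalization policy for locating occurrences.
#' @return `existing` plus `resolved` plus the propagated copies, sorted
#'   by start.
#' @export
propagate_markup <- function(text, resolved, existing = list(),
                             policy = norm_policy()) {
  stopifnot(inherits(resolved, "term_annotation"))
  if (is.na(resolved$resolved))
    stop("annotation must be resolved before propagation", call. = FALSE)
  ex_s <- vapply(existing, function(a) as.integer(a$start), integer(1))
  ex_e <- vapply(existing, function(a) as.integer(a$end), integer(1))
  out <- existing
  if (!any(ex_s == resolved$start & ex_e == resolved$end)) {
    out <- c(out, list(resolved))
    ex_s <- c(ex_s, resolved$start); ex_e <- c(ex_e, resolved$end)
  }
  form <- normalize_surface(resolved$surface, policy)
  m <- gregexpr(form_pattern(form, policy), text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      s <- as.integer(m[k]) - 1L; e <- s + len[k]
      if (any(spans_overlap(s, e, ex_s, ex_e))) next
      copy <- resolved
      copy$start <- s; copy$end <- e
      copy$surface <- span_text(text, s, e)
      out <- c(out, list(copy))
      ex_s <- c(ex_s, s); ex_e <- c(ex_e, e)
    }
  }
  out[order(vapply(out, function(a) as.integer(a$start), integer(1)))]
}

#' Annotations as a standoff data frame
#'
#' @param anns list of [term_annotation()] objects.
#' @param doc_id document id column value.
#' @return data frame with columns `doc_id`, `start`, `end`, `surface`,
#'   `ncbo_id`, `term_id` (of the resolved candidate, or of the first
#'   candidate prefixed with nothing when unresolved — unresolved rows
#'   repeat one row per candidate), and `resolved` (logical).
#' @export
annotations_standoff <- function(anns, doc_id = "doc") {
  rows <- lapply(anns, function(a) {
    idx <- if (!is.na(a$resolved)) a$resolved else seq_len(nrow(a$candidates))
    data.frame(doc_id = doc_id, start = a$start, end = a$end,
               surface = a$surface,
               ncbo_id = a$candidates$ncbo_id[idx],
               term_id = a$candidates$term_id[idx],
               resolved = !is.na(a$resolved),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(doc_id = character(), start = integer(),
                      end = integer(), surface = character(),
                      ncbo_id = character(), term_id = character(),
                      resolved = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
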