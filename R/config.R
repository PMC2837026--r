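#' Load a run configuration
#'
#' The run configuration replaces an interactive configuration panel: it
#' declares the active ontologies (with their registry metadata), which
#' database recognizers are on, ignore rules, recorded ambiguity
#' decisions, the normalization policy and the auto-single rule.  The
#' file is YAML with the following top-level keys, all optional except
#' `ontologies`:
#'
#' \preformatted{
#' ontologies:
#'   - obo_path: cl-subset.obo        # required per entry
#'     ncbo_id: "38436"               # registry id, default ""
#'     label: Cell Ontology           # default ""
#'     url_template: bioportal.bioontology.org/visualize/39004
#'     enabled: true                  # default true
#' databases: {pdb: true, uniprotkb: true, genbank: true, refseq: true}
#' ignore:
#'   terms: [sodium]
#'   instances: [{doc_id: doc, start: 10, end: 16}]
#' decisions:
#'   terms: [{surface: neuroblast, ncbo_id: "38436", term_id: CL:0000031}]
#'   ids:   [{id_text: A12345, database: genbank}]
#' href_templates: {uniprotkb: "https://www.uniprot.org/uniprotkb/%s"}
#' normalization: {case_insensitive: true, collapse_whitespace: true}
#' auto_single: false
#' include_obsolete: false
#' }
#'
#' Defaults: all four databases enabled, empty ignore list, no decisions,
#' `auto_single` off.
#'
#' @param path path to the YAML file.
#' @param base_dir directory against which relative `obo_path`s are
#'   resolved; defaults to the config file's directory.
#' @return An object of class `"run_config"`.
#' @section Errors: an unknown database label, or an enabled ontology
#'   entry whose `obo_path` is unreadable, is an error naming the entry.
#' @export
load_config <- function(path, base_dir = dirname(path)) {
  raw <- yaml::read_yaml(path)
  run_config(
    ontologies = raw$ontologies %||% list(),
    databases = raw$databases,
    ignore = raw$ignore,
    decisions = raw$decisions,
    href_templates = raw$href_templates,
    normalization = raw$normalization,
    auto_single = isTRUE(raw$auto_single),
    include_obsolete = isTRUE(raw$include_obsolete),
    base_dir = base_dir
  )
}

#' @rdname load_config
#' @param ontologies list of registry entries (see above).
#' @param databases named logical list/vector of per-database flags.
#' @param ignore list with `terms` and/or `instances`.
#' @param decisions list with `terms` and/or `ids` decision records.
#' @param href_templates named overrides for link templates.
#' @param normalization list with `case_insensitive`,
#'   `collapse_whitespace`.
#' @param auto_single automatically resolve single-candidate spans?
#' @param include_obsolete index obsolete term labels?
#' @export
run_config <- function(ontologies = list(), databases = NULL, ignore = NULL,
                       decisions = NULL, href_templates = NULL,
                       normalization = NULL, auto_single = FALSE,
                       include_obsolete = FALSE, base_dir = ".") {
  entries <- lapply(seq_along(ontologies), function(i) {
    e <- ontologies[[i]]
    if (is.null(e$obo_path))
      stop("ontology entry ", i, " has no obo_path", call. = FALSE)
    p <- e$obo_path
    if (!file.exists(p) && !grepl("^(/|[A-Za-z]:)", p))
      p <- file.path(base_dir, e$obo_path)
    enabled <- e$enabled %||% TRUE
    if (isTRUE(enabled) && !file.exists(p))
      stop("ontology entry ", i, " (", e$label %||% e$obo_path,
           "): obo_path not readable: ", p, call. = FALSE)
    list(obo_path = p, ncbo_id = as.character(e$ncbo_id %||% ""),
         label = as.character(e$label %||% ""),
         url_template = as.character(e$url_template %||% ""),
         enabled = isTRUE(enabled))
  })

  db <- setNames(rep(TRUE, 4L), db_label_order)
  if (!is.null(databases)) {
    labs <- match_db_labels(names(databases))
    for (l in labs) db[[l]] <- isTRUE(databases[[l]])
  }

  ign <- ignore_list(
    terms = as.character(ignore$terms %||% character()),
    instances = if (length(ignore$instances)) {
      do.call(rbind, lapply(ignore$instances, function(r)
        data.frame(doc_id = as.character(r$doc_id %||% "doc"),
                   start = as.integer(r$start), end = as.integer(r$end),
                   stringsAsFactors = FALSE)))
    } else NULL)

  dec_terms <- lapply(decisions$terms %||% list(), function(d) {
    if (is.null(d$surface) || is.null(d$term_id))
      stop("term decision needs 'surface' and 'term_id'", call. = FALSE)
    list(surface = as.character(d$surface),
         ncbo_id = as.character(d$ncbo_id %||% ""),
         term_id = as.character(d$term_id))
  })
  dec_ids <- lapply(decisions$ids %||% list(), function(d) {
    if (is.null(d$id_text) || is.null(d$database))
      stop("id decision needs 'id_text' and 'database'", call. = FALSE)
    list(id_text = as.character(d$id_text),
         database = match_db_labels(d$database))
  })

  tpl <- default_href_templates()
  if (!is.null(href_templates)) {
    labs <- match_db_labels(names(href_templates))
    for (l in labs) tpl[[l]] <- as.character(href_templates[[l]])
  }

  pol <- norm_policy(
    case_insensitive = normalization$case_insensitive %||% TRUE,
    collapse_whitespace = normalization$collapse_whitespace %||% TRUE)

  structure(
    list(ontologies = entries, databases = db, ignore = ign,
         decisions = list(terms = dec_terms, ids = dec_ids),
         href_templates = tpl, policy = pol,
         auto_single = isTRUE(auto_single),
         include_obsolete = isTRUE(include_obsolete)),
    class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> ", length(x$ontologies), " ontology entr",
      if (length(x$ontologies) == 1) "y" else "ies", "; databases on: ",
      paste(names(x$databases)[x$databases], collapse = ", "),
      "; auto_single=", x$auto_single, "\n", sep = "")
  invisible(x)
}

# load and validate every enabled ontology of a config
load_config_ontologies <- function(config) {
  onts <- list()
  for (e in config$ontologies) {
    if (!e$enabled) next
    ont <- parse_obo(file = e$obo_path, ncbo_id = e$ncbo_id,
                     label = e$label, url_template = e$url_template)
    rep <- validate_ontology(ont)
    if (!is_usable(rep))
      stop("ontology ", e$label %||% e$obo_path, " failed validation: ",
           paste(unique(rep$issue), collapse = ", "), call. = FALSE)
    onts <- c(onts, list(ont))
  }
  onts
}

#' Annotate a document
#'
#' Runs the whole flow over one document: load the enabled ontologies,
#' build the term index, recognize terms and database identifiers, apply
#' ignore rules and recorded decisions (plus the auto-single rule),
#' inject mark-up over whatever mark-up the document already carries, and
#' report per-stage counts.  Unresolved ambiguous spans are never
#' injected — choosing among candidates is the author's call — so they
#' are only counted and exported.
#'
#' Spans that already carry mark-up (from an earlier pass or another
#' author) are left untouched: a recognized occurrence overlapping an
#' existing span is dropped before resolution, which makes the pipeline
#' idempotent.
#'
#' @param doc document as a file path (default) or, with
#'   `from_text = TRUE`, the document string itself.  May be plain text
#'   or a fragment with existing inline mark-up.
#' @param config a [run_config()] / [load_config()] object.
#' @param doc_id id used in reports and ignore-instance matching;
#'   defaults to the file name (or `"doc"` for text input).
#' @param from_text treat `doc` as the document text itself.
#' @return An object of class `"biolit_run"` with elements `document`
#'   (the [marked_document()]), `serialized` (its string form), `report`
#'   (class `"pipeline_report"`), `annotations` and `id_matches` (the
#'   unfiltered recognition results with resolutions applied).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: CL:0000031", "name: neuroblast"), obo)
#' cfg <- run_config(ontologies = list(list(obo_path = obo,
#'                                          ncbo_id = "38436")),
#'                   auto_single = TRUE)
#' run <- run_pipeline("the neuroblast divides", cfg, from_text = TRUE)
#' run$serialized
#' @export
run_pipeline <- function(doc, config, doc_id = NULL, from_text = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (from_text) {
    raw <- doc
    doc_id <- doc_id %||% "doc"
  } else {
    if (!file.exists(doc)) stop("document not found: ", doc, call. = FALSE)
    raw <- paste(readLines(doc, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
    doc_id <- doc_id %||% basename(doc)
  }

  onts <- load_config_ontologies(config)
  index <- build_index(onts, policy = config$policy,
                       include_obsolete = config$include_obsolete)

  # decisions must reference loaded terms
  for (d in config$decisions$terms) {
    found <- any(vapply(onts, function(o) {
      !is.null(o$terms[[d$term_id]]) &&
        (!nzchar(d$ncbo_id) || identical(o$ncbo_id, d$ncbo_id))
    }, logical(1)))
    if (!found)
      stop("decision for surface '", d$surface, "' references term ",
           d$term_id, " which is not loaded", call. = FALSE)
  }

  existing <- parse_markup(raw)
  text <- existing$text
  ex_s <- vapply(existing$spans, function(x) as.integer(x$start), integer(1))
  ex_e <- vapply(existing$spans, function(x) as.integer(x$end), integer(1))

  anns <- recognize_terms(text, index, ignore = NULL, doc_id = doc_id)
  enabled_dbs <- names(config$databases)[config$databases]
  ids <- if (length(enabled_dbs)) recognize_ids(text, enabled = enabled_dbs)
         else list()

  # drop occurrences already covered by existing mark-up (idempotence)
  overlaps_existing <- function(s, e) any(spans_overlap(s, e, ex_s, ex_e))
  anns <- Filter(function(a) !overlaps_existing(a$start, a$end), anns)
  ids <- Filter(function(m) !overlaps_existing(m$start, m$end), ids)
  n_term_rec <- length(anns); n_id_rec <- length(ids)

  # ignore rules (terms): by normalized form or by exact instance span
  ign_forms <- normalize_surface(config$ignore$terms, config$policy)
  inst <- config$ignore$instances
  inst <- inst[inst$doc_id == doc_id, , drop = FALSE]
  is_ignored <- function(a) {
    normalize_surface(a$surface, config$policy) %in% ign_forms ||
      (nrow(inst) > 0 && any(inst$start == a$start & inst$end == a$end))
  }
  ignored <- vapply(anns, is_ignored, logical(1))
  n_term_ign <- sum(ignored)
  live <- anns[!ignored]

  # resolution: decisions file first, then the auto-single rule
  dec_by_surface <- config$decisions$terms
  resolve_ann <- function(a) {
    surf <- normalize_surface(a$surface, config$policy)
    for (d in dec_by_surface) {
      if (normalize_surface(d$surface, config$policy) != surf) next
      hit <- which(a$candidates$term_id == d$term_id &
                     (!nzchar(d$ncbo_id) | a$candidates$ncbo_id == d$ncbo_id))
      if (length(hit)) return(resolve_candidate(a, hit[1]))
    }
    if (config$auto_single && nrow(a$candidates) == 1L)
      return(resolve_candidate(a, 1L))
    a
  }
  live <- lapply(live, resolve_ann)
  resolved_terms <- Filter(function(a) !is.na(a$resolved), live)
  n_term_res <- length(resolved_terms)
  n_term_unres <- length(live) - n_term_res

  resolve_id <- function(m) {
    for (d in config$decisions$ids) {
      if (identical(d$id_text, m$id_text) && d$database %in% m$candidates)
        return(resolve_db_match(m, d$database, config$href_templates))
    }
    if (config$auto_single && length(m$candidates) == 1L)
      return(resolve_db_match(m, m$candidates[1], config$href_templates))
    m
  }
  ids <- lapply(ids, resolve_id)
  resolved_ids <- Filter(function(m) !is.na(m$resolved), ids)
  n_id_res <- length(resolved_ids)
  n_id_unres <- n_id_rec - n_id_res

  out_doc <- inject_markup(text, resolved_terms, resolved_ids,
                           existing = existing)

  report <- structure(
    list(doc_id = doc_id,
         terms = c(recognized = n_term_rec, resolved = n_term_res,
                   ignored = n_term_ign, unresolved = n_term_unres),
         ids = c(recognized = n_id_rec, resolved = n_id_res,
                 ignored = 0L, unresolved = n_id_unres),
         existing_spans = length(existing$spans),
         rejected_overlaps = nrow(attr(out_doc, "rejected"))),
    class = "pipeline_report")

  structure(list(document = out_doc, serialized = serialize_markup(out_doc),
                 report = report, annotations = live, id_matches = ids),
            class = "biolit_run")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", x$doc_id, "\n", sep = "")
  cat("  terms: ", paste(names(x$terms), x$terms, sep = "=",
                         collapse = " "), "\n", sep = "")
  cat("  ids:   ", paste(names(x$ids), x$ids, sep = "=",
                         collapse = " "), "\n", sep = "")
  cat("  existing spans: ", x$existing_spans,
      "; rejected overlaps: ", x$rejected_overlaps, "\n", sep = "")
  invisible(x)
}

#' @export
print.biolit_run <- function(x, ...) {
  print(x$report)
  cat("  output: ", nchar(x$serialized), " chars, ",
      length(x$document$spans), " span(s)\n", sep = "")
  invisible(x)
}
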