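#' Specification for synthetic test fixtures
#'
#' The fixture generator produces toy OBO ontologies and documents with
#' exact, by-construction ground truth, so every recognizer can be tested
#' without downloading anything.  Generation is a pure function of
#' `seed`: the same spec yields byte-identical output.  Filler prose is
#' drawn from a fixed lowercase word list disjoint from every generated
#' label, so a planted span is the only way an indexed form can occur.
#'
#' @param seed integer RNG seed.
#' @param n_terms terms per generated ontology (>= 2; the canonical
#'   neuroblast term CL:0000031 is always included in the first
#'   ontology).
#' @param synonym_rate probability a term gets a synonym.
#' @param max_parents maximum `is_a` parents per term (DAG kept acyclic
#'   by only linking to earlier terms).
#' @param ambiguity_rate fraction of term names shared verbatim between
#'   the two ontologies of a generated pair.
#' @param n_filler filler words in a generated document.
#' @param n_planted_terms,n_planted_ids planted term/identifier
#'   occurrences per document.
#' @param decoys plant near-miss tokens (`"1MU2x"`, `"1mu2"`, pluralized
#'   term forms) that must NOT be recognized?
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_terms = 10L, synonym_rate = 0.5,
                         max_parents = 2L, ambiguity_rate = 0,
                         n_filler = 120L, n_planted_terms = 3L,
                         n_planted_ids = 2L, decoys = TRUE) {
  stopifnot(n_terms >= 2L, synonym_rate >= 0, synonym_rate <= 1,
            ambiguity_rate >= 0, ambiguity_rate <= 1, max_parents >= 0L)
  structure(list(seed = as.integer(seed), n_terms = as.integer(n_terms),
                 synonym_rate = synonym_rate,
                 max_parents = as.integer(max_parents),
                 ambiguity_rate = ambiguity_rate,
                 n_filler = as.integer(n_filler),
                 n_planted_terms = as.integer(n_planted_terms),
                 n_planted_ids = as.integer(n_planted_ids),
                 decoys = isTRUE(decoys)),
            class = "fixture_spec")
}

# syllable-built label vocabulary; disjoint from fixture_filler_words()
fixture_label_words <- function(n, prefix = "") {
  syll <- c("zor", "vex", "mek", "quol", "brix", "fyn", "dax", "plu",
            "gri", "tob", "wist", "kel", "nuv", "ryl", "shom", "jaq")
  combos <- as.vector(outer(syll, syll, paste0))
  if (n > length(combos))
    combos <- c(combos, as.vector(outer(combos, syll, paste0)))
  stopifnot(n <= length(combos))
  paste0(prefix, combos[seq_len(n)])
}

fixture_filler_words <- function() {
  c("the", "was", "were", "with", "into", "during", "after", "before",
    "observed", "measured", "incubated", "treated", "analyzed", "showed",
    "results", "samples", "control", "significant", "increase", "decrease",
    "protein", "gene", "expression", "levels", "assay", "buffer", "figure",
    "shown", "data", "method", "described", "previously", "compared",
    "between", "groups", "study", "found", "these", "under", "conditions")
}

# valid accessions with their candidate database sets (by construction of
# the printed patterns; the dual-candidate A12345 case is deliberate)
fixture_id_pool <- function() {
  list(
    list(id = "1MU2", dbs = "pdb"),
    list(id = "2XYZ", dbs = "pdb"),
    list(id = "P0A7G6", dbs = "uniprotkb"),
    list(id = "Q9H0H5", dbs = "uniprotkb"),
    list(id = "A12345", dbs = c("uniprotkb", "genbank")),
    list(id = "U93236", dbs = "genbank"),
    list(id = "AF231982", dbs = "genbank"),
    list(id = "GAA01234", dbs = "genbank"),
    list(id = "NM_000546", dbs = "refseq"),
    list(id = "XP_0123456", dbs = "refseq")
  )
}

fixture_decoy_tokens <- function() {
  c("1MU2x", "1mu2", "in1MU2x", "nm_000546", "P0A7G", "12345",
    "neuroblasts")
}

#' Generate a synthetic ontology
#'
#' Produces well-formed OBO 1.2 text with an acyclic `is_a` DAG and a
#' ground-truth table.  The first generated ontology of a run always
#' contains the canonical neuroblast term (`CL:0000031`, ncbo_id 38436
#' registry entry in the canonical config) so that the worked mark-up
#' example is always exercisable.
#'
#' @param spec a [fixture_spec()].
#' @param ncbo_id,label registry metadata for the parsed ontology.
#' @param id_prefix CURIE prefix for generated term ids.
#' @param share_names labels to re-use verbatim as term names (drives
#'   cross-ontology ambiguity); extra terms are appended for them.
#' @param include_neuroblast include the canonical CL:0000031 term?
#' @return list with `obo` (the OBO text), `ontology` (parsed, with
#'   registry metadata), and `truth` (data frame: `term_id`, `name`,
#'   `synonyms` (";"-joined), `parents` (";"-joined)).
#' @export
gen_ontology <- function(spec, ncbo_id = "38436", label = "fixture ontology",
                         id_prefix = "FX", share_names = character(),
                         include_neuroblast = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_private_seed(spec$seed + 1000L, {
    n <- spec$n_terms
    # distinct by construction: single-word names use words[1..n], the
    # second word of a two-word name comes from the reserved upper half
    words <- sample(fixture_label_words(2L * n))
    term_names <- vapply(seq_len(n), function(i) {
      if (runif(1) < 0.4) paste(words[i], words[n + i]) else words[i]
    }, character(1))
    if (length(share_names)) term_names <- c(term_names, share_names)
    if (include_neuroblast) term_names <- c("neuroblast", term_names)
    n_all <- length(term_names)

    ids <- sprintf("%s:%07d", id_prefix, seq_len(n_all))
    if (include_neuroblast) ids[1] <- "CL:0000031"

    terms <- vector("list", n_all)
    for (i in seq_len(n_all)) {
      parents <- character()
      if (i > 1L && spec$max_parents > 0L) {
        k <- sample(0:min(spec$max_parents, i - 1L), 1L)
        if (k > 0L) parents <- sample(ids[seq_len(i - 1L)], k)
      }
      syns <- character()
      if (runif(1) < spec$synonym_rate) {
        syns <- paste(term_names[i], "variant")
        names(syns) <- sample(c("EXACT", "RELATED", "BROAD", "NARROW"), 1L)
      }
      terms[[i]] <- ontology_term(ids[i], term_names[i], synonyms = syns,
                                  parents = parents)
    }
    ont <- ontology(terms, ncbo_id = ncbo_id, label = label,
                    url_template = "")
    obo <- write_obo(ont)
    truth <- data.frame(
      term_id = ids, name = term_names,
      synonyms = vapply(terms, function(t)
        paste(t$synonyms, collapse = ";"), character(1)),
      parents = vapply(terms, function(t)
        paste(t$parents, collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
    list(obo = obo, ontology = ont, truth = truth)
  })
}

#' Generate a pair of ontologies with controlled ambiguity
#'
#' @param spec a [fixture_spec()]; `ambiguity_rate` controls the fraction
#'   of the first ontology's term names duplicated verbatim in the
#'   second.
#' @return list of two [gen_ontology()] results.
#' @export
gen_ontology_pair <- function(spec) {
  first <- gen_ontology(spec, ncbo_id = "38436", label = "fixture ontology A",
                        id_prefix = "FX")
  shared <- with_private_seed(spec$seed + 2000L, {
    pool <- first$truth$name
    n_share <- round(spec$ambiguity_rate * length(pool))
    if (n_share > 0L) sample(pool, n_share) else character()
  })
  spec2 <- spec
  spec2$seed <- spec$seed + 1L
  second <- gen_ontology(spec2, ncbo_id = "40000",
                         label = "fixture ontology B", id_prefix = "GX",
                         share_names = shared, include_neuroblast = FALSE)
  list(first, second)
}

#' Generate a document with exact ground truth
#'
#' Assembles a document from filler words, planted term surfaces (names
#' or synonyms of the supplied ontologies), planted database accessions,
#' optional decoy tokens, and optional foreign mark-up, with at least one
#' filler word between planted items.  Because filler and decoys can
#' never produce a dictionary or pattern match, the ground-truth tables
#' list exactly the spans the recognizers must return.
#'
#' @param spec a [fixture_spec()].
#' @param ontologies list of [ontology()] objects (typically from
#'   [gen_ontology()]`$ontology`).
#' @param with_foreign also insert a foreign `<bold>` element (recorded
#'   in `foreign`, excluded from plain text ground truth)?
#' @return list with `text`, `term_truth` (data frame `start`, `end`,
#'   `surface`, `n_candidates`), `id_truth` (data frame `start`, `end`,
#'   `id_text`, `databases` (";"-joined)), and `foreign` (data frame
#'   `start`, `end`, `raw`; zero rows unless `with_foreign`).
#' @export
gen_document <- function(spec, ontologies, with_foreign = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (inherits(ontologies, "ontology")) ontologies <- list(ontologies)

  # all indexed forms with candidate counts, computed from the ontology
  # structures themselves (construction-side, not via the recognizer)
  form_count <- new.env(parent = emptyenv())
  bump <- function(f) {
    f <- tolower(gsub("[[:space:]]+", " ", trimws(f)))
    form_count[[f]] <- (form_count[[f]] %||% 0L) + 1L
  }
  for (ont in ontologies) for (tm in ont$terms) {
    if (tm$obsolete) next
    bump(tm$name)
    for (s in tm$synonyms) bump(s)
  }
  all_forms <- ls(form_count)

  with_private_seed(spec$seed + 3000L, {
    filler <- fixture_filler_words()
    tokens <- sample(filler, spec$n_filler, replace = TRUE)

    plant <- list()  # list of (token string, kind, payload)
    if (spec$n_planted_terms > 0L && length(all_forms)) {
      forms <- sample(all_forms, min(spec$n_planted_terms, length(all_forms)),
                      replace = FALSE)
      for (f in forms) plant <- c(plant, list(list(tok = f, kind = "term")))
    }
    if (spec$n_planted_ids > 0L) {
      pool <- fixture_id_pool()
      picks <- sample(length(pool), min(spec$n_planted_ids, length(pool)))
      for (p in pool[picks])
        plant <- c(plant, list(list(tok = p$id, kind = "id", dbs = p$dbs)))
    }
    if (spec$decoys) {
      for (d in sample(fixture_decoy_tokens(), 3L))
        plant <- c(plant, list(list(tok = d, kind = "decoy")))
    }
    if (with_foreign) {
      plant <- c(plant, list(list(
        tok = "landmark", kind = "foreign",
        raw = "<bold>landmark</bold>")))
    }

    # insertion points: distinct filler gaps so planted items never touch
    n_slots <- length(tokens) + 1L
    if (length(plant) > n_slots)
      stop("document too short for planted items", call. = FALSE)
    slots <- sort(sample(n_slots, length(plant)))
    # weave: after filler token (slot-1)
    out_tokens <- character(); kinds <- character()
    payload <- vector("list", 0L)
    prev <- 0L
    for (j in seq_along(slots)) {
      gap_tokens <- if (slots[j] - 1L >= prev + 1L)
        tokens[seq(prev + 1L, slots[j] - 1L)] else character()
      out_tokens <- c(out_tokens, gap_tokens, plant[[j]]$tok)
      kinds <- c(kinds, rep("filler", length(gap_tokens)), plant[[j]]$kind)
      payload <- c(payload, rep(list(NULL), length(gap_tokens)),
                   list(plant[[j]]))
      prev <- slots[j] - 1L
    }
    if (prev < length(tokens)) {
      rest <- tokens[seq(prev + 1L, length(tokens))]
      out_tokens <- c(out_tokens, rest)
      kinds <- c(kinds, rep("filler", length(rest)))
      payload <- c(payload, rep(list(NULL), length(rest)))
    }

    # offsets: tokens joined by single spaces (0-based half-open)
    lens <- nchar(out_tokens)
    starts <- cumsum(c(0L, (lens + 1L)[-length(lens)]))
    ends <- starts + lens
    text <- paste(out_tokens, collapse = " ")

    term_rows <- list(); id_rows <- list(); foreign_rows <- list()
    for (j in seq_along(out_tokens)) {
      k <- kinds[j]
      if (k == "term") {
        f <- out_tokens[j]
        term_rows <- c(term_rows, list(data.frame(
          start = starts[j], end = ends[j], surface = f,
          n_candidates = form_count[[f]], stringsAsFactors = FALSE)))
      } else if (k == "id") {
        id_rows <- c(id_rows, list(data.frame(
          start = starts[j], end = ends[j], id_text = out_tokens[j],
          databases = paste(payload[[j]]$dbs, collapse = ";"),
          stringsAsFactors = FALSE)))
      } else if (k == "foreign") {
        foreign_rows <- c(foreign_rows, list(data.frame(
          start = starts[j], end = ends[j], raw = payload[[j]]$raw,
          stringsAsFactors = FALSE)))
      }
    }
    bind <- function(rows, proto) if (length(rows)) do.call(rbind, rows) else proto
    list(
      text = text,
      term_truth = bind(term_rows, data.frame(
        start = integer(), end = integer(), surface = character(),
        n_candidates = integer(), stringsAsFactors = FALSE)),
      id_truth = bind(id_rows, data.frame(
        start = integer(), end = integer(), id_text = character(),
        databases = character(), stringsAsFactors = FALSE)),
      foreign = bind(foreign_rows, data.frame(
        start = integer(), end = integer(), raw = character(),
        stringsAsFactors = FALSE))
    )
  })
}

#' Write a complete fixture set to a directory
#'
#' Writes two OBO ontologies, a document, ground-truth TSVs, and a ready
#' run-configuration file.
#'
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @param spec optional [fixture_spec()]; defaults to
#'   `fixture_spec(seed)`.
#' @return Invisibly, the list of written paths.
#' @export
gen_fixtures <- function(seed = 1L, out_dir, spec = fixture_spec(seed)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pair <- gen_ontology_pair(spec)
  doc <- gen_document(spec, list(pair[[1]]$ontology, pair[[2]]$ontology))
  paths <- c(
    obo_a = file.path(out_dir, "ontology_a.obo"),
    obo_b = file.path(out_dir, "ontology_b.obo"),
    doc = file.path(out_dir, "document.txt"),
    term_truth = file.path(out_dir, "term_truth.tsv"),
    id_truth = file.path(out_dir, "id_truth.tsv"),
    config = file.path(out_dir, "config.yaml"))
  writeLines(pair[[1]]$obo, paths[["obo_a"]], useBytes = TRUE)
  writeLines(pair[[2]]$obo, paths[["obo_b"]], useBytes = TRUE)
  writeLines(doc$text, paths[["doc"]], useBytes = TRUE)
  utils::write.table(doc$term_truth, paths[["term_truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(doc$id_truth, paths[["id_truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- list(
    ontologies = list(
      list(obo_path = "ontology_a.obo", ncbo_id = "38436",
           label = "fixture ontology A",
           url_template = "bioportal.bioontology.org/visualize/39004"),
      list(obo_path = "ontology_b.obo", ncbo_id = "40000",
           label = "fixture ontology B")),
    auto_single = TRUE)
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(as.list(paths))
}
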