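make_index <- function(..., policy = norm_policy()) {
  build_index(list(...), policy = policy)
}

test_that("the index has one entry per distinct normalized name and synonym", {
  ont <- neuroblast_ontology()
  idx <- build_index(ont)
  expect_length(idx$entries, 2L)      # name + one synonym
  expect_equal(nrow(idx$entries[["neuroblast"]]), 1L)
  expect_equal(idx$entries[["neuroblast"]]$term_id, "CL:0000031")
})

test_that("a form defined in two ontologies maps to two candidates", {
  a <- ontology(list(ontology_term("HD:0000001", "leukemia")),
                ncbo_id = "1009")
  b <- ontology(list(ontology_term("FHH:0000077", "leukemia")),
                ncbo_id = "1126")
  idx <- make_index(a, b)
  expect_equal(nrow(idx$entries[["leukemia"]]), 2L)
  expect_setequal(idx$entries[["leukemia"]]$ncbo_id, c("1009", "1126"))
})

test_that("an empty ontology list yields an empty index, not an error", {
  idx <- build_index(list())
  expect_length(idx$entries, 0L)
  expect_equal(recognize_terms("any text", idx), list())
})

test_that("obsolete terms are excluded from the index by default", {
  ont <- parse_obo(text = c("[Term]", "id: A:1", "name: oldterm",
                            "is_obsolete: true",
                            "[Term]", "id: A:2", "name: newterm"))
  expect_length(build_index(ont)$entries, 1L)
  expect_length(build_index(ont, include_obsolete = TRUE)$entries, 2L)
})

test_that("recognition finds a term with its span, surface and candidate", {
  anns <- recognize_terms("the neuroblast divides",
                          build_index(neuroblast_ontology()))
  expect_length(anns, 1L)
  a <- anns[[1]]
  expect_equal(a$start, 4L)
  expect_equal(a$end, 14L)
  expect_equal(a$surface, "neuroblast")
  expect_equal(a$candidates$term_id, "CL:0000031")
  expect_true(is.na(a$resolved))
})

test_that("matching is case-insensitive and collapses whitespace runs", {
  ont <- ontology(list(ontology_term("X:1", "hairy cell leukemia")))
  idx <- build_index(ont)
  anns <- recognize_terms("Hairy  Cell\nLeukemia was seen", idx)
  expect_length(anns, 1L)
  expect_equal(anns[[1]]$surface, "Hairy  Cell\nLeukemia")
  # a paragraph break (two newlines) does not bridge a multi-word term
  expect_length(recognize_terms("hairy cell\n\nleukemia", idx), 0L)
})

test_that("token boundaries block matches inside longer words", {
  ont <- ontology(list(ontology_term("X:1", "leukemia")))
  idx <- build_index(ont)
  expect_length(recognize_terms("leukemias are diseases", idx), 0L)
  expect_length(recognize_terms("(leukemia)", idx), 1L)
  expect_length(recognize_terms("pre-leukemia.", idx), 1L)
})

test_that("a phrase absent from the dictionary is not recognized", {
  # the precise HTLV-II term and its synonym do not match the natural
  # phrasing an author actually uses
  idx <- build_index(make_leukemia_ontology())
  anns <- recognize_terms("we observed hairy T cell leukemia in samples", idx)
  expect_length(anns, 0L)
})

test_that("overlapping occurrences resolve longest-first, leftmost on ties", {
  ont <- ontology(list(ontology_term("X:1", "cell"),
                       ontology_term("X:2", "hairy cell leukemia"),
                       ontology_term("X:3", "hairy cell")))
  idx <- build_index(ont)
  anns <- recognize_terms("hairy cell leukemia", idx)
  expect_length(anns, 1L)
  expect_equal(anns[[1]]$candidates$term_id, "X:2")
  # ties: "alpha beta" and "beta gamma" over "alpha beta gamma"
  ont2 <- ontology(list(ontology_term("Y:1", "alpha beta"),
                        ontology_term("Y:2", "beta gamma")))
  anns2 <- recognize_terms("alpha beta gamma", build_index(ont2))
  expect_length(anns2, 1L)
  expect_equal(anns2[[1]]$candidates$term_id, "Y:1")
})

test_that("annotations never overlap and are sorted by start", {
  for (seed in 1:10) {
    spec <- fixture_spec(seed, n_terms = 12, ambiguity_rate = 0.4,
                         n_planted_terms = 5, n_filler = 60)
    pair <- gen_ontology_pair(spec)
    onts <- list(pair[[1]]$ontology, pair[[2]]$ontology)
    doc <- gen_document(spec, onts)
    anns <- recognize_terms(doc$text, build_index(onts))
    if (length(anns) < 2L) next
    s <- vapply(anns, `[[`, integer(1), "start")
    e <- vapply(anns, `[[`, integer(1), "end")
    expect_true(all(diff(s) > 0))
    expect_true(all(s[-1] >= e[-length(e)]))
  }
})

test_that("recognition equals the naive sliding-scan oracle on 100 random documents", {
  for (seed in 1:100) {
    spec <- fixture_spec(seed, n_terms = 10, ambiguity_rate = 0.3,
                         n_planted_terms = 4, n_planted_ids = 0,
                         n_filler = 50)
    pair <- gen_ontology_pair(spec)
    onts <- list(pair[[1]]$ontology, pair[[2]]$ontology)
    doc <- gen_document(spec, onts)
    idx <- build_index(onts)
    got <- annotations_standoff(recognize_terms(doc$text, idx))
    got <- unique(got[, c("start", "end")])
    want <- oracle_recognize_terms(doc$text, names(idx$entries))
    expect_equal(got$start, want$start, info = paste("seed", seed))
    expect_equal(got$end, want$end, info = paste("seed", seed))
  }
})

test_that("ignoring a form or an instance removes only those annotations", {
  ont <- ontology(list(ontology_term("X:1", "alpha"),
                       ontology_term("X:2", "beta")))
  idx <- build_index(ont)
  text <- "alpha then beta then alpha"
  base <- recognize_terms(text, idx)
  expect_length(base, 3L)
  ign_form <- recognize_terms(text, idx, ignore_list(terms = "Alpha"))
  expect_length(ign_form, 1L)
  expect_equal(ign_form[[1]]$surface, "beta")
  inst <- ignore_list(instances = data.frame(doc_id = "d", start = 0L,
                                             end = 5L))
  ign_inst <- recognize_terms(text, idx, inst, doc_id = "d")
  expect_length(ign_inst, 2L)
  expect_setequal(vapply(ign_inst, `[[`, integer(1), "start"), c(11L, 21L))
  # instance spans only apply to their own document
  expect_length(recognize_terms(text, idx, inst, doc_id = "other"), 3L)
})

test_that("ignoring is monotone: more ignores never add annotations", {
  for (seed in 1:10) {
    spec <- fixture_spec(seed, n_terms = 10, n_planted_terms = 5,
                         n_filler = 50)
    g <- gen_ontology(spec)
    idx <- build_index(g$ontology)
    doc <- gen_document(spec, g$ontology)
    base <- annotations_standoff(recognize_terms(doc$text, idx))
    base_keys <- unique(paste(base$start, base$end))
    for (f in unique(doc$term_truth$surface)) {
      sub <- annotations_standoff(
        recognize_terms(doc$text, idx, ignore_list(terms = f)))
      sub_keys <- unique(paste(sub$start, sub$end))
      expect_true(all(sub_keys %in% base_keys))
    }
  }
})

test_that("recognition is deterministic", {
  spec <- fixture_spec(5, n_terms = 10, n_planted_terms = 4)
  g <- gen_ontology(spec)
  doc <- gen_document(spec, g$ontology)
  idx <- build_index(g$ontology)
  expect_identical(recognize_terms(doc$text, idx),
                   recognize_terms(doc$text, idx))
})

test_that("adding an ontology only grows coverage: old spans survive or are subsumed", {
  # with the longest-match rule a second ontology can contribute a longer
  # form that shadows a previous shorter match, so the right invariant is
  # coverage: every earlier span is either still annotated or strictly
  # contained in a longer annotation of the larger index
  for (seed in c(7, 11, 19)) {
    spec <- fixture_spec(seed, n_terms = 10, ambiguity_rate = 0.5,
                         n_planted_terms = 5)
    pair <- gen_ontology_pair(spec)
    doc <- gen_document(spec, list(pair[[1]]$ontology, pair[[2]]$ontology))
    one <- unique(annotations_standoff(
      recognize_terms(doc$text, build_index(pair[[1]]$ontology)))[
        , c("start", "end")])
    both <- unique(annotations_standoff(
      recognize_terms(doc$text, build_index(
        list(pair[[1]]$ontology, pair[[2]]$ontology))))[, c("start", "end")])
    for (i in seq_len(nrow(one))) {
      covered <- any(both$start <= one$start[i] & one$end[i] <= both$end &
                       (both$end - both$start) >= (one$end[i] - one$start[i]))
      expect_true(covered, info = paste("seed", seed, "span", one$start[i]))
    }
    # and candidate sets only grow for spans present in both runs
    kept <- merge(one, both)
    expect_gte(nrow(both), nrow(kept))
  }
})

test_that("resolve_candidate sets the choice and rejects out-of-range indices", {
  a <- ontology(list(ontology_term("HD:0000001", "leukemia")), ncbo_id = "1009")
  b <- ontology(list(ontology_term("FHH:0000077", "leukemia")), ncbo_id = "1126")
  ann <- recognize_terms("leukemia", make_index(a, b))[[1]]
  expect_equal(nrow(ann$candidates), 2L)
  res <- resolve_candidate(ann, 2L)
  expect_equal(res$resolved, 2L)
  expect_equal(res$candidates$ncbo_id[res$resolved], "1126")
  one <- resolve_candidate(recognize_terms("leukemia", make_index(a))[[1]], 1L)
  expect_equal(one$resolved, 1L)
  expect_error(resolve_candidate(ann, 5L), "out of range")
})

test_that("custom term assignment keeps the manuscript wording", {
  ont <- make_leukemia_ontology()
  text <- "we observed hairy T cell leukemia in samples"
  span <- regexpr("hairy T cell leukemia", text, fixed = TRUE)
  s <- as.integer(span) - 1L; e <- s + attr(span, "match.length")
  ann <- apply_custom_term(text, s, e, ont, "HDX:0000200")
  expect_equal(ann$surface, "hairy T cell leukemia")
  expect_equal(ann$candidates$name, "Leukemia, T-Cell, HTLV-II-Associated")
  expect_equal(ann$resolved, 1L)
  expect_error(apply_custom_term(text, s, e, ont, "HDX:9999999"),
               "not found")
  expect_error(apply_custom_term(text, 3L, 3L, ont, "HDX:0000200"),
               "invalid span")
})

test_that("custom assignment over a recognized span equals recognize+resolve", {
  ont <- neuroblast_ontology()
  text <- "the neuroblast divides"
  auto <- resolve_candidate(recognize_terms(text, build_index(ont))[[1]], 1L)
  manual <- apply_custom_term(text, 4L, 14L, ont, "CL:0000031")
  expect_equal(manual$start, auto$start)
  expect_equal(manual$end, auto$end)
  expect_equal(manual$surface, auto$surface)
  expect_equal(manual$candidates$term_id,
               auto$candidates$term_id[auto$resolved])
})

test_that("propagation marks all other occurrences, skipping overlaps", {
  ont <- neuroblast_ontology()
  idx <- build_index(ont)
  text <- "a neuroblast divides; the neuroblast migrates; a neuroblast dies"
  anns <- recognize_terms(text, idx)
  expect_length(anns, 3L)
  res <- resolve_candidate(anns[[1]], 1L)
  out <- propagate_markup(text, res, existing = list())
  expect_length(out, 3L)
  expect_true(all(vapply(out, function(a) a$resolved == 1L, logical(1))))
  expect_true(all(vapply(out, function(a)
    a$candidates$term_id[a$resolved] == "CL:0000031", logical(1))))

  # an occurrence under an existing span is skipped
  blocker <- anns[[2]]
  out2 <- propagate_markup(text, res, existing = list(blocker))
  starts <- vapply(out2, `[[`, integer(1), "start")
  expect_length(out2, 3L)
  expect_true(blocker$start %in% starts)
  # count check against the raw occurrence scan
  occ <- oracle_scan_terms(text, "neuroblast")
  expect_equal(length(out2),
               sum(!(occ$start == blocker$start)) + 1L)

  # single occurrence: propagation adds nothing
  single <- recognize_terms("one neuroblast only", idx)[[1]]
  single <- resolve_candidate(single, 1L)
  expect_length(propagate_markup("one neuroblast only", single,
                                 existing = list(single)), 1L)
})
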