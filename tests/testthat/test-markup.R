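# build a random marked document programmatically: random text tokens with
# randomly chosen term / ext-link / foreign spans over whole tokens
random_marked_document <- function(seed) {
  set.seed(seed)
  words <- c(fixture_filler_words(), "alpha&beta", "x<y")
  tokens <- sample(words, 30, replace = TRUE)
  lens <- nchar(tokens)
  starts <- cumsum(c(0L, (lens + 1L)[-length(lens)]))
  text <- paste(tokens, collapse = " ")
  picks <- sort(sample(length(tokens), 5))
  spans <- list()
  for (i in seq_along(picks)) {
    j <- picks[i]
    surf <- tokens[j]
    esc <- gsub(">", "&gt;", gsub("<", "&lt;", gsub("&", "&amp;", surf)))
    tag <- switch(1L + (i %% 3L),
      term_tag(ncbo_id = "38436", term_id = sprintf("FX:%07d", j),
               term = paste0("term ", j),
               url = if (i %% 2L) "example.org/view" else NULL,
               surface = surf),
      extlink_tag(href = href_for("pdb", "1MU2"), ext_link_type = "pdb",
                  id_text = surf),
      foreign_tag(raw = paste0("<bold>", esc, "</bold>"), text = surf))
    spans <- c(spans, list(list(start = starts[j], end = starts[j] + lens[j],
                                tag = tag)))
  }
  marked_document(text, spans)
}

test_that("the canonical term element serializes byte-exactly", {
  tag <- term_tag("38436", "CL:0000031", "neuroblast",
                  url = "bioportal.bioontology.org/visualize/39004")
  expect_identical(emit_term_tag(tag), table1_term_element())
})

test_that("the url field is omitted when absent and kept verbatim with a scheme", {
  no_url <- emit_term_tag(term_tag("38436", "CL:0000031", "neuroblast"))
  expect_identical(no_url, sub(";url=[^\"]*", "", table1_term_element()))
  https <- emit_term_tag(term_tag("1", "A:1", "x", url = "https://h/p"))
  expect_match(https, ";url=https://h/p\"", fixed = TRUE)
})

test_that("term emission rejects empty mandatory fields", {
  expect_error(emit_term_tag(term_tag("1", "A:1", "")), "non-empty")
  tag <- term_tag("1", "A:1", "x"); tag$term_id <- ""
  expect_error(emit_term_tag(tag), "non-empty")
})

test_that("term text with XML specials escapes on emit and round-trips", {
  tag <- term_tag("1", "A:1", "AT&T <cells>", surface = "AT&T <cells>")
  s <- emit_term_tag(tag)
  expect_false(grepl("<cells>", s, fixed = TRUE))
  doc <- parse_markup(s)
  expect_equal(doc$text, "AT&T <cells>")
  expect_equal(doc$spans[[1]]$tag$term, "AT&T <cells>")
})

test_that("the canonical ext-link element serializes byte-exactly", {
  tag <- extlink_tag(href_for("pdb", "1MU2"), "pdb", "1MU2")
  expect_identical(emit_dbid_tag(tag), table1_extlink_element())
})

test_that("ext-link emission validates fields and round-trips", {
  expect_error(emit_dbid_tag(extlink_tag("", "pdb", "1MU2")), "non-empty")
  expect_error(emit_dbid_tag(extlink_tag("http://x", "pdb", "")), "non-empty")
  tag <- extlink_tag("http://x?a=1&b=2", "refseq", "NM_000546")
  doc <- parse_markup(emit_dbid_tag(tag))
  expect_equal(doc$spans[[1]]$tag, tag)
})

test_that("injection around a recognized term reproduces the canonical element", {
  ont <- neuroblast_ontology()
  anns <- recognize_terms("the neuroblast divides", build_index(ont))
  doc <- inject_markup("the neuroblast divides",
                       resolved_terms = list(resolve_candidate(anns[[1]], 1L)))
  expect_identical(
    serialize_markup(doc),
    paste0("the ", table1_term_element(), " divides"))
})

test_that("injecting nothing is the identity on plain text", {
  doc <- inject_markup("no markup here")
  expect_identical(serialize_markup(doc), "no markup here")
  expect_length(parse_markup("no markup here")$spans, 0L)
})

test_that("a new span overlapping a foreign tag is rejected and reported", {
  text <- "the neuroblast divides"
  foreign <- marked_document(text, list(list(
    start = 4L, end = 14L, tag = foreign_tag("<bold>neuroblast</bold>",
                                             "neuroblast"))))
  ann <- resolve_candidate(
    recognize_terms(text, build_index(neuroblast_ontology()))[[1]], 1L)
  ok_ann <- apply_custom_term(text, 15L, 22L, neuroblast_ontology(),
                              "CL:0000031")
  expect_warning(
    doc <- inject_markup(text, list(ann, ok_ann), existing = foreign),
    "overlapping")
  rej <- attr(doc, "rejected")
  expect_equal(nrow(rej), 1L)
  expect_equal(rej$start, 4L)
  # the other span was injected, the foreign span kept
  expect_length(doc$spans, 2L)
})

test_that("overlapping new spans are an error", {
  text <- "abcdef ghij"
  ont <- neuroblast_ontology()
  a1 <- apply_custom_term(text, 0L, 6L, ont, "CL:0000031")
  a2 <- apply_custom_term(text, 3L, 10L, ont, "CL:0000031")
  expect_error(inject_markup(text, list(a1, a2)), "overlapping new spans")
})

test_that("unresolved annotations are refused by injection", {
  anns <- recognize_terms("the neuroblast divides",
                          build_index(neuroblast_ontology()))
  expect_error(inject_markup("the neuroblast divides", anns), "unresolved")
})

test_that("the canonical element embedded in a sentence parses to its fields", {
  s <- paste0("As shown, the ", table1_term_element(), " divides.")
  doc <- parse_markup(s)
  expect_equal(doc$text, "As shown, the neuroblast divides.")
  expect_length(doc$spans, 1L)
  tag <- doc$spans[[1]]$tag
  expect_s3_class(tag, "term_tag")
  expect_equal(tag$ncbo_id, "38436")
  expect_equal(tag$term_id, "CL:0000031")
  expect_equal(tag$term, "neuroblast")
  expect_equal(tag$url, "bioportal.bioontology.org/visualize/39004")
  expect_equal(doc$spans[[1]]$start, 14L)
  expect_equal(doc$spans[[1]]$end, 24L)
})

test_that("id-attribute fields are accepted in any order but emitted canonically", {
  shuffled <- paste0('<named-content content-type="biolit" ',
                     'id="term=neuroblast;ncbo_id=38436;term_id=CL:0000031;',
                     'url=http://bioportal.bioontology.org/visualize/39004">',
                     'neuroblast</named-content>')
  doc <- parse_markup(shuffled)
  expect_s3_class(doc$spans[[1]]$tag, "term_tag")
  expect_identical(serialize_markup(doc), table1_term_element())
})

test_that("a malformed biolit id demotes the element to a foreign tag", {
  bad <- '<named-content content-type="biolit" id="nonsense">x</named-content>'
  expect_warning(doc <- parse_markup(bad), "malformed biolit id")
  expect_s3_class(doc$spans[[1]]$tag, "foreign_tag")
  expect_identical(serialize_markup(doc), bad)
})

test_that("ill-formed XML is a parse error", {
  expect_error(parse_markup("a <b>unclosed"), class = "error")
})

test_that("parse/serialize round-trips and text conservation hold on random documents", {
  for (seed in 1:25) {
    doc <- random_marked_document(seed)
    s <- serialize_markup(doc)
    back <- parse_markup(s)
    expect_identical(back$text, doc$text, info = paste("seed", seed))
    expect_identical(serialize_markup(back), s, info = paste("seed", seed))
    expect_identical(strip_markup(s), doc$text, info = paste("seed", seed))
    # foreign bytes preserved verbatim
    for (sp in doc$spans) {
      if (inherits(sp$tag, "foreign_tag"))
        expect_true(grepl(sp$tag$raw, s, fixed = TRUE))
    }
  }
})

test_that("injection is order-independent", {
  text <- "the neuroblast divides near 1MU2 structures"
  ont <- neuroblast_ontology()
  ann <- resolve_candidate(recognize_terms(text, build_index(ont))[[1]], 1L)
  id <- resolve_db_match(recognize_ids(text)[[1]], "pdb")
  d1 <- inject_markup(text, list(ann), list(id))
  d2 <- inject_markup(text, list(ann), list(id))  # same inputs
  expect_identical(serialize_markup(d1), serialize_markup(d2))
  # spans handed over in a different order give the same document
  ann2 <- apply_custom_term(text, 33L, 43L, ont, "CL:0000031")
  da <- inject_markup(text, list(ann, ann2), list(id))
  db <- inject_markup(text, list(ann2, ann), list(id))
  expect_identical(serialize_markup(da), serialize_markup(db))
})

test_that("standoff export reports one row per span with 0-based offsets", {
  text <- "the neuroblast divides near 1MU2 structures"
  ont <- neuroblast_ontology()
  ann <- resolve_candidate(recognize_terms(text, build_index(ont))[[1]], 1L)
  id <- resolve_db_match(recognize_ids(text)[[1]], "pdb")
  doc <- inject_markup(text, list(ann), list(id))
  so <- markup_standoff(doc, doc_id = "d1")
  expect_equal(nrow(so), 2L)
  expect_equal(so$surface[1], "neuroblast")
  expect_equal(so$start[1], 4L)
  expect_equal(so$ncbo_id[2], "db:pdb")
  expect_equal(so$term_id[2], "1MU2")
})
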