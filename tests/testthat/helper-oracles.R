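# Independent oracles used across the suite.  These deliberately avoid the
# package's matching machinery: the term oracle is a character-level sliding
# scan, the id oracle evaluates independently transcribed patterns anchored
# per token, the OBO oracle counts raw lines.

# ---- OBO line-scanning oracle -------------------------------------------

oracle_obo_counts <- function(obo_text) {
  lines <- strsplit(obo_text, "\n", fixed = TRUE)[[1]]
  in_term <- FALSE
  n_terms <- 0L; n_syn <- 0L; n_isa <- 0L
  for (line in lines) {
    t <- trimws(line)
    if (grepl("^\\[", t)) { in_term <- identical(t, "[Term]"); next }
    if (!in_term) next
    if (grepl("^id:", t)) n_terms <- n_terms + 1L
    if (grepl("^synonym:", t)) n_syn <- n_syn + 1L
    if (grepl("^is_a:", t)) n_isa <- n_isa + 1L
  }
  list(terms = n_terms, synonyms = n_syn, is_a = n_isa)
}

# ---- term recognition oracle --------------------------------------------

# all boundary-aligned occurrences of the normalized forms, found by a
# naive character-level scan; returns data.frame(start, end, form) with
# 0-based half-open offsets
oracle_scan_terms <- function(text, forms) {
  n <- nchar(text)
  lower <- tolower(text)
  chars <- strsplit(text, "")[[1]]
  is_alnum <- grepl("[[:alnum:]]", chars)
  is_ws <- chars %in% c(" ", "\t", "\r", "\n")
  res_s <- integer(); res_e <- integer(); res_f <- character()
  for (form in forms) {
    ftoks <- strsplit(form, " ", fixed = TRUE)[[1]]
    for (s in seq_len(n)) {
      pos <- s; ok <- TRUE
      for (ti in seq_along(ftoks)) {
        L <- nchar(ftoks[ti])
        if (pos + L - 1L > n ||
            substr(lower, pos, pos + L - 1L) != ftoks[ti]) { ok <- FALSE; break }
        pos <- pos + L
        if (ti < length(ftoks)) {
          ws <- 0L; nl <- 0L
          while (pos + ws <= n && is_ws[pos + ws]) {
            if (chars[pos + ws] == "\n") nl <- nl + 1L
            ws <- ws + 1L
          }
          if (ws < 1L || nl > 1L) { ok <- FALSE; break }
          pos <- pos + ws
        }
      }
      if (!ok) next
      e <- pos - 1L                       # 1-based inclusive end
      if (s > 1L && is_alnum[s - 1L]) next
      if (e < n && is_alnum[e + 1L]) next
      res_s <- c(res_s, s - 1L); res_e <- c(res_e, e)
      res_f <- c(res_f, form)
    }
  }
  data.frame(start = res_s, end = res_e, form = res_f,
             stringsAsFactors = FALSE)
}

# longest-match-wins / leftmost-tie-break selection, re-stated simply
oracle_select <- function(occ) {
  if (!nrow(occ)) return(occ[order(occ$start), , drop = FALSE])
  occ <- occ[order(-(occ$end - occ$start), occ$start), , drop = FALSE]
  kept <- occ[0, , drop = FALSE]
  for (i in seq_len(nrow(occ))) {
    if (!any(occ$start[i] < kept$end & kept$start < occ$end[i]))
      kept <- rbind(kept, occ[i, , drop = FALSE])
  }
  kept[order(kept$start), , drop = FALSE]
}

oracle_recognize_terms <- function(text, forms) {
  oracle_select(oracle_scan_terms(text, forms))
}

# ---- database identifier oracle -----------------------------------------

# independently transcribed accession patterns
oracle_id_patterns <- function() {
  data.frame(
    database = c("pdb", "uniprotkb", "uniprotkb", "genbank", "genbank",
                 "genbank", "refseq"),
    pattern = c("[1-9][A-Z][A-Z0-9]{2}",
                "[A-Z][0-9][A-Z][0-9A-Z]{2}[0-9]",
                "[AOPQ][0-9][0-9A-Z]{3}[0-9]",
                "[ABCDEFGHIJKLMNSTUVWXYZ][0-9]{5}",
                "[ABCDEFGHIJKLMNSTUVWXYZ][A-Z][0-9]{6}",
                "[ABCDEFG]A[AE][0-9]{5}",
                "[ANXYZ][CPMRWZS]_[0-9]{6,}"),
    stringsAsFactors = FALSE)
}

# per-token direct evaluation: a pattern hits a token iff it matches at the
# token start and the first unmatched character (if any) is not
# alphanumeric.  Returns data.frame(token, database, len), one row per
# (token index, pattern row) hit.
oracle_id_token_matches <- function(tokens) {
  pats <- oracle_id_patterns()
  out <- vector("list", nrow(pats))
  for (i in seq_len(nrow(pats))) {
    m <- regexpr(paste0("^(?:", pats$pattern[i], ")"), tokens, perl = TRUE)
    len <- attr(m, "match.length")
    hit <- m == 1L
    if (any(hit)) {
      nxt <- substr(tokens[hit], len[hit] + 1L, len[hit] + 1L)
      good <- nxt == "" | !grepl("[A-Za-z0-9]", nxt)
      idx <- which(hit)[good]
      out[[i]] <- data.frame(token = idx, database = pats$database[i],
                             len = len[hit][good], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(token = integer(), database = character(),
                      len = integer(), stringsAsFactors = FALSE)
  unique(res[order(res$token, res$database, res$len), , drop = FALSE])
}

# run recognize_ids over tokens embedded in one space-separated text and
# map matches back to token indices; returns the same shape as the oracle
implementation_id_token_matches <- function(tokens) {
  text <- paste(tokens, collapse = " ")
  lens <- nchar(tokens)
  starts <- cumsum(c(0L, (lens + 1L)[-length(lens)]))
  ms <- recognize_ids(text)
  if (!length(ms))
    return(data.frame(token = integer(), database = character(),
                      len = integer(), stringsAsFactors = FALSE))
  tok <- match(vapply(ms, `[[`, integer(1), "start"), starts)
  stopifnot(!anyNA(tok))                   # matches must start at a token
  ncand <- vapply(ms, function(m) length(m$candidates), integer(1))
  res <- unique(data.frame(
    token = rep(tok, ncand),
    database = unlist(lapply(ms, `[[`, "candidates")),
    len = rep(vapply(ms, function(m) m$end - m$start, integer(1)), ncand),
    stringsAsFactors = FALSE))
  res[order(res$token, res$database, res$len), , drop = FALSE]
}

# ---- shared fixtures ------------------------------------------------------

# synthetic stand-in mirroring a disease-ontology neighbourhood: a "hairy
# cell leukemia" parent with 13 child leukemias, one of which is the
# HTLV-II-associated term with its printed synonym
make_leukemia_ontology <- function() {
  kids <- lapply(1:12, function(i)
    ontology_term(sprintf("HDX:%07d", 100 + i),
                  paste("distinct leukemia", i),
                  parents = "HDX:0000001"))
  htlv <- ontology_term(
    "HDX:0000200", "Leukemia, T-Cell, HTLV-II-Associated",
    synonyms = c(EXACT = "Atypical hairy cell leukemia (disorder)"),
    parents = "HDX:0000001")
  parent <- ontology_term("HDX:0000001", "Hairy cell leukemia")
  ontology(c(list(parent), kids, list(htlv)),
           ncbo_id = "99001", label = "synthetic disease fixture")
}

neuroblast_ontology <- function() {
  parse_obo(text = c("format-version: 1.2", "", "[Term]",
                     "id: CL:0000031", "name: neuroblast",
                     'synonym: "neuroblast (sensu Nematoda and Protostomia)" NARROW []'),
            ncbo_id = "38436", label = "cell fixture",
            url_template = "bioportal.bioontology.org/visualize/39004")
}

table1_term_element <- function() {
  paste0('<named-content content-type="biolit" ',
         'id="ncbo_id=38436;term_id=CL:0000031;term=neuroblast;',
         'url=http://bioportal.bioontology.org/visualize/39004">',
         'neuroblast</named-content>')
}

table1_extlink_element <- function() {
  paste0('<ext-link xlink:href="http://www.rcsb.org/pdb/explore/',
         'explore.do?structureId=1MU2" ext-link-type="pdb">1MU2</ext-link>')
}
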