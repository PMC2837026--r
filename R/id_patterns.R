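#' Built-in database identifier patterns
#'
#' The seven accession patterns for the Protein Data Bank, UniProtKB and
#' the NCBI databases (GenBank, RefSeq), as used for pattern-matched ID
#' recognition.  Two transcription details are deliberate: the PDB
#' pattern is `[1-9][A-Z][A-Z0-9]{2}` (a PDB code such as 1MU2: digit,
#' letter, two alphanumerics), and pipe-delimited character classes like
#' `[A|O|P|Q]` are read as the plain letter sets — no real accession
#' begins with a literal `|`.  Matching is uppercase-only; accessions are
#' case-sensitive.
#'
#' @param enabled database labels to include; subset of
#'   `c("pdb", "uniprotkb", "genbank", "refseq")`.
#' @return data frame with columns `database`, `pattern`.
#' @examples
#' db_patterns()
#' @export
db_patterns <- function(enabled = c("pdb", "uniprotkb", "genbank", "refseq")) {
  enabled <- match_db_labels(enabled)
  pat <- data.frame(
    database = c("pdb",
                 "uniprotkb", "uniprotkb",
                 "genbank", "genbank", "genbank",
                 "refseq"),
    pattern = c(
      "[1-9][A-Z][A-Z0-9]{2}",                 # PDB structure code
      "[A-Z][0-9][A-Z][0-9A-Z]{2}[0-9]",       # UniProtKB accession
      "[AOPQ][0-9][0-9A-Z]{3}[0-9]",           # UniProtKB accession (2nd form)
      "[A-NS-Z][0-9]{5}",                      # GenBank 1 letter + 5 digits
      "[A-NS-Z][A-Z][0-9]{6}",                 # GenBank 2 letters + 6 digits
      "[A-G]A[AE][0-9]{5}",                    # GenBank WGS-style
      "[ANXYZ][CPMRWZS]_[0-9]{6,}"             # RefSeq accession
    ),
    stringsAsFactors = FALSE
  )
  pat[pat$database %in% enabled, , drop = FALSE]
}

db_label_order <- c("pdb", "uniprotkb", "genbank", "refseq")

match_db_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(labels, db_label_order)
  if (length(bad))
    stop("unknown database label(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(db_label_order, collapse = ", "),
         call. = FALSE)
  labels
}

# default link templates; the PDB template is the canonical structure
# explorer URL, the others are sensible, configurable defaults
default_href_templates <- function() {
  c(pdb = "http://www.rcsb.org/pdb/explore/explore.do?structureId=%s",
    uniprotkb = "http://www.uniprot.org/uniprot/%s",
    genbank = "http://www.ncbi.nlm.nih.gov/nuccore/%s",
    refseq = "http://www.ncbi.nlm.nih.gov/nuccore/%s")
}

#' Database link URL for an identifier
#'
#' @param database_label one of `"pdb"`, `"uniprotkb"`, `"genbank"`,
#'   `"refseq"`.
#' @param id_text the accession; must be non-empty.
#' @param templates named character vector of `sprintf` templates with one
#'   `%s` slot; defaults ship the canonical PDB explorer URL.
#' @return The URL string.
#' @examples
#' href_for("pdb", "1MU2")
#' @export
href_for <- function(database_label, id_text,
                     templates = default_href_templates()) {
  if (length(database_label) != 1L || !database_label %in% names(templates))
    stop("unknown database label: ", paste(database_label, collapse = ","),
         call. = FALSE)
  if (length(id_text) != 1L || is.na(id_text) || !nzchar(id_text))
    stop("id_text must be a non-empty string", call. = FALSE)
  sprintf(templates[[database_label]], id_text)
}

#' Construct a database identifier match
#'
#' @param start,end 0-based half-open character offsets.
#' @param id_text matched identifier string.
#' @param candidates character vector of database labels (at least one).
#' @param resolved resolved database label or `NA`.
#' @param href link URL; set iff resolved.
#' @return An object of class `"db_id_match"`.
#' @export
db_id_match <- function(start, end, id_text, candidates,
                        resolved = NA_character_, href = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop("invalid span [", start, ",", end, ")", call. = FALSE)
  candidates <- match_db_labels(candidates)
  if (!length(candidates)) stop("candidates must be non-empty", call. = FALSE)
  if (!is.na(resolved) && !resolved %in% candidates)
    stop("resolved label '", resolved, "' is not a candidate", call. = FALSE)
  if (is.na(resolved) != is.na(href))
    stop("href must be set iff resolved is set", call. = FALSE)
  structure(list(start = start, end = end, id_text = as.character(id_text),
                 candidates = candidates, resolved = resolved, href = href),
            class = "db_id_match")
}

#' @export
print.db_id_match <- function(x, ...) {
  cat("<db_id_match> [", x$start, ",", x$end, ") \"", x$id_text, "\" {",
      paste(x$candidates, collapse = ","), "}", sep = "")
  if (!is.na(x$resolved)) cat(" -> ", x$resolved, sep = "")
  cat("\n")
  invisible(x)
}

#' Recognize database identifiers in text
#'
#' Scans for the enabled accession patterns.  Identifiers are expected to
#' be preceded by a space: a match must start at the beginning of the
#' text or after whitespace, and must end at the end of the text or
#' before a non-alphanumeric character, so `"in1MU2x"` matches nothing.
#' A span matched by the patterns of several databases yields one match
#' carrying all candidate labels.
#'
#' @param text document text (single string).
#' @param enabled database labels to scan for.
#' @param patterns pattern table, by default [db_patterns()]; overridable
#'   for custom pattern sets.
#' @return List of [db_id_match()] objects sorted by `start` (then end).
#' @examples
#' recognize_ids(" 1MU2 ")[[1]]$id_text
#' sapply(recognize_ids(" A12345 "), function(m) m$candidates)
#' @export
recognize_ids <- function(text,
                          enabled = c("pdb", "uniprotkb", "genbank", "refseq"),
                          patterns = db_patterns()) {
  stopifnot(length(text) == 1L)
  enabled <- match_db_labels(enabled)
  pat <- patterns[patterns$database %in% enabled, , drop = FALSE]
  if (!nzchar(text) || !nrow(pat)) return(list())
  starts <- integer(); ends <- integer(); dbs <- character()
  txts <- character()
  for (i in seq_len(nrow(pat))) {
    rx <- paste0("(?<!\\S)(?:", pat$pattern[i], ")(?![A-Za-z0-9])")
    m <- gregexpr(rx, text, perl = TRUE)
    if (m[[1]][1] == -1L) next
    len <- attr(m[[1]], "match.length")
    starts <- c(starts, as.integer(m[[1]]) - 1L)
    ends <- c(ends, as.integer(m[[1]]) - 1L + len)
    dbs <- c(dbs, rep(pat$database[i], length(m[[1]])))
    txts <- c(txts, regmatches(text, m)[[1]])
  }
  if (!length(starts)) return(list())
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]
  dbs <- dbs[ord]; txts <- txts[ord]
  # group identical spans (one match, k candidate databases)
  n <- length(starts)
  grp <- cumsum(c(TRUE, starts[-1L] != starts[-n] | ends[-1L] != ends[-n]))
  first <- which(!duplicated(grp))
  cand_by_grp <- unname(split(dbs, grp))
  lapply(seq_along(first), function(g) {
    cand <- db_label_order[db_label_order %in% cand_by_grp[[g]]]
    db_id_match(starts[first[g]], ends[first[g]], txts[first[g]], cand)
  })
}

#' Resolve a database identifier match
#'
#' @param match a [db_id_match()].
#' @param database_label the chosen candidate label.
#' @param templates link templates passed to [href_for()].
#' @return The match with `resolved` and `href` set.
#' @export
resolve_db_match <- function(match, database_label,
                             templates = default_href_templates()) {
  stopifnot(inherits(match, "db_id_match"))
  if (!database_label %in% match$candidates)
    stop("'", database_label, "' is not a candidate for \"", match$id_text,
         "\" (candidates: ", paste(match$candidates, collapse = ", "), ")",
         call. = FALSE)
  match$resolved <- database_label
  match$href <- href_for(database_label, match$id_text, templates)
  match
}
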