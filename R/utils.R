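# internal helpers shared across modules

# escape a literal string for use inside a PCRE pattern
rx_escape <- function(x) gsub("([][{}()*+?.\\^$|\\\\-])", "\\\\\\1", x)

# XML escaping for text content and (optionally) attribute values
xml_escape <- function(x, attribute = FALSE) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  if (attribute) x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# do half-open [s1,e1) and [s2,e2) intervals (0-based) overlap?
spans_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# extract a 0-based half-open span from text (1-based substr internally)
span_text <- function(text, start, end) substr(text, start + 1L, end)

# run code with a private RNG stream so generators are pure functions of
# their seed and never disturb the caller's .Random.seed
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
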