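#' Surface-form normalization policy
#'
#' Term recognition compares document text and dictionary entries after
#' normalization.  The default policy folds case and collapses internal
#' whitespace runs to a single space, which maximizes recall for ontology
#' labels that differ from manuscript usage only in capitalization or
#' line-wrapping.  Database identifiers are never normalized (accessions
#' are case-sensitive as printed).
#'
#' @param case_insensitive fold case before comparison? Default `TRUE`.
#' @param collapse_whitespace collapse internal whitespace runs (including
#'   a single line break) to one space? Default `TRUE`.
#' @return An object of class `"norm_policy"`.
#' @examples
#' normalize_surface("Hairy  Cell\nLeukemia", norm_policy())
#' @export
norm_policy <- function(case_insensitive = TRUE, collapse_whitespace = TRUE) {
  structure(
    list(case_insensitive = isTRUE(case_insensitive),
         collapse_whitespace = isTRUE(collapse_whitespace)),
    class = "norm_policy"
  )
}

#' @export
print.norm_policy <- function(x, ...) {
  cat("<norm_policy> case_insensitive=", x$case_insensitive,
      " collapse_whitespace=", x$collapse_whitespace, "\n", sep = "")
  invisible(x)
}

#' Normalize a surface form under a policy
#'
#' @param x character vector of surface forms.
#' @param policy a [norm_policy()].
#' @return character vector of normalized forms.
#' @export
normalize_surface <- function(x, policy = norm_policy()) {
  stopifnot(inherits(policy, "norm_policy"))
  out <- as.character(x)
  if (policy$collapse_whitespace) {
    out <- gsub("[[:space:]]+", " ", out)
    out <- trimws(out)
  }
  if (policy$case_insensitive) out <- tolower(out)
  out
}
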