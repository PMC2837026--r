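# biolitmark

Inline semantic mark-up of biomedical text: dictionary-based recognition
of ontology terms and pattern-based recognition of biological database
accessions, embedded as NLM/JATS inline XML.

## Who this is for

Authors, curators and publishing pipelines that want machine-readable
semantics *inside* the manuscript text rather than in a separate
database: every recognized concept becomes a JATS `named-content`
element carrying the ontology registry id, the term CURIE, the preferred
name and a browse URL; every recognized accession becomes an `ext-link`
with a resolvable `xlink:href`. The mark-up coexists with, and
preserves, XML added by other tools.

## The method in brief

* **Terms.** All preferred names and synonyms of the active OBO
  ontologies are indexed after normalization (case-folding, whitespace
  collapsing). Occurrences must be token-boundary aligned (so
  `leukemia` is not found inside `leukemias`); overlapping occurrences
  resolve longest-match-first, leftmost on ties, because inline tags may
  not overlap. A form found in several ontologies carries all candidate
  terms; exactly one candidate must be chosen (a decisions file,
  programmatic choice, or the opt-in `auto_single` rule) before mark-up
  is emitted. Terms the dictionary misses can be applied manually to any
  span while keeping the manuscript wording.
* **Identifiers.** PDB, UniProtKB, GenBank and RefSeq accessions are
  matched by seven fixed regular expressions (e.g. PDB
  `[1-9][A-Z][A-Z0-9]{2}`, RefSeq `[ANXYZ][CPMRWZS]_[0-9]{6,}`).
  An identifier must be preceded by whitespace and end at a
  non-alphanumeric boundary, so `in1MU2x` matches nothing. A token
  matching several databases (e.g. `A12345`) carries all candidate
  labels.
* **Mark-up.** Injection, parsing and serialization round-trip exactly:
  tag-stripped output equals the input text character for character,
  foreign tags are preserved verbatim, and re-running the pipeline on
  its own output adds nothing.

## Worked example

```r
library(biolitmark)

obo <- tempfile(fileext = ".obo")
writeLines(c("format-version: 1.2", "",
             "[Term]", "id: CL:0000031", "name: neuroblast"), obo)

cfg <- run_config(
  ontologies = list(list(
    obo_path = obo, ncbo_id = "38436", label = "Cell Ontology",
    url_template = "bioportal.bioontology.org/visualize/39004")),
  auto_single = TRUE)

run <- run_pipeline("the neuroblast divides near 1MU2", cfg,
                    from_text = TRUE)
cat(run$serialized)
#> the <named-content content-type="biolit"
#> id="ncbo_id=38436;term_id=CL:0000031;term=neuroblast;url=http://bioportal.bioontology.org/visualize/39004">neuroblast</named-content>
#> divides near <ext-link
#> xlink:href="http://www.rcsb.org/pdb/explore/explore.do?structureId=1MU2"
#> ext-link-type="pdb">1MU2</ext-link>

print(run$report)
#> <pipeline_report> doc
#>   terms: recognized=1 resolved=1 ignored=0 unresolved=0
#>   ids:   recognized=1 resolved=1 ignored=0 unresolved=0
#>   existing spans: 0; rejected overlaps: 0
```

(The serialized output is a single line; it is wrapped here for
readability.) The report reads: one ontology term and one PDB accession
were recognized, both had a single candidate and were auto-resolved, and
nothing was ignored, left ambiguous, or rejected for overlapping
existing mark-up. Re-running `run_pipeline` on `run$serialized` returns
it unchanged.

Other entry points: `parse_obo()` / `validate_ontology()` for OBO files,
`search_terms()` / `path_to_root()` / `children()` for hierarchy
navigation, `recognize_terms()` / `recognize_ids()` for standoff
annotation without injection, `gen_fixtures()` for seeded synthetic test
data, and `inst/cli/biolit.R` for a shell front end
(`annotate`, `search`, `tree`, `validate-obo`, `gen-fixtures`).

See `vignettes/biolit-markup.Rmd` for the method, its design decisions
and its limitations.

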