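# sonq — spreadsheet-specified search ontologies and an extended boolean query engine

`sonq` is an R toolkit for teams who must screen literature and incident
reports systematically — the motivating use case is post-market
surveillance (PMS) of medical devices, where complex search queries have
to be maintained for every device, material and risk under observation.
Writing such queries by hand requires knowing each engine's syntax and is
error-prone; `sonq` lets domain experts specify *what* to search for in a
spreadsheet and generates the queries mechanically.

The package implements three connected pieces:

1. **A search-ontology model.** A domain-specific search ontology (dSON)
   arranges *search concepts* into facets (e.g. `Material`,
   `Medical_Device`, `Incident`). Each concept carries *simple terms* —
   single words (`clip`, `Nitinol`) or fixed phrases (`endoscopic
   clipping system`), optionally boosted (`incident^5`) or wildcarded.
   *Negated concepts* list terms that must **not** occur. A *composite
   term* combines two concepts: the AND-connection of their OR-linked
   simple terms,

   ```
   (unexpected OR unforeseeable OR unknown) AND (complication OR failure OR incident)
   ```

   A *single concept query* is the OR-connection of all of a concept's
   terms (negated: `NOT (…)`), and a *multiple concept query* is the
   AND-connection of selected single concept queries.

2. **Compilers.** The dSON is read from an Excel template (facet sheets
   plus the reserved sheets `Negated_Concept`, `Composite_Term`,
   `Multiple_Concept_Query`) and serialized to OWL (RDF/XML; a base
   vocabulary of 9 classes and 13 annotation properties, with the domain
   classes beneath it) and to JSON for downstream apps. Both directions
   round-trip, and external label ontologies can be imported as facets.

3. **A reference query engine** for the extended Lucene-style syntax the
   generator emits: `AND`/`OR`/`NOT`, proximity operators `NEAR/n`
   (token distance ≤ n), `NEAR/S` (same sentence), `NEAR/P` (same
   paragraph), term-type modes `MODE/E|D|B|C` (exact surface /
   diacritics-normalized / lemmatized baseform / compound parts, via a
   pluggable lexicon), boosts and wildcards — evaluated with span
   semantics over tokenized plain-text documents.

## Worked example

The bundled fixture rebuilds the dSON-Niti example — screening for
unexpected side effects of the nickel-titanium alloy Nitinol in
endoscopic clipping systems, excluding preclinical work:

```r
library(sonq)

path <- build_niti_workbook(file.path(tempdir(), "dSON_Niti.xlsx"))
d <- generate_all(read_template(path), generation_options("en"))
d
#> dSON 'dSON_Niti' <http://example.org/dson/dSON_Niti#>
#>   facets:           3 (Material, Medical_Device, Incident)
#>   search concepts:  11 standard, 1 negated
#>   composite terms:  1
#>   multiple queries: 1

d$composite_terms[[1]]$query$en
#> (unexpected OR unforeseeable OR unknown) AND (complication OR failure OR incident)

d$multiple_queries[[1]]$query$en
#> (((unexpected OR unforeseeable OR unknown) AND (complication OR failure OR incident)))
#>   AND (Nitinol OR "Nickel Titanium" OR NiTi) AND ("endoscopic clipping system")
#>   AND NOT (animal OR study OR preclinical)
```

Running that query over a small corpus matches exactly the document that
mentions an unexpected complication, the material and the device — and
rejects the one that also mentions a preclinical animal study:

```r
ast <- parse_query(d$multiple_queries[[1]]$query$en)
corpus <- lapply(c(
  "An unexpected complication was reported for a Nitinol endoscopic clipping system.",
  "A preclinical study: unexpected complication of a Nitinol endoscopic clipping system in animal models.",
  "Routine use of a titanium stent."), tokenize)
search_corpus(ast, corpus)[, c("doc_index", "score")]
#>   doc_index score
#> 1         1     4
```

The score 4 is the boost-sum of the four distinct matched term
occurrences (`unexpected`, `complication`, `Nitinol`, the device
phrase), each with the default boost 1.

Export and per-shell usage:

```r
xml2::write_xml(to_owl(d), "dSON_Niti.owl")
writeLines(to_json(d), "dSON_Niti.json")
```

```sh
Rscript inst/cli/sonq.R generate -i dSON_Niti.xlsx -o out/ --lang en
Rscript inst/cli/sonq.R search --query-name Niti_Query --corpus docs/ -i out/dSON_Niti.owl
```

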