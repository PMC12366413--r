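# taxrecon

Taxonomic name reconciliation against a **local copy of the NCBI
taxonomy**, for people who clean species lists: ecologists merging survey
data, database curators reconciling host–pathogen tables, anyone whose
input column says `European chub` in one file, `Leuciscus cephalus` in
another, and `Squalius cephalus` in a third — all the same fish.

Matching a free-text name to a taxonomic backbone fails in predictable
ways: **synonyms** (several valid names, one taxon), **homonyms** (one
name, several taxa — the genus *Io* is both an aster and a gastropod),
**vernaculars** (lamb/sheep/wild sheep/domestic sheep are all *Ovis
aries*), **typos** (most names are typed by hand at some point), and
**nomenclatural churn** (merged and deleted identifiers). taxrecon
addresses each one explicitly, and — because it is meant for unattended
pipeline runs on clusters — it *never prompts*: a resolution either
returns a taxon or a **typed failure value** (`NO_DIRECT_MATCH` /
`MULTIPLE_MATCHES`) that carries the candidate list.

## What it computes

* **Staged matching.** An exact lookup of the normalized query (Unicode
  NFC, whitespace collapsed, ligatures `œ`→`oe`/`æ`→`ae` expanded;
  optionally case-folded) runs first; only if it finds nothing and
  `strict = FALSE` does a fuzzy scan run, keeping every candidate at the
  minimal Levenshtein distance `d ≤ max_distance` (default 2). Matches
  can be restricted by rank, by NCBI division pools
  (`mammal_pool(store, inclusive = TRUE)` = Mammals ∪ Primates ∪
  Rodents), or by an arbitrary subtree.
* **Lineage navigation.** `tax_parent`, `tax_children`,
  `tax_descendants`, `tax_lineage`, `tax_lca`.
* **Taxonomic distance.** For a species list, the pairwise distance is
  the score of the most specific shared ancestor with a scored rank,
  under the standard taxonomic-distinctness weights
  `species = 0, genus = 1, family = 2, subclass = 3`, everything
  else 4 — a coarse proxy for phylogenetic distance when no tree is
  available. Any NCBI rank can be re-scored.

## Worked example

```r
library(taxrecon)

dir <- tempfile()
write_taxdump(fixture_taxonomy(), dir)   # or point load_taxdump at a real dump
store <- load_taxdump(dir)

survey <- c("European chub", "Cyprinus cephalus",
            "Leuciscus cephalus", "Squalius cephalus")
rec <- reconcile_names(store, survey)
rec[, c("query", "status", "matched_name", "tax_id")]
#>                query status      matched_name   tax_id
#> 1      European chub     ok Squalius cephalus 10000131
#> 2  Cyprinus cephalus     ok Squalius cephalus 10000131
#> 3 Leuciscus cephalus     ok Squalius cephalus 10000131
#> 4  Squalius cephalus     ok Squalius cephalus 10000131
length(unique(rec$tax_id[rec$status == "ok"]))
#> [1] 1
```

Four user-supplied names; a naive richness estimate says 4 species, the
reconciled estimate says 1 — which is the truth.

```r
resolve_name(store, "Boops bops", strict = FALSE)  # typo, 1 edit away
#> Boops boops (tax_id 36219, rank species)

resolve_name(store, "Io")
#> <MULTIPLE_MATCHES> 'Io' matches 2 distinct taxa; alternative_taxa() lists them
#>   - Io [10000301] (scientific name, distance 0)
#>   - Io [10000311] (scientific name, distance 0)
resolve_name(store, "Io", pool = plant_pool(store))
#> Io (tax_id 10000301, rank genus)

taxonomic_distance(store, list(resolve_name(store, "Squalius cephalus"),
                               resolve_name(store, "Squalius squalus"),
                               resolve_name(store, "Bos taurus")))
#>                   Squalius cephalus Squalius squalus Bos taurus
#> Squalius cephalus                 0                1          4
#> Squalius squalus                  1                0          4
#> Bos taurus                        4                4          0
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "taxrecon", package = "taxrecon"))')
Rscript "$CLI" fixtures write --kind demo --out /tmp/dump
Rscript "$CLI" build --db /tmp/taxdb --from-dir /tmp/dump
Rscript "$CLI" get "Boops boops" --db /tmp/taxdb
Rscript "$CLI" reconcile names.txt --db /tmp/taxdb --fuzzy --out report.tsv
```

Exit codes: 0 = all inputs resolved, 1 = at least one unmatched or
ambiguous input, 2 = usage/data error. Logs go to stderr, data to stdout
or `--out`; no command ever reads the terminal.

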