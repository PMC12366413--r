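---
title: "Reconciling biological names against a local NCBI taxonomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling biological names against a local NCBI taxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxrecon)
```

## The problem

A string in a species column is not an identifier. The same taxon may
appear under several valid synonyms, under language-specific vernacular
names, or under a formerly accepted binomial; conversely one string can
validly denote several taxa (homonyms), and on top of all that most
names are at some point typed by hand, with the error rates any manual
data entry has. taxrecon resolves such strings against a locally stored,
versioned copy of the NCBI taxonomy, so that repeated runs of an
analysis see exactly the same backbone — something an online API query
cannot guarantee.

The package is built for unattended pipelines. No operation ever prompts
the user: resolution returns either a `taxon` or a typed failure value
(`NO_DIRECT_MATCH` or `MULTIPLE_MATCHES`, both carrying candidates) that
batch code inspects with `is_match_failure()`.

## The matching model

Resolution is staged, and the stages are ordered by cost and by risk of
a false merge:

1. **Exact lookup** of the normalized query. Normalization is Unicode
   NFC, internal whitespace collapsed, surrounding whitespace trimmed,
   and the ligatures `œ`/`æ` expanded to `oe`/`ae` (these are common
   typographic variants in Latin names, e.g. *Isœtes* for *Isoetes*, and
   a plain lookup should survive them). With `case_sensitive = FALSE`
   the lookup runs on case-folded keys — cheap, and often the right tool
   for virus names carrying alphanumeric codes, where fuzzy matching
   would surface several equally distant neighbours.
2. **Fuzzy scan**, only when the exact stage found nothing and
   `strict = FALSE`. Every name in scope is compared by Levenshtein
   distance on case-folded keys (case errors are treated as typos
   regardless of `case_sensitive`, which governs only the exact stage);
   all candidates at the minimal distance within `max_distance` survive.

At each stage candidates may be filtered by rank, and
`prefer_scientific = TRUE` drops vernacular-style records ("common
name", "genbank common name", "includes", "in-part") and lets any
surviving scientific-name record suppress the rest. Distinct records of
the *same* taxon (a synonym plus the scientific name) are one match;
distinct taxa are never auto-picked — ambiguity is always an explicit
failure, because silently choosing wrong is worse than stopping a
pipeline row.

### Parameters that matter

* `max_distance` (default **2**, integer edit operations). One covers
  the common single-typo case; two also covers short vernacular-to-genus
  accidents while still bounding false merges. Raising it on an
  unrestricted pool is the classic way to fuzzy-match your way into a
  wrong genus (see the pitfall below), so prefer restricting the pool
  over raising the threshold.
* `case_sensitive` (default `TRUE`) — exact stage only; fold it off for
  coded names (viruses, strains).
* Pools: `division_pool()` and friends materialize an id-set once, so
  repeated fuzzy scans pay for the restriction a single time. The fuzzy
  comparison count equals the pool's name count exactly
  (`last_comparison_count()`), which is both the speed argument and the
  disambiguation argument: a homonym that is ambiguous on the full store
  is unique inside the right division.

### The pitfall the pool solves

A fuzzy search for `"Lizard"` over the whole store lands on the
hemipteran genus *Lisarda* (2 edits) long before the reptile class
*Lepidosauria* (8 edits) — edit distance knows nothing about taxonomy.
Restricting the pool to the group you know you are working in avoids
precisely this class of error.

```{r}
dir <- tempfile(); write_taxdump(fixture_taxonomy(), dir)
store <- load_taxdump(dir)
cands <- similar_names(store, "Lizard", max_distance = 10, limit = 3)
vapply(cands, function(c) c$record$name_txt, "")
```

## Local storage and versioning

`load_taxdump()` parses the NCBI dmp dialect (fields separated by
`TAB|TAB`, records terminated by `TAB|`) and enforces referential
integrity: every parent resolves, tax_id 1 is the unique root, no
cycles, exactly one scientific name per node. Merged identifiers are
remapped lazily at query time (`resolve_tax_id()`, transitive to a fixed
point), so the cache stays a faithful snapshot of the dump. The cache
itself is one deterministic TSV per table plus a JSON metadata file
(schema version, creation time, source checksum); the Arrow columnar
format the original tooling in this space uses is not available in this
environment, and plain columnar text keeps the round-trip byte-stable
and diffable at no practical cost at taxonomy scale. A schema-version
mismatch is an instructive error (rebuild), never a silent re-parse.

Staleness: the store's age is measured from the raw files' modification
time (creation time is not portable across filesystems), and a copy
older than 90 days is flagged and warned about — never an error, since
the package's deployment mode is unattended cluster runs. Whether the
90-day clock should run from NCBI's release date instead is genuinely
underdetermined; file time was chosen as the observable quantity.

## Taxonomic distance

For taxa *i*, *j*, the distance is the score of the most specific common
ancestor whose rank carries a score, under the default
taxonomic-distinctness table `species = 0, genus = 1, family = 2,
subclass = 3`, fallback 4. NCBI lineages are rank-sparse ("no rank" and
"clade" nodes abound), so when the lowest common ancestor itself has an
unscored rank the path is walked rootward to the first scored rank, and
the fallback applies only when none exists — this makes the default
table total over real lineages. Any rank can be re-scored
(`rank_scores(c(genus = 0.5))`), including making all distances collapse
to 0 as a degenerate check. `taxonomic_distance_into()` overwrites an
existing matrix for re-scoring workflows; under R's value semantics this
is an interface-level contract (same values, checked dimensions), not a
literal allocation guarantee.

```{r}
taxa <- lapply(c("Squalius cephalus", "Squalius squalus", "Rutilus rutilus",
                 "Bos taurus"), function(q) resolve_name(store, q))
taxonomic_distance(store, taxa)
```

## What the fixture generator emulates — and what it does not

`fixture_taxonomy()` is a frozen ~50-node taxonomy that embeds, with
correct structure, each failure mode the matcher must handle: the
synonym/vernacular tangle around *Squalius cephalus*; *Bos taurus* and
its subspecies-style synonym; the *Ovis aries* vernaculars; the homonym
genus *Io* in two divisions; genus *Mus* containing an identically named
subgenus; *Lisarda*/*Lepidosauria*; ligature-prone *Isoetes minima*; a
rank-less influenza strain name; one merged and one deleted identifier.
Real tax_ids are kept where well known (root 1, *Boops boops* 36219);
everything else lives above 10,000,000 so fixture ids can never collide
with real ones. The three adeno-associated-virus records are synthetic
stand-ins: one conventional capitalization plus two one-edit
neighbours, built so that a case-insensitive exact search is unique
while fuzzy search reproduces a three-way equal-distance ambiguity.
(Three *pure* case variants, the naive reading, would make the
case-folded search ambiguous too, which is not the behaviour being
modelled.)

`random_taxonomy()` adds seeded trees with pseudo-Latin binomials and,
optionally, a minimum pairwise edit distance between species names;
`perturb_names()` generates typo'd queries whose realized distance is
verified (substitution/insertion/deletion count 1, transposition 2,
case flips and ligature swaps 0 — they vanish under normalization).

What the generator does **not** emulate: the size (≈3M names) and name-length
distribution of the real table, non-Latin scripts, authority-string
variability, or the real density of near-collisions between valid names.
A green test here therefore establishes the *logic* of matching,
pooling, and distance computation — not recall/precision on real messy
datasets, and not wall-clock performance, which is hardware-dependent
and deliberately asserted only as a comparison-count proportionality.

## Numerical and design choices

* Levenshtein distance (unit costs) is the ranking metric; ties are
  broken by C-locale radix sort on the name, so candidate order is
  identical on every platform.
* Fuzzy candidate sets keep *all* ties at the cutoff distance even past
  `limit` — truncating inside a tie class would make results
  platform-order-dependent.
* Diacritic folding (`é`→`e`) exists but defaults to off; expanding it
  silently would over-merge legitimately distinct strings.
* Hybrid markers ("×") are not normalized; they are left to fuzzy
  matching.
* The typo-recovery experiment (100 single-substitution queries over a
  120-species random taxonomy with pairwise name distance ≥ 5) is
  constructed so recovery is guaranteed by the triangle inequality; it
  validates the machinery end-to-end rather than estimating a real-world
  recovery rate.

## Known limitations

Only the English vernacular classes NCBI distributes are searchable; no
phonetic matching or abbreviation expansion ("E. coli"); no cross-walks
to other backbones (GBIF, ITIS); the distance construction is a rank
proxy, not a phylogeny. The real-database smoke test requires a network
connection and a current taxdump; offline it fails by design rather than
skipping, so its status is always visible.
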