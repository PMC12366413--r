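test_that("taxon_by_id resolves current, root and merged identifiers", {
  b <- taxon_by_id(STORE, 36219L)
  expect_identical(b$name, "Boops boops")
  expect_identical(b$id, 36219L)
  expect_identical(b$rank, "species")
  expect_identical(taxon_by_id(STORE, 1L)$name, "root")
  expect_identical(taxon_by_id(STORE, fx$merged_old)$id, fx$squalius)
  expect_error(taxon_by_id(STORE, fx$deleted_id), class = "tax_deleted_id")
})

test_that("strict resolution: exact hits, synonyms, vernaculars, homonyms", {
  expect_identical(resolve_name(STORE, "Boops boops")$id, fx$boops)
  # a vernacular and a synonym both land on the same species, unambiguously
  expect_identical(resolve_name(STORE, "European chub")$id, fx$squalius)
  expect_identical(resolve_name(STORE, "Cyprinus cephalus")$id, fx$squalius)
  # homonymy is an explicit typed failure carrying both senses
  io <- resolve_name(STORE, "Io")
  expect_s3_class(io, "tax_multiple_matches")
  expect_identical(failure_kind(io), "MULTIPLE_MATCHES")
  expect_length(io$candidates, 2L)
  expect_setequal(vapply(io$candidates, function(c) c$taxon$id, 1L),
                  c(fx$io_aster, fx$io_gastropod))
  # unknown name
  miss <- resolve_name(STORE, "Nosuchname xyz")
  expect_s3_class(miss, "tax_no_direct_match")
  expect_length(miss$candidates, 0L)
})

test_that("fuzzy resolution catches typos at minimal edit distance", {
  hit <- resolve_name(STORE, "Boops bops", strict = FALSE)
  expect_identical(hit$name, "Boops boops")
  # ranking distance agrees with the independent DP oracle
  expect_identical(oracle_levenshtein("boops bops", "boops boops"), 1L)
  cands <- similar_names(STORE, "Boops bops")
  expect_identical(cands[[1L]]$record$name_txt, "Boops boops")
  expect_identical(cands[[1L]]$distance, 1L)
  expect_error(resolve_name(STORE, "x", strict = FALSE, max_distance = 0L),
               "max_distance")
})

test_that("case-insensitive exact search beats fuzzy for coded virus names", {
  # strict, case-sensitive: no record is spelled exactly this way
  expect_s3_class(resolve_name(STORE, "Adeno-associated virus 3b"),
                  "tax_no_direct_match")
  # the case-folded exact stage returns the single correct record,
  # deterministically
  hit <- resolve_name(STORE, "adeno-associated virus 3b",
                      case_sensitive = FALSE)
  expect_identical(hit$id, fx$aav3b)
  expect_identical(hit$name, "Adeno-associated virus 3B")
  # fuzzy instead surfaces the three near-variants as an ambiguity
  fz <- resolve_name(STORE, "Adeno-associated virus 3x", strict = FALSE)
  expect_s3_class(fz, "tax_multiple_matches")
  expect_gte(length(fz$candidates), 2L)
})

test_that("the Lizard pitfall: fuzzy ranks Lisarda far above Lepidosauria", {
  cands <- similar_names(STORE, "Lizard", max_distance = 10L, limit = 100L)
  nms <- vapply(cands, function(c) c$record$name_txt, "")
  d <- vapply(cands, `[[`, 1L, "distance")
  expect_identical(nms[[1L]], "Lisarda")
  expect_identical(d[[1L]], 2L)
  expect_identical(oracle_levenshtein("lizard", "lisarda"), 2L)
  expect_identical(oracle_levenshtein("lizard", "lepidosauria"), 8L)
  expect_identical(d[match("Lepidosauria", nms)], 8L)
})

test_that("similar_names order is (distance, name), ties kept, deterministic", {
  a <- similar_names(STORE, "Mus", max_distance = 3L, limit = 5L)
  b <- similar_names(STORE, "Mus", max_distance = 3L, limit = 5L)
  expect_identical(a, b)
  d <- vapply(a, `[[`, 1L, "distance")
  expect_true(!is.unsorted(d))
  nms <- vapply(a, function(c) c$record$name_txt, "")
  for (dist in unique(d)) {
    expect_identical(nms[d == dist], sort(nms[d == dist], method = "radix"))
  }
  # vernacular "chimpanzees" is reachable within a primate-restricted pool
  cands <- similar_names(STORE, "chimpanzees", pool = primate_pool(STORE))
  expect_true(any(vapply(cands, function(c)
    c$taxon$id == fx$pan && c$matched_class == "common name", TRUE)))
})

test_that("ranking distances equal the DP oracle across fixture name pairs", {
  queries <- c("Boops bops", "Lizard", "Mus", "Isoetes minima",
               "Squalius cephalus", "chimpanzee")
  keys <- STORE$names$key_ci
  for (q in queries) {
    qk <- normalize_name(q, fold_case = TRUE)
    got <- as.integer(utils::adist(qk, keys))
    want <- vapply(keys, function(k) oracle_levenshtein(qk, k), 1L,
                   USE.NAMES = FALSE)
    expect_identical(got, want, info = q)
  }
})

test_that("alternative_taxa lists every bearer of a name, by tax_id", {
  io <- alternative_taxa(STORE, "Io")
  expect_identical(vapply(io, `[[`, 1L, "id"), c(fx$io_aster, fx$io_gastropod))
  mus <- alternative_taxa(STORE, "Mus")
  expect_identical(vapply(mus, `[[`, 1L, "id"), c(fx$mus_genus, fx$mus_sub))
  expect_identical(vapply(mus, `[[`, "", "rank"), c("genus", "subgenus"))
  expect_length(alternative_taxa(STORE, "Boops boops"), 1L)
})

test_that("a rank hint disambiguates subgenus homonymy", {
  amb <- resolve_name(STORE, "Mus")
  expect_s3_class(amb, "tax_multiple_matches")
  expect_identical(resolve_name(STORE, "Mus", rank = "genus")$id, fx$mus_genus)
  expect_identical(resolve_name(STORE, "Mus", rank = "subgenus")$id, fx$mus_sub)
})

test_that("prefer_scientific suppresses vernacular-class matches", {
  # "sheep" only exists as a vernacular; with prefer_scientific it vanishes
  expect_identical(resolve_name(STORE, "sheep")$id, fx$ovis)
  expect_s3_class(resolve_name(STORE, "sheep", prefer_scientific = TRUE),
                  "tax_no_direct_match")
  expect_identical(
    resolve_name(STORE, "Ovis aries", prefer_scientific = TRUE)$id, fx$ovis)
})

test_that("synonym collapse: all names of a taxon resolve to one id", {
  for (id in c(fx$squalius, fx$bos, fx$ovis)) {
    sci <- STORE$names[tax_id == id & name_class == "scientific name",
                       name_txt]
    syns <- tax_synonyms(STORE, id)
    ids <- vapply(c(sci, syns), function(q) resolve_name(STORE, q)$id, 1L)
    expect_identical(unique(unname(ids)), id)
  }
})

test_that("staged-resolution consistency: strict hits are stable under fuzzy", {
  queries <- STORE$names[name_class == "scientific name", name_txt]
  for (q in queries) {
    strict <- resolve_name(STORE, q)
    if (is_match_failure(strict)) next
    for (md in c(1L, 3L)) {
      fuzzy <- resolve_name(STORE, q, strict = FALSE, max_distance = md)
      expect_identical(fuzzy$id, strict$id, info = q)
    }
  }
})

test_that("reconcile_names keeps order, types failures as rows", {
  survey <- c("European chub", "Cyprinus cephalus", "Leuciscus cephalus",
              "Squalius cephalus")
  rec <- reconcile_names(STORE, survey)
  expect_identical(rec$query, survey)
  expect_identical(rec$status, rep("ok", 4L))
  expect_identical(length(unique(rec$tax_id)), 1L)

  mixed <- reconcile_names(STORE, c("Boops boops", "Nosuchname xyz", "Io"))
  expect_identical(mixed$status, c("ok", "no_match", "ambiguous"))
  expect_identical(nrow(mixed), 3L)
  expect_error(reconcile_names(STORE, character()), "non-empty")
  one <- reconcile_names(STORE, "Boops boops")
  expect_identical(nrow(one), 1L)
})

test_that("pool monotonicity: subset hits persist in supersets", {
  plants <- plant_pool(STORE)
  full_io <- similar_names(STORE, "Io", max_distance = 1L)
  pool_io <- similar_names(STORE, "Io", pool = plants, max_distance = 1L)
  ids_full <- vapply(full_io, function(c) c$taxon$id, 1L)
  ids_pool <- vapply(pool_io, function(c) c$taxon$id, 1L)
  expect_true(all(ids_pool %in% ids_full))
  # NO_DIRECT_MATCH on the full store implies it on every subset
  expect_s3_class(resolve_name(STORE, "Nosuchname xyz"), "tax_no_direct_match")
  expect_s3_class(resolve_name(STORE, "Nosuchname xyz", pool = plants),
                  "tax_no_direct_match")
})
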