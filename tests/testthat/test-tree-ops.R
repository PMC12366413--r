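test_that("parent walks one step rootward; the root is its own parent", {
  p1 <- tax_parent(STORE, fx$mus_musculus)
  expect_identical(p1$id, fx$mus_sub)
  expect_identical(p1$rank, "subgenus")
  p2 <- tax_parent(STORE, p1)
  expect_identical(p2$id, fx$mus_genus)
  expect_identical(p2$rank, "genus")
  expect_warning(root_parent <- tax_parent(STORE, fx$root), "root")
  expect_identical(root_parent$id, 1L)
})

test_that("children and descendants", {
  kids <- tax_children(STORE, fx$mus_genus)
  expect_identical(vapply(kids, `[[`, 1L, "id"), fx$mus_sub)
  desc <- tax_descendants(STORE, fx$mus_genus)
  expect_setequal(vapply(desc, `[[`, 1L, "id"),
                  c(fx$mus_sub, fx$mus_musculus))
  expect_length(tax_descendants(STORE, fx$boops), 0L)
  expect_length(tax_descendants(STORE, fx$root), nrow(STORE$nodes) - 1L)
})

test_that("lineage runs root-to-leaf and honours stop_at", {
  lin <- tax_lineage(STORE, fx$mus_musculus)
  ids <- vapply(lin, `[[`, 1L, "id")
  expect_identical(ids[1L], 1L)
  expect_identical(ids[length(ids)], fx$mus_musculus)
  cut <- tax_lineage(STORE, fx$mus_musculus, stop_at = fx$mus_genus)
  expect_identical(vapply(cut, `[[`, 1L, "id"),
                   c(fx$mus_genus, fx$mus_sub, fx$mus_musculus))
  expect_identical(vapply(tax_lineage(STORE, fx$root), `[[`, 1L, "id"), 1L)
  expect_error(tax_lineage(STORE, fx$boops, stop_at = fx$mus_genus),
               "not an ancestor")
})

test_that("descendants/lineage duality holds across the whole fixture", {
  all_ids <- STORE$nodes$tax_id
  desc_of <- lapply(setNames(all_ids, all_ids), function(id)
    taxrecon:::descendant_ids(STORE, id))
  for (b in all_ids) {
    lin <- taxrecon:::lineage_ids(STORE, b)
    ancestors <- setdiff(lin, b)
    for (a in all_ids[all_ids != b]) {
      expect_identical(b %in% desc_of[[as.character(a)]], a %in% ancestors)
    }
  }
})

test_that("lca equals the last common element of root-ordered lineages", {
  ids <- STORE$nodes$tax_id
  set.seed(7)
  pairs <- cbind(sample(ids, 40L, TRUE), sample(ids, 40L, TRUE))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1L]; b <- pairs[k, 2L]
    la <- taxrecon:::lineage_ids(STORE, a)
    lb <- taxrecon:::lineage_ids(STORE, b)
    brute <- la[max(which(la %in% lb))]
    expect_identical(tax_lca(STORE, a, b)$id, brute)
  }
  expect_identical(tax_lca(STORE, fx$boops, fx$boops)$id, fx$boops)
  expect_identical(tax_lca(STORE, fx$mus_musculus, fx$mus_sub)$id, fx$mus_sub)
  # two fish species coalesce inside the fish clade, below the root
  fish_lca <- tax_lca(STORE, fx$squalius, fx$boops)
  expect_identical(fish_lca$id, 10000100L)  # their common fish ancestor
})

test_that("per-taxon metadata: rank, synonyms, vernacular, authority", {
  expect_identical(tax_rank(STORE, fx$bos), "species")
  expect_true("Bos primigenius taurus" %in% tax_synonyms(STORE, fx$bos))
  expect_true(all(c("lamb", "sheep", "wild sheep", "domestic sheep") %in%
                    tax_vernacular(STORE, fx$ovis)))
  expect_identical(tax_vernacular(STORE, fx$lisarda), character())
  expect_identical(tax_authority(STORE, fx$bos), "Bos taurus Linnaeus, 1758")
  # "equivalent name" records count as synonyms; deterministic sort order
  syn <- tax_synonyms(STORE, fx$ovis)
  expect_identical(syn, sort(syn, method = "radix"))
})

test_that("default distance table scores pairs by first scored shared rank", {
  d <- taxonomic_distance(STORE, list(fx$squalius, fx$s_squalus,
                                      fx$rutilus_sp, fx$bos,
                                      fx$mus_musculus, fx$boops))
  expect_identical(unname(d["Squalius cephalus", "Squalius squalus"]), 1)
  expect_identical(unname(d["Squalius cephalus", "Rutilus rutilus"]), 2)
  expect_identical(unname(d["Bos taurus", "Mus musculus"]), 3)
  expect_identical(unname(d["Bos taurus", "Boops boops"]), 4)
  expect_true(all(diag(d) == 0))
  expect_identical(d, t(d))
})

test_that("custom rank scores apply to any level; duplicates are rejected", {
  half <- taxonomic_distance(STORE, list(fx$squalius, fx$s_squalus),
                             rank_scores(c(genus = 0.5)))
  expect_identical(unname(half[1L, 2L]), 0.5)
  zero <- taxonomic_distance(STORE, list(fx$squalius, fx$bos, fx$boops),
                             rank_scores(numeric(), fallback = 0))
  expect_true(all(zero == 0))
  expect_error(taxonomic_distance(STORE, list(fx$bos, fx$bos)), "distinct")
  expect_error(rank_scores(c(genus = -1)), "non-negative")
})

test_that("distance matrices are symmetric, zero-diagonal, score-ranged", {
  taxa <- list(fx$squalius, fx$s_squalus, fx$rutilus_sp, fx$bos, fx$ovis,
               fx$mus_musculus, fx$pan, fx$boops, fx$io_aster)
  set.seed(42)
  for (rep in 1:5) {
    sc <- rank_scores(
      c(species = 0, genus = runif(1, 0, 2), family = runif(1, 1, 3),
        subclass = runif(1, 2, 4)),
      fallback = runif(1, 4, 6))
    m <- taxonomic_distance(STORE, taxa, sc)
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m %in% c(0, unname(sc$scores), sc$fallback)))
  }
})

test_that("monotonicity: deeper coalescence never increases distance", {
  # lca(a,b) descends from lca(a,c) => d(a,b) <= d(a,c)
  taxa <- c(fx$squalius, fx$s_squalus, fx$rutilus_sp, fx$boops, fx$bos,
            fx$mus_musculus)
  m <- taxonomic_distance(STORE, as.list(taxa))
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) for (k in seq_along(taxa)) {
    if (i == j || i == k) next
    lab <- tax_lca(STORE, taxa[i], taxa[j])$id
    lac <- tax_lca(STORE, taxa[i], taxa[k])$id
    if (lac %in% taxrecon:::lineage_ids(STORE, lab)) {
      expect_lte(m[i, j], m[i, k])
    }
  }
})

test_that("taxonomic_distance_into overwrites in place, idempotently", {
  taxa <- list(fx$squalius, fx$s_squalus, fx$bos)
  out <- matrix(99, 3L, 3L)
  got <- taxonomic_distance_into(STORE, taxa, default_rank_scores(), out)
  fresh <- taxonomic_distance(STORE, taxa)
  expect_identical(unname(got), unname(fresh))
  # re-scoring the same matrix equals a fresh computation
  sc <- rank_scores(c(genus = 0.25))
  again <- taxonomic_distance_into(STORE, taxa, sc, got)
  expect_identical(unname(again), unname(taxonomic_distance(STORE, taxa, sc)))
  expect_identical(taxonomic_distance_into(STORE, taxa, sc, again), again)
  expect_error(taxonomic_distance_into(STORE, taxa, out = matrix(0, 2L, 2L)),
               "2x2 but 3 taxa")
})
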