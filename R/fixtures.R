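# Offline taxdump generators. Two kinds: a frozen hand-built taxonomy that
# embeds the classic reconciliation pitfalls (synonyms, homonyms,
# vernaculars, ligatures, case-variant virus names, subgenus homonymy), and
# seeded random taxonomies with controlled name perturbations for
# recovery-rate experiments. Both serialize to the exact NCBI taxdump
# dialect, so everything downstream is testable without a download.

new_fixture_spec <- function(nodes, names, divisions, merged, deleted) {
  structure(
    list(
      nodes = as.data.table(nodes), names = as.data.table(names),
      divisions = as.data.table(divisions),
      merged = as.data.table(merged), deleted = as.integer(deleted)
    ),
    class = "fixture_spec"
  )
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf("<fixture_spec> %d nodes, %d name records\n",
              nrow(x$nodes), nrow(x$names)))
  invisible(x)
}

# NCBI's division table (ids and codes as published)
ncbi_divisions <- function() {
  data.table(
    division_id = 0:11,
    code = c("BCT", "INV", "MAM", "PHG", "PLN", "PRI",
             "ROD", "SYN", "UNA", "VRL", "VRT", "ENV"),
    division_name = c("Bacteria", "Invertebrates", "Mammals", "Phages",
                      "Plants and Fungi", "Primates", "Rodents",
                      "Synthetic and Chimeric", "Unassigned", "Viruses",
                      "Vertebrates", "Environmental samples")
  )
}

#' Hand-built demonstration taxonomy
#'
#' A small, frozen taxonomy exercising every reconciliation pitfall the
#' package addresses: the riverine-fish synonym/vernacular tangle around
#' *Squalius cephalus*; the *Bos taurus* synonym; the *Ovis aries*
#' vernaculars; the homonymous genus *Io* (an aster and a gastropod); the
#' genus *Mus* with its identically named subgenus; the "Lizard" fuzzy
#' pitfall (genus *Lisarda* vs class *Lepidosauria*); the ligature-prone
#' *Isoetes minima*; three near-variant adeno-associated-virus names (the
#' exact variants are synthetic stand-ins: one pure case variant of the
#' conventional capitalization plus two one-edit neighbours); an influenza
#' strain name with no rank; plus one merged and one deleted identifier.
#'
#' Real tax_ids are used where they are well known (root 1, *Boops boops*
#' 36219); all other identifiers come from a reserved high range
#' (>= 10,000,000) so they can never collide with real NCBI ids in mixed
#' tests.
#'
#' @return a `fixture_spec`; serialize with [write_taxdump()].
#' @export
fixture_taxonomy <- function() {
  N <- function(tax_id, parent, rank, div) {
    data.table(tax_id = as.integer(tax_id),
               parent_tax_id = as.integer(parent),
               rank = rank, embl_code = "", division_id = as.integer(div))
  }
  nodes <- rbind(
    N(1L,        1L,        "no rank",      8L),   # root
    N(10000050L, 1L,        "clade",        10L),  # Vertebrata
    N(10000100L, 10000050L, "class",        10L),  # Actinopteri
    N(10000110L, 10000100L, "order",        10L),  # Cypriniformes
    N(10000120L, 10000110L, "family",       10L),  # Cyprinidae
    N(10000130L, 10000120L, "genus",        10L),  # Squalius
    N(10000131L, 10000130L, "species",      10L),  # Squalius cephalus
    N(10000132L, 10000130L, "species",      10L),  # Squalius squalus
    N(10000140L, 10000120L, "genus",        10L),  # Rutilus
    N(10000141L, 10000140L, "species",      10L),  # Rutilus rutilus
    N(10000150L, 10000100L, "family",       10L),  # Sparidae
    N(10000151L, 10000150L, "genus",        10L),  # Boops
    N(36219L,    10000151L, "species",      10L),  # Boops boops
    N(10000330L, 10000050L, "class",        10L),  # Lepidosauria
    N(10000200L, 10000050L, "class",        2L),   # Mammalia
    N(10000201L, 10000200L, "subclass",     2L),   # Theria
    N(10000210L, 10000201L, "family",       2L),   # Bovidae
    N(10000211L, 10000210L, "genus",        2L),   # Bos
    N(10000212L, 10000211L, "species",      2L),   # Bos taurus
    N(10000213L, 10000210L, "genus",        2L),   # Ovis
    N(10000214L, 10000213L, "species",      2L),   # Ovis aries
    N(10000220L, 10000201L, "family",       5L),   # Hominidae
    N(10000221L, 10000220L, "genus",        5L),   # Pan
    N(10000230L, 10000201L, "family",       6L),   # Muridae
    N(10000231L, 10000230L, "genus",        6L),   # Mus
    N(10000232L, 10000231L, "subgenus",     6L),   # Mus <subgenus>
    N(10000233L, 10000232L, "species",      6L),   # Mus musculus
    N(10000240L, 10000201L, "family",       2L),   # Procyonidae
    N(10000241L, 10000240L, "genus",        2L),   # Procyon
    N(10000242L, 10000241L, "species",      2L),   # Procyon lotor
    N(10000290L, 1L,        "kingdom",      4L),   # Viridiplantae
    N(10000300L, 10000290L, "family",       4L),   # Asteraceae
    N(10000301L, 10000300L, "genus",        4L),   # Io (aster)
    N(10000340L, 10000290L, "family",       4L),   # Isoetaceae
    N(10000341L, 10000340L, "genus",        4L),   # Isoetes
    N(10000342L, 10000341L, "species",      4L),   # Isoetes minima
    N(10000310L, 1L,        "phylum",       1L),   # Mollusca
    N(10000311L, 10000310L, "genus",        1L),   # Io (gastropod)
    N(10000320L, 1L,        "order",        1L),   # Hemiptera
    N(10000321L, 10000320L, "genus",        1L),   # Lisarda
    N(10000400L, 1L,        "superkingdom", 9L),   # Viruses
    N(10000410L, 10000400L, "genus",        9L),   # Dependoparvovirus
    N(10000411L, 10000410L, "species",      9L),   # AAV 3B
    N(10000412L, 10000410L, "species",      9L),   # AAV 3
    N(10000413L, 10000410L, "species",      9L),   # AAV 3A
    N(10000420L, 10000400L, "genus",        9L),   # Alphainfluenzavirus
    N(10000421L, 10000420L, "species",      9L),   # Influenza A virus
    N(10000422L, 10000421L, "no rank",      9L),   # the Sydney/97 strain
    N(10000500L, 1L,        "superkingdom", 0L),   # Bacteria
    N(10000510L, 10000500L, "genus",        0L),   # Myxococcus
    N(10000511L, 10000510L, "species",      0L)    # the Welsh isolate
  )

  R <- function(tax_id, name_txt, name_class, unique_name = "") {
    data.table(tax_id = as.integer(tax_id), name_txt = name_txt,
               unique_name = unique_name, name_class = name_class)
  }
  sci <- function(tax_id, name, unique = "") {
    R(tax_id, name, "scientific name", unique)
  }
  names <- rbind(
    sci(1L, "root"),
    sci(10000050L, "Vertebrata"),
    sci(10000100L, "Actinopteri"),
    sci(10000110L, "Cypriniformes"),
    sci(10000120L, "Cyprinidae"),
    sci(10000130L, "Squalius"),
    sci(10000131L, "Squalius cephalus"),
    R(10000131L, "Leuciscus cephalus", "synonym"),
    R(10000131L, "Cyprinus cephalus", "synonym"),
    R(10000131L, "European chub", "common name"),
    R(10000131L, "Squalius cephalus (Linnaeus, 1758)", "authority"),
    sci(10000132L, "Squalius squalus"),
    sci(10000140L, "Rutilus"),
    sci(10000141L, "Rutilus rutilus"),
    R(10000141L, "roach", "common name"),
    sci(10000150L, "Sparidae"),
    sci(10000151L, "Boops"),
    sci(36219L, "Boops boops"),
    R(36219L, "bogue", "genbank common name"),
    sci(10000330L, "Lepidosauria"),
    sci(10000200L, "Mammalia"),
    R(10000200L, "mammals", "common name"),
    sci(10000201L, "Theria", "Theria <mammals>"),
    sci(10000210L, "Bovidae"),
    sci(10000211L, "Bos"),
    sci(10000212L, "Bos taurus"),
    R(10000212L, "Bos primigenius taurus", "synonym"),
    R(10000212L, "Bos taurus Linnaeus, 1758", "authority"),
    R(10000212L, "cattle", "genbank common name"),
    R(10000212L, "domestic cow", "common name"),
    sci(10000213L, "Ovis"),
    sci(10000214L, "Ovis aries"),
    R(10000214L, "lamb", "common name"),
    R(10000214L, "sheep", "genbank common name"),
    R(10000214L, "wild sheep", "common name"),
    R(10000214L, "domestic sheep", "common name"),
    R(10000214L, "Ovis ammon aries", "synonym"),
    sci(10000220L, "Hominidae"),
    sci(10000221L, "Pan"),
    R(10000221L, "chimpanzees", "common name"),
    sci(10000230L, "Muridae"),
    sci(10000231L, "Mus", "Mus <genus>"),
    sci(10000232L, "Mus", "Mus <subgenus>"),
    sci(10000233L, "Mus musculus"),
    R(10000233L, "house mouse", "genbank common name"),
    sci(10000240L, "Procyonidae"),
    sci(10000241L, "Procyon"),
    sci(10000242L, "Procyon lotor"),
    R(10000242L, "raccoon", "genbank common name"),
    sci(10000290L, "Viridiplantae"),
    sci(10000300L, "Asteraceae"),
    sci(10000301L, "Io", "Io <asters>"),
    sci(10000340L, "Isoetaceae"),
    sci(10000341L, "Isoetes"),
    sci(10000342L, "Isoetes minima"),
    sci(10000310L, "Mollusca"),
    sci(10000311L, "Io", "Io <gastropods>"),
    sci(10000320L, "Hemiptera"),
    sci(10000321L, "Lisarda"),
    sci(10000400L, "Viruses"),
    sci(10000410L, "Dependoparvovirus"),
    sci(10000411L, "Adeno-associated virus 3B"),
    sci(10000412L, "Adeno-associated virus 3"),
    sci(10000413L, "Adeno-associated virus 3A"),
    sci(10000420L, "Alphainfluenzavirus"),
    sci(10000421L, "Influenza A virus"),
    R(10000421L, "influenza", "common name"),
    sci(10000422L, "Influenza A virus (A/Sydney/05/97-like(H3N2))"),
    sci(10000500L, "Bacteria"),
    sci(10000510L, "Myxococcus"),
    sci(10000511L, paste0("Myxococcus llanfairpwllgwyngyllgogerychwyrndrob",
                          "wllllantysiliogogogochensis"))
  )

  merged <- data.table(old_tax_id = 10009001L, new_tax_id = 10000131L)
  deleted <- 10009002L
  new_fixture_spec(nodes, names, ncbi_divisions(), merged, deleted)
}

#' Serialize a fixture to a taxdump directory
#'
#' Writes `names.dmp`, `nodes.dmp`, `division.dmp`, `merged.dmp` and
#' `delnodes.dmp` in the exact NCBI dmp dialect (fields separated by
#' `TAB|TAB`, records terminated by `TAB|`), so the output loads through
#' the same path as a real dump. Output bytes are deterministic for a
#' given spec.
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_taxdump <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- function(dt) lapply(seq_len(nrow(dt)), function(i)
    as.character(unlist(dt[i], use.names = FALSE)))
  # canonical order (stable sort on tax_id) so serialize -> load ->
  # re-serialize is byte-identical
  nm <- spec$names[order(tax_id)]
  nd <- spec$nodes[order(tax_id)]
  mg <- spec$merged[order(old_tax_id)]
  write_dmp_file(rows(nm), file.path(dir, "names.dmp"))
  write_dmp_file(rows(nd), file.path(dir, "nodes.dmp"))
  write_dmp_file(rows(spec$divisions[, .(division_id, code, division_name)]),
                 file.path(dir, "division.dmp"))
  write_dmp_file(rows(mg), file.path(dir, "merged.dmp"))
  write_dmp_file(lapply(sort(spec$deleted), as.character),
                 file.path(dir, "delnodes.dmp"))
  invisible(dir)
}

# pseudo-Latin word generator
latin_word <- function(n_syllables) {
  syl <- c("ba", "ce", "di", "fo", "gu", "la", "mi", "no", "pa", "ru",
           "sa", "te", "vi", "xo", "ze", "bra", "cro", "dus", "fer",
           "gon", "lix", "mor", "nus", "pex", "qua", "rit", "sol",
           "tum", "vel", "wex")
  paste(sample(syl, n_syllables, replace = TRUE), collapse = "")
}

#' Seeded random taxonomy
#'
#' Builds a rooted tree with ranks assigned by depth along `ranks` and
#' unique pseudo-Latin binomials at the species rank; deterministic for a
#' fixed seed. `n_taxa` is the number of species (leaves); internal levels
#' are sized by `branching` (mean children per internal node). With
#' `min_name_distance > 0`, species binomials are rejection-sampled until
#' every pair is at least that many edits apart, which makes single-edit
#' typo recovery unambiguous by construction.
#'
#' @param n_taxa number of species leaves (>= 2).
#' @param ranks rank ladder, root-to-leaf; the last entry must be
#'   `"species"`.
#' @param branching mean children per internal node.
#' @param seed integer seed.
#' @param min_name_distance minimal pairwise edit distance between species
#'   binomials (0 disables the check).
#' @return a `fixture_spec`.
#' @export
random_taxonomy <- function(n_taxa, ranks = c("kingdom", "phylum", "class",
                                              "order", "family", "genus",
                                              "species"),
                            branching = 3, seed = 1L,
                            min_name_distance = 0L) {
  stopifnot(n_taxa >= 2L, branching >= 1,
            identical(ranks[length(ranks)], "species"))
  set.seed(as.integer(seed))

  # level sizes leaf-to-root, then ids assigned level by level from the root
  sizes <- integer(length(ranks))
  sizes[length(ranks)] <- as.integer(n_taxa)
  for (k in rev(seq_len(length(ranks) - 1L))) {
    sizes[k] <- max(1L, as.integer(ceiling(sizes[k + 1L] / branching)))
  }

  next_id <- 10000000L
  level_ids <- vector("list", length(ranks))
  for (k in seq_along(ranks)) {
    level_ids[[k]] <- next_id + seq_len(sizes[k]) - 1L
    next_id <- next_id + sizes[k]
  }

  nodes <- data.table(tax_id = 1L, parent_tax_id = 1L, rank = "no rank",
                      embl_code = "", division_id = 8L)
  names_dt <- data.table(tax_id = 1L, name_txt = "root", unique_name = "",
                         name_class = "scientific name")

  used <- new.env(parent = emptyenv())
  fresh_word <- function(capitalize) {
    repeat {
      w <- latin_word(sample(3:4, 1L))
      if (capitalize) {
        substr(w, 1L, 1L) <- toupper(substr(w, 1L, 1L))
      }
      if (!exists(w, envir = used, inherits = FALSE)) {
        assign(w, TRUE, envir = used)
        return(w)
      }
    }
  }

  # species binomials: genus word of the parent + a species epithet
  genus_word <- character()
  species_names <- character(n_taxa)
  for (k in seq_along(ranks)) {
    ids <- level_ids[[k]]
    parents <- if (k == 1L) rep(1L, length(ids)) else {
      level_ids[[k - 1L]][((seq_along(ids) - 1L) %%
                             length(level_ids[[k - 1L]])) + 1L]
    }
    words <- vapply(ids, function(i) fresh_word(capitalize = TRUE),
                    character(1))
    if (ranks[k] == "genus") genus_word <- setNames(words, as.character(ids))
    if (ranks[k] == "species") {
      repeat {
        epithet <- vapply(ids, function(i) fresh_word(capitalize = FALSE),
                          character(1))
        words <- paste(genus_word[as.character(parents)], epithet)
        if (min_name_distance <= 0L) break
        d <- utils::adist(tolower(words))
        diag(d) <- Inf
        if (min(d) >= min_name_distance) break
      }
      species_names <- words
    }
    nodes <- rbind(nodes, data.table(
      tax_id = ids, parent_tax_id = parents, rank = ranks[k],
      embl_code = "", division_id = 8L
    ))
    names_dt <- rbind(names_dt, data.table(
      tax_id = ids, name_txt = words, unique_name = "",
      name_class = "scientific name"
    ))
  }

  new_fixture_spec(nodes, names_dt, ncbi_divisions(),
                   data.table(old_tax_id = integer(),
                              new_tax_id = integer()),
                   integer())
}

#' Perturbed queries over a fixture's scientific names
#'
#' Samples scientific names from the spec and applies random edit
#' operations, returning each perturbed query with its true tax_id and the
#' realized edit count. The realized count is the Levenshtein distance
#' between the case-folded, normalized query and its source — so
#' `case_flip` and `ligature_swap` contribute 0 (they vanish under
#' normalization), `substitute`/`delete`/`insert` contribute 1 each and
#' `transpose` 2. Draws where the edits partly cancel, or where the
#' perturbed string collapses onto an existing name of another taxon, are
#' re-drawn.
#'
#' @param spec a `fixture_spec`.
#' @param n_queries number of perturbed queries.
#' @param ops edit operations to sample from: `substitute`, `delete`,
#'   `insert`, `transpose`, `case_flip`, `ligature_swap`.
#' @param max_edits substantive edits per query (1..max_edits applied).
#' @param seed integer seed.
#' @return `data.frame` with columns `query`, `true_tax_id`, `edits`.
#' @export
perturb_names <- function(spec, n_queries = 100L,
                          ops = c("substitute", "delete", "insert",
                                  "transpose", "case_flip",
                                  "ligature_swap"),
                          max_edits = 1L, seed = 1L) {
  set.seed(as.integer(seed))
  sci <- spec$names[name_class == "scientific name" & tax_id != 1L]
  stopifnot(nrow(sci) >= 1L, max_edits >= 1L)
  op_cost <- c(substitute = 1L, delete = 1L, insert = 1L, transpose = 2L,
               case_flip = 0L, ligature_swap = 0L)
  fold <- function(x) normalize_name(x, fold_case = TRUE)
  key_by_taxon <- split(fold(spec$names$name_txt), spec$names$tax_id)

  one_query <- function() {
    repeat {
      row <- sci[sample(nrow(sci), 1L)]
      n_edits <- sample(max_edits, 1L)
      for (try in seq_len(100L)) {
        s <- row$name_txt
        applied <- sample(ops, n_edits, replace = TRUE)
        for (op in applied) s <- apply_edit(s, op)
        realized <- as.integer(utils::adist(fold(s), fold(row$name_txt)))
        if (realized != sum(op_cost[applied])) next
        # collision: folded query equals a name of a *different* taxon
        others <- unlist(key_by_taxon[names(key_by_taxon) !=
                                        as.character(row$tax_id)])
        if (fold(s) %in% others) next
        return(list(query = s, true_tax_id = row$tax_id, edits = realized))
      }
    }
  }

  out <- lapply(seq_len(n_queries), function(i) one_query())
  data.frame(
    query = vapply(out, `[[`, "", "query"),
    true_tax_id = vapply(out, `[[`, 1L, "true_tax_id"),
    edits = vapply(out, `[[`, 1L, "edits"),
    stringsAsFactors = FALSE
  )
}

apply_edit <- function(s, op) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  letters_pool <- letters
  switch(op,
    substitute = {
      i <- sample(n, 1L)
      repl <- sample(setdiff(letters_pool, tolower(chars[i])), 1L)
      chars[i] <- repl
      paste(chars, collapse = "")
    },
    delete = {
      if (n <= 2L) return(s)
      paste(chars[-sample(n, 1L)], collapse = "")
    },
    insert = {
      i <- sample(n + 1L, 1L)
      paste(c(chars[seq_len(i - 1L)], sample(letters_pool, 1L),
              chars[seq.int(i, length.out = n - i + 1L)]), collapse = "")
    },
    transpose = {
      if (n < 2L) return(s)
      i <- sample(n - 1L, 1L)
      tmp <- chars[i]; chars[i] <- chars[i + 1L]; chars[i + 1L] <- tmp
      paste(chars, collapse = "")
    },
    case_flip = {
      i <- sample(n, 1L)
      chars[i] <- if (chars[i] %in% LETTERS) tolower(chars[i]) else
        toupper(chars[i])
      paste(chars, collapse = "")
    },
    ligature_swap = {
      if (grepl("oe", s, fixed = TRUE)) {
        sub("oe", "œ", s, fixed = TRUE)
      } else if (grepl("ae", s, fixed = TRUE)) {
        sub("ae", "æ", s, fixed = TRUE)
      } else {
        s
      }
    },
    stop("unknown edit op: ", op, call. = FALSE)
  )
}
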