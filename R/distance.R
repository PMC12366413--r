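#' Default rank-score table for taxonomic distances
#'
#' Pairs of taxa are scored by the rank at which they first connect:
#' conspecific 0, congeneric 1, confamilial 2, same subclass 3, and
#' everything coarser 4. Any NCBI rank can be (re)scored by passing a
#' modified table to [taxonomic_distance()].
#'
#' @param scores named numeric vector: rank string to score.
#' @param fallback score applied when no ancestor on the path has a mapped
#'   rank.
#' @return a `rank_scores` object.
#' @export
rank_scores <- function(scores = c(species = 0, genus = 1, family = 2,
                                   subclass = 3),
                        fallback = 4) {
  if (any(scores < 0) || fallback < 0) {
    stop("rank scores must be non-negative", call. = FALSE)
  }
  structure(list(scores = scores, fallback = fallback),
            class = "rank_scores")
}

#' @rdname rank_scores
#' @export
default_rank_scores <- function() rank_scores()

# Score for one pair: walk rootward from the LCA to the first ancestor whose
# rank is in the table (NCBI lineages are rank-sparse: many "no rank"/clade
# nodes); fallback when none is.
pair_score <- function(store, lca_id, table) {
  id <- lca_id
  repeat {
    r <- store$nodes[.(id), rank]
    if (r %in% names(table$scores)) return(unname(table$scores[[r]]))
    pid <- store$nodes[.(id), parent_tax_id]
    if (pid == id) return(table$fallback)
    id <- pid
  }
}

#' Taxonomy-based distance matrix
#'
#' A coarse proxy for phylogenetic distance when no phylogeny is available:
#' the distance between two taxa is the score of the most specific common
#' ancestor whose rank carries a score (see [rank_scores()]); the diagonal
#' is 0. The matrix is symmetric with the input taxa as dimnames.
#'
#' @param store a `taxonomy_store`.
#' @param taxa non-empty list of distinct [taxon] objects (or tax_ids).
#' @param scores a [rank_scores] table.
#' @return square symmetric numeric matrix.
#' @export
taxonomic_distance <- function(store, taxa, scores = default_rank_scores()) {
  taxa <- lapply(taxa, as_taxon, store = store)
  n <- length(taxa)
  if (n == 0L) stop("taxa must be non-empty", call. = FALSE)
  ids <- vapply(taxa, `[[`, 1L, "id")
  if (anyDuplicated(ids)) {
    stop("taxa must be distinct (duplicated tax_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), ")",
         call. = FALSE)
  }
  out <- matrix(0, n, n,
                dimnames = rep(list(vapply(taxa, `[[`, "", "name")), 2L))
  fill_distance(store, out, taxa, scores)
}

#' Recompute a distance matrix into an existing matrix
#'
#' Overwrites `out` with `taxonomic_distance(store, taxa, scores)`; the
#' dimensions must already match. This mirrors the workflow of re-scoring
#' the same taxa set under several rank-score tables without allocating a
#' fresh matrix each time (R's copy-on-modify semantics permitting).
#'
#' @inheritParams taxonomic_distance
#' @param out numeric matrix with `length(taxa)` rows and columns.
#' @return the overwritten matrix.
#' @export
taxonomic_distance_into <- function(store, taxa, scores = default_rank_scores(),
                                    out) {
  taxa <- lapply(taxa, as_taxon, store = store)
  n <- length(taxa)
  if (!is.matrix(out) || nrow(out) != n || ncol(out) != n) {
    stop(sprintf("output matrix is %dx%d but %d taxa were given",
                 NROW(out), NCOL(out), n), call. = FALSE)
  }
  fill_distance(store, out, taxa, scores)
}

fill_distance <- function(store, out, taxa, scores) {
  n <- length(taxa)
  lcas_cache <- lapply(taxa, function(t) lineage_ids(store, t$id))
  for (i in seq_len(n)) {
    out[i, i] <- 0
    if (i < n) for (j in seq.int(i + 1L, n)) {
      la <- lcas_cache[[i]]; lb <- lcas_cache[[j]]
      common <- la[la %in% lb]
      d <- pair_score(store, common[length(common)], scores)
      out[i, j] <- d
      out[j, i] <- d
    }
  }
  out
}
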