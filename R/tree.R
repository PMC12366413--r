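#' Navigate the taxonomy graph
#'
#' `tax_parent()` gives the taxon a taxon descends from (the root is its
#' own parent, with a warning); `tax_children()` its direct descendants;
#' `tax_descendants()` the transitive closure of children, excluding the
#' taxon itself; `tax_lineage()` the root-to-taxon chain of parents, and
#' `tax_lca()` the deepest taxon shared by two lineages.
#'
#' @param store a `taxonomy_store`.
#' @param t,a,b a [taxon] or tax_id.
#' @param stop_at ancestor at which to truncate the lineage (default: the
#'   root, tax_id 1).
#' @return `tax_parent`/`tax_lca`: a [taxon]. `tax_children`/
#'   `tax_descendants`: a list of taxa ordered by tax_id.
#'   `tax_lineage`: a list of taxa in root-to-leaf order.
#' @export
tax_parent <- function(store, t) {
  t <- as_taxon(store, t)
  pid <- store$nodes[.(t$id), parent_tax_id]
  if (pid == t$id) {
    warning("taxon ", t$id, " is the taxonomy root; returning it unchanged",
            call. = FALSE)
  }
  taxon_by_id(store, pid)
}

#' @rdname tax_parent
#' @export
tax_children <- function(store, t) {
  t <- as_taxon(store, t)
  ids <- store$nodes[parent_tax_id == t$id & tax_id != t$id, tax_id]
  taxa_by_ids(store, sort(ids))
}

# iterative (explicit stack) traversal: the real taxonomy is deep and wide
# enough that recursion limits are a genuine risk
descendant_ids <- function(store, id) {
  out <- integer()
  stack <- store$nodes[parent_tax_id == id & tax_id != id, tax_id]
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, cur)
    stack <- c(stack, store$nodes[parent_tax_id == cur, tax_id])
  }
  sort(out)
}

#' @rdname tax_parent
#' @export
tax_descendants <- function(store, t) {
  t <- as_taxon(store, t)
  taxa_by_ids(store, descendant_ids(store, t$id))
}

# root-to-node vector of tax_ids
lineage_ids <- function(store, id) {
  path <- id
  while (id != 1L) {
    id <- store$nodes[.(id), parent_tax_id]
    path <- c(id, path)
  }
  path
}

#' @rdname tax_parent
#' @export
tax_lineage <- function(store, t, stop_at = NULL) {
  t <- as_taxon(store, t)
  ids <- lineage_ids(store, t$id)
  if (!is.null(stop_at)) {
    s <- as_taxon(store, stop_at)
    pos <- match(s$id, ids)
    if (is.na(pos)) {
      stop(sprintf("'%s' (tax_id %d) is not an ancestor of '%s' (tax_id %d)",
                   s$name, s$id, t$name, t$id), call. = FALSE)
    }
    ids <- ids[pos:length(ids)]
  }
  taxa_by_ids(store, ids)
}

#' @rdname tax_parent
#' @export
tax_lca <- function(store, a, b) {
  a <- as_taxon(store, a); b <- as_taxon(store, b)
  la <- lineage_ids(store, a$id)
  lb <- lineage_ids(store, b$id)
  common <- la[la %in% lb]
  taxon_by_id(store, common[length(common)])
}

#' Per-taxon metadata
#'
#' `tax_rank()` returns the taxon's rank string; `tax_synonyms()` its
#' alternative valid scientific names (name classes "synonym" and
#' "equivalent name"); `tax_vernacular()` its English common names
#' (classes "common name" and "genbank common name"); `tax_authority()`
#' its full taxonomic authority records. List outputs are sorted
#' (C-locale), so ordering is platform-independent.
#'
#' @inheritParams tax_parent
#' @return `tax_rank`: a string; the others: character vectors (possibly
#'   empty).
#' @export
tax_rank <- function(store, t) as_taxon(store, t)$rank

names_of_class <- function(store, t, classes) {
  t <- as_taxon(store, t)
  out <- store$names[tax_id == t$id & name_class %in% classes, name_txt]
  sort(out, method = "radix")
}

#' @rdname tax_rank
#' @export
tax_synonyms <- function(store, t) {
  names_of_class(store, t, c("synonym", "equivalent name"))
}

#' @rdname tax_rank
#' @export
tax_vernacular <- function(store, t) {
  names_of_class(store, t, VERNACULAR_CLASSES)
}

#' @rdname tax_rank
#' @export
tax_authority <- function(store, t) names_of_class(store, t, "authority")
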