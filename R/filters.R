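#' Restricted name pools
#'
#' A `name_pool` is a materialized set of tax_ids used to scope searches:
#' restricting the pool both speeds up fuzzy matching (the comparison count
#' equals the pool's name count) and avoids cross-group false matches on
#' shared or similar names.
#'
#' @param store a `taxonomy_store`.
#' @param member_ids integer tax_ids in the pool.
#' @param label human-readable description of the restriction.
#' @return a `name_pool` object.
#' @export
name_pool <- function(store, member_ids, label = "custom pool") {
  member_ids <- unique(as.integer(member_ids))
  bad <- setdiff(member_ids, store$nodes$tax_id)
  if (length(bad)) {
    stop("pool member tax_id(s) not in store: ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(member_ids = member_ids, label = label),
            class = "name_pool")
}

#' @export
print.name_pool <- function(x, ...) {
  cat(sprintf("<name_pool> %s (%d taxa)\n", x$label, length(x$member_ids)))
  invisible(x)
}

#' Pool of all taxa in one or more NCBI divisions
#'
#' @param store a `taxonomy_store`.
#' @param division_names division names as in `division.dmp` (e.g.
#'   `"Mammals"`, `"Viruses"`, `"Plants and Fungi"`).
#' @return a [name_pool].
#' @export
division_pool <- function(store, division_names) {
  known <- store$divisions$division_name
  bad <- setdiff(division_names, known)
  if (length(bad)) {
    stop(sprintf("unknown division(s): %s. Valid divisions: %s",
                 paste(bad, collapse = ", "),
                 paste(sort(known), collapse = ", ")), call. = FALSE)
  }
  div_ids <- store$divisions[division_name %in% division_names, division_id]
  ids <- store$nodes[division_id %in% div_ids, tax_id]
  name_pool(store, ids,
            label = paste("divisions:", paste(division_names, collapse = "+")))
}

#' Convenience division pools
#'
#' Thin wrappers over [division_pool()] for the NCBI divisions. NCBI places
#' primates and rodents in their own divisions, so `mammal_pool(store,
#' inclusive = TRUE)` unions Mammals with Primates and Rodents (and
#' `vertebrate_pool(..., inclusive = TRUE)` additionally pulls those three
#' into Vertebrates).
#'
#' @param store a `taxonomy_store`.
#' @param inclusive include the nested divisions (see Details).
#' @return a [name_pool].
#' @export
mammal_pool <- function(store, inclusive = FALSE) {
  divs <- if (inclusive) c("Mammals", "Primates", "Rodents") else "Mammals"
  division_pool(store, divs)
}

#' @rdname mammal_pool
#' @export
vertebrate_pool <- function(store, inclusive = FALSE) {
  divs <- if (inclusive) c("Vertebrates", "Mammals", "Primates", "Rodents")
          else "Vertebrates"
  division_pool(store, divs)
}

#' @rdname mammal_pool
#' @export
primate_pool <- function(store) division_pool(store, "Primates")

#' @rdname mammal_pool
#' @export
rodent_pool <- function(store) division_pool(store, "Rodents")

#' @rdname mammal_pool
#' @export
invertebrate_pool <- function(store) division_pool(store, "Invertebrates")

#' @rdname mammal_pool
#' @export
plant_pool <- function(store) division_pool(store, "Plants and Fungi")

#' @rdname mammal_pool
#' @export
virus_pool <- function(store) division_pool(store, "Viruses")

#' @rdname mammal_pool
#' @export
phage_pool <- function(store) division_pool(store, "Phages")

#' @rdname mammal_pool
#' @export
bacteria_pool <- function(store) division_pool(store, "Bacteria")

#' @rdname mammal_pool
#' @export
environmental_pool <- function(store) {
  division_pool(store, "Environmental samples")
}

#' Pool of a taxon and all its descendants
#'
#' @param store a `taxonomy_store`.
#' @param ancestor a [taxon] (or tax_id) rooting the subtree.
#' @return a [name_pool] containing the ancestor and every descendant.
#' @export
subtree_pool <- function(store, ancestor) {
  t <- as_taxon(store, ancestor)
  ids <- c(t$id, descendant_ids(store, t$id))
  name_pool(store, ids, label = paste("subtree of", t$name))
}

# accept a taxon object or a bare id
as_taxon <- function(store, x) {
  if (is_taxon(x)) x else taxon_by_id(store, x)
}
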