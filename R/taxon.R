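#' Resolved taxon identity
#'
#' A `taxon` couples a canonical current tax_id with its unique scientific
#' name, rank and NCBI division. It is the success value of every matching
#' operation.
#'
#' @param store a `taxonomy_store`.
#' @param id a tax_id; merged identifiers are remapped first, deleted or
#'   unknown ones raise the corresponding store error.
#' @return a `taxon` object with fields `id`, `name`, `rank`,
#'   `division_id`.
#' @examples
#' \dontrun{taxon_by_id(store, 36219)  # Boops boops}
#' @export
taxon_by_id <- function(store, id) {
  id <- resolve_tax_id(store, id)
  node <- store$nodes[.(id)]
  name <- store$names[tax_id == id & name_class == "scientific name",
                      name_txt]
  structure(
    list(id = id, name = name, rank = node$rank,
         division_id = node$division_id),
    class = "taxon"
  )
}

#' @export
print.taxon <- function(x, ...) {
  cat(sprintf("%s (tax_id %d, rank %s)\n", x$name, x$id, x$rank))
  invisible(x)
}

#' @export
format.taxon <- function(x, ...) sprintf("%s [%d]", x$name, x$id)

is_taxon <- function(x) inherits(x, "taxon")

# taxa for a vector of current ids, as a list
taxa_by_ids <- function(store, ids) lapply(ids, taxon_by_id, store = store)
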