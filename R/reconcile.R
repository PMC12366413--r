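#' Reconcile a list of names against the taxonomy
#'
#' Applies [resolve_name()] to each query and returns one row per input, in
#' input order. Failures become rows (`status` of `"no_match"` or
#' `"ambiguous"`), never exceptions, so batch runs complete unattended. The
#' number of distinct `tax_id` values over `"ok"` rows is the deduplicated
#' species richness of the list.
#'
#' @inheritParams resolve_name
#' @param queries non-empty character vector of name strings.
#' @return a `data.frame` with columns `query`, `status` (`ok` /
#'   `no_match` / `ambiguous`), `matched_name`, `tax_id`, `rank`,
#'   `matched_class`, `distance`.
#' @examples
#' \dontrun{
#' survey <- c("European chub", "Cyprinus cephalus",
#'             "Leuciscus cephalus", "Squalius cephalus")
#' rec <- reconcile_names(store, survey)
#' length(unique(rec$tax_id[rec$status == "ok"]))  # 1: one real species
#' }
#' @export
reconcile_names <- function(store, queries, pool = NULL, strict = TRUE,
                            case_sensitive = TRUE, rank = NULL,
                            prefer_scientific = FALSE, max_distance = 2L) {
  if (!is.character(queries) || length(queries) == 0L) {
    stop("queries must be a non-empty character vector", call. = FALSE)
  }
  rows <- lapply(queries, function(q) {
    res <- resolve_name(store, q, pool = pool, strict = strict,
                        case_sensitive = case_sensitive, rank = rank,
                        prefer_scientific = prefer_scientific,
                        max_distance = max_distance)
    if (is_taxon(res)) {
      # distance 0 when the exact stage hit; re-derive for fuzzy successes
      d <- if (identical(normalize_name(q, fold_case = TRUE),
                         normalize_name(res$name, fold_case = TRUE))) 0L else
        match_distance(store, q, res$id)
      data.frame(query = q, status = "ok", matched_name = res$name,
                 tax_id = res$id, rank = res$rank,
                 matched_class = matched_class_for(store, q, res$id),
                 distance = d, stringsAsFactors = FALSE)
    } else {
      data.frame(query = q,
                 status = if (res$kind == "NO_DIRECT_MATCH") "no_match"
                          else "ambiguous",
                 matched_name = NA_character_, tax_id = NA_integer_,
                 rank = NA_character_, matched_class = NA_character_,
                 distance = NA_integer_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# minimal edit distance from the query to any name record of taxon id
match_distance <- function(store, query, id) {
  keys <- store$names[tax_id == id, key_ci]
  min(as.integer(utils::adist(normalize_name(query, fold_case = TRUE), keys)))
}

# name_class of the record that carried the match (closest record of id)
matched_class_for <- function(store, query, id) {
  recs <- store$names[tax_id == id]
  d <- as.integer(utils::adist(normalize_name(query, fold_case = TRUE),
                               recs$key_ci))
  recs$name_class[which.min(d)]
}

#' Read a batch name list from disk
#'
#' Plain text (one name per line) or a delimited table (CSV/TSV inferred
#' from the extension) with a named column.
#'
#' @param path input file.
#' @param column column holding the names, for delimited input.
#' @return character vector of queries.
#' @export
read_name_list <- function(path, column = NULL) {
  if (!file.exists(path)) stop("cannot read input file ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv") || !is.null(column)) {
    dt <- fread(path, sep = if (ext == "tsv") "\t" else ",",
                colClasses = "character", encoding = "UTF-8")
    if (is.null(column)) {
      stop("delimited input requires a column name (--column)", call. = FALSE)
    }
    if (!column %in% names(dt)) {
      stop(sprintf("column '%s' not found in %s (has: %s)", column, path,
                   paste(names(dt), collapse = ", ")), call. = FALSE)
    }
    queries <- dt[[column]]
  } else {
    queries <- readLines(path, encoding = "UTF-8", warn = FALSE)
  }
  queries <- queries[nzchar(trimws(queries))]
  queries
}
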