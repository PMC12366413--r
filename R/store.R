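#' Load an NCBI taxdump directory into a taxonomy store
#'
#' Reads `names.dmp`, `nodes.dmp` and `division.dmp` (plus `merged.dmp` and
#' `delnodes.dmp` when present) from `directory`, validates referential
#' integrity, and returns an indexed, immutable `taxonomy_store`. Columns of
#' `nodes.dmp` beyond the division id are parsed but unused, so both real
#' NCBI dumps and generated fixtures load unchanged.
#'
#' @param directory path to a taxdump directory.
#' @param source_checksum optional checksum string recorded in the store
#'   (e.g. the MD5 of the downloaded archive).
#' @return a `taxonomy_store` object.
#' @seealso [write_cache()], [resolve_tax_id()], [staleness_days()]
#' @export
load_taxdump <- function(directory, source_checksum = NA_character_) {
  mandatory <- c("names.dmp", "nodes.dmp", "division.dmp")
  paths <- file.path(directory, mandatory)
  missing <- mandatory[!file.exists(paths)]
  if (length(missing)) {
    stop(sprintf(
      "taxdump load error: missing mandatory file(s) %s in %s",
      paste(missing, collapse = ", "), directory
    ), call. = FALSE)
  }

  nrec <- read_dmp_file(file.path(directory, "names.dmp"))
  names_dt <- data.table(
    tax_id      = as.integer(dmp_field(nrec, 1L)),
    name_txt    = dmp_field(nrec, 2L),
    unique_name = dmp_field(nrec, 3L),
    name_class  = dmp_field(nrec, 4L)
  )

  orec <- read_dmp_file(file.path(directory, "nodes.dmp"))
  nodes_dt <- data.table(
    tax_id        = as.integer(dmp_field(orec, 1L)),
    parent_tax_id = as.integer(dmp_field(orec, 2L)),
    rank          = dmp_field(orec, 3L),
    embl_code     = dmp_field(orec, 4L),
    division_id   = suppressWarnings(as.integer(dmp_field(orec, 5L)))
  )

  drec <- read_dmp_file(file.path(directory, "division.dmp"))
  divisions_dt <- data.table(
    division_id   = as.integer(dmp_field(drec, 1L)),
    code          = dmp_field(drec, 2L),
    division_name = dmp_field(drec, 3L)
  )

  merged_path <- file.path(directory, "merged.dmp")
  if (file.exists(merged_path)) {
    mrec <- read_dmp_file(merged_path)
    merged_dt <- data.table(
      old_tax_id = as.integer(dmp_field(mrec, 1L)),
      new_tax_id = as.integer(dmp_field(mrec, 2L))
    )
  } else {
    merged_dt <- data.table(old_tax_id = integer(), new_tax_id = integer())
  }

  del_path <- file.path(directory, "delnodes.dmp")
  deleted <- if (file.exists(del_path)) {
    as.integer(dmp_field(read_dmp_file(del_path), 1L))
  } else {
    integer()
  }

  created_at <- min(file.mtime(paths))

  new_taxonomy_store(
    names = names_dt, nodes = nodes_dt, divisions = divisions_dt,
    merged = merged_dt, deleted = deleted,
    created_at = created_at, source_checksum = source_checksum
  )
}

# Assemble, validate and index a store from already-built tables.
new_taxonomy_store <- function(names, nodes, divisions, merged, deleted,
                               created_at, source_checksum) {
  store <- structure(
    list(
      names = names, nodes = nodes, divisions = divisions,
      merged = merged, deleted = as.integer(deleted),
      created_at = created_at,
      source_checksum = source_checksum
    ),
    class = "taxonomy_store"
  )
  validate_store(store)
  build_indexes(store)
}

# Referential-integrity checks; errors list the offending tax_ids.
validate_store <- function(store) {
  nodes <- store$nodes
  ids <- nodes$tax_id
  if (anyDuplicated(ids)) {
    stop("taxonomy integrity error: duplicated node tax_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  orphan <- !(nodes$parent_tax_id %in% ids)
  if (any(orphan)) {
    stop("taxonomy integrity error: parent of tax_id(s) ",
         paste(nodes$tax_id[orphan], collapse = ", "),
         " not present in nodes", call. = FALSE)
  }
  self <- nodes$tax_id == nodes$parent_tax_id
  if (sum(self) != 1L || nodes$tax_id[self] != 1L) {
    stop("taxonomy integrity error: tax_id 1 must be the unique root ",
         "(parent_tax_id == tax_id)", call. = FALSE)
  }
  # cycle check: every node must reach the root by parent links
  parent <- setNames(nodes$parent_tax_id, as.character(nodes$tax_id))
  n <- length(ids)
  reaches <- logical(n)
  names(reaches) <- as.character(ids)
  reaches[["1"]] <- TRUE
  for (id in ids) {
    path <- character()
    cur <- as.character(id)
    steps <- 0L
    while (!reaches[[cur]]) {
      path <- c(path, cur)
      cur <- as.character(parent[[cur]])
      steps <- steps + 1L
      if (steps > n) {
        stop("taxonomy integrity error: cycle involving tax_id ", id,
             call. = FALSE)
      }
    }
    reaches[path] <- TRUE
  }
  bad_name <- !(store$names$tax_id %in% ids)
  if (any(bad_name)) {
    stop("taxonomy integrity error: name record(s) for unknown tax_id(s) ",
         paste(unique(store$names$tax_id[bad_name]), collapse = ", "),
         call. = FALSE)
  }
  sci <- store$names[name_class == "scientific name", .N, by = tax_id]
  if (nrow(sci) != n || any(sci$N != 1L)) {
    missing <- setdiff(ids, sci$tax_id)
    multi <- sci$tax_id[sci$N > 1L]
    stop("taxonomy integrity error: each node needs exactly one ",
         "'scientific name' record; missing for [",
         paste(missing, collapse = ", "), "], duplicated for [",
         paste(multi, collapse = ", "), "]", call. = FALSE)
  }
  if (any(store$merged$old_tax_id %in% ids)) {
    stop("taxonomy integrity error: merged old_tax_id(s) still present in ",
         "nodes: ",
         paste(intersect(store$merged$old_tax_id, ids), collapse = ", "),
         call. = FALSE)
  }
  overlap <- store$deleted[store$deleted %in% c(ids, store$merged$old_tax_id)]
  if (length(overlap)) {
    stop("taxonomy integrity error: deleted tax_id(s) also present ",
         "elsewhere: ", paste(overlap, collapse = ", "), call. = FALSE)
  }
  invisible(store)
}

#' Resolve a possibly merged tax_id to its canonical, current identifier
#'
#' Merged identifiers (from `merged.dmp`) are followed transitively to a
#' fixed point; deleted or unknown identifiers raise classed errors
#' (`tax_deleted_id`, `tax_unknown_id`).
#'
#' @param store a `taxonomy_store`.
#' @param id a positive integer tax_id.
#' @return the canonical current tax_id (integer).
#' @export
resolve_tax_id <- function(store, id) {
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L) {
    stop("tax_id must be a single positive integer", call. = FALSE)
  }
  mmap <- store$merged_map
  seen <- integer()
  while (TRUE) {
    if (id %in% store$deleted) {
      stop(errorCondition(
        sprintf("tax_id %d refers to a deleted taxon", id),
        class = c("tax_deleted_id", "taxrecon_error")
      ))
    }
    key <- as.character(id)
    if (exists(key, envir = mmap, inherits = FALSE)) {
      if (id %in% seen) {
        stop("merged.dmp contains a remapping cycle at tax_id ", id,
             call. = FALSE)
      }
      seen <- c(seen, id)
      id <- get(key, envir = mmap)
      next
    }
    break
  }
  if (!(id %in% store$nodes$tax_id)) {
    stop(errorCondition(
      sprintf("tax_id %d is unknown to this taxonomy", id),
      class = c("tax_unknown_id", "taxrecon_error")
    ))
  }
  id
}

#' Age of the local taxonomy copy
#'
#' The taxonomy remains fully queryable when stale; staleness is a flag (and
#' a warning at load/CLI level), never an error, so unattended pipeline runs
#' are not interrupted.
#'
#' @param store a `taxonomy_store`.
#' @param now reference timestamp (defaults to the current time).
#' @return list with `age_days` (floor of elapsed days) and `stale`
#'   (`TRUE` when age exceeds 90 days).
#' @export
staleness_days <- function(store, now = Sys.time()) {
  if (now < store$created_at) {
    stop("'now' precedes the store creation timestamp", call. = FALSE)
  }
  age <- as.integer(floor(as.numeric(difftime(now, store$created_at,
                                              units = "days"))))
  list(age_days = age, stale = age > 90L)
}

#' @export
print.taxonomy_store <- function(x, ...) {
  cat(sprintf(
    "<taxonomy_store> %d nodes, %d name records, %d divisions (built %s)\n",
    nrow(x$nodes), nrow(x$names), nrow(x$divisions),
    format(x$created_at, "%Y-%m-%d")
  ))
  invisible(x)
}

#' Resolve the local taxonomy storage directory
#'
#' Resolution order: explicit argument, then the `NCBITAXONOMY_PATH`
#' environment variable (so each project can pin its own taxonomy copy),
#' then a per-user data directory.
#'
#' @param path explicit directory, or `NULL`.
#' @return a directory path (not necessarily existing yet).
#' @export
taxonomy_path <- function(path = NULL) {
  if (!is.null(path) && nzchar(path)) return(path)
  env <- Sys.getenv("NCBITAXONOMY_PATH", "")
  if (nzchar(env)) return(env)
  file.path(tools::R_user_dir("taxrecon", which = "data"), "taxonomy")
}

# -- fetcher interface -------------------------------------------------------
# The download step is isolated behind a single function so that tests (and
# offline builds) can substitute a local directory. The default fetcher
# retrieves NCBI's taxdump archive and validates it against the published
# .md5 sidecar before extraction.

taxdump_url <- "https://ftp.ncbi.nlm.nih.gov/pub/taxonomy/taxdump.tar.gz"

default_fetcher <- function(dest_dir, url = taxdump_url) {
  dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
  archive <- file.path(dest_dir, basename(url))
  utils::download.file(url, archive, mode = "wb", quiet = TRUE)
  utils::download.file(paste0(url, ".md5"), paste0(archive, ".md5"),
                       mode = "wb", quiet = TRUE)
  expected <- strsplit(readLines(paste0(archive, ".md5"), n = 1L), "\\s+")[[1L]][1L]
  got <- unname(tools::md5sum(archive))
  if (!identical(got, expected)) {
    stop(sprintf("checksum mismatch for %s: expected %s, got %s",
                 basename(url), expected, got), call. = FALSE)
  }
  utils::untar(archive, exdir = dest_dir)
  list(dir = dest_dir, checksum = got)
}

# Fetcher for an already-downloaded (or generated) taxdump directory; the
# checksum recorded is the MD5 of names.dmp, giving a stable content tag.
local_dir_fetcher <- function(src_dir) {
  function(dest_dir, ...) {
    list(dir = src_dir,
         checksum = unname(tools::md5sum(file.path(src_dir, "names.dmp"))))
  }
}

#' Build (download, validate, parse, cache) a local taxonomy
#'
#' @param path cache directory (see [taxonomy_path()]).
#' @param fetcher function placing raw taxdump files and returning
#'   `list(dir =, checksum =)`; defaults to downloading from NCBI. Use
#'   `local_dir_fetcher(dir)` semantics via `from_dir` for offline builds.
#' @param from_dir optional local taxdump directory used instead of a
#'   download.
#' @param force overwrite an existing cache.
#' @return the built `taxonomy_store`, invisibly.
#' @export
build_taxonomy <- function(path = taxonomy_path(), fetcher = default_fetcher,
                           from_dir = NULL, force = FALSE) {
  if (!is.null(from_dir)) fetcher <- local_dir_fetcher(from_dir)
  cache_dir <- file.path(path, "cache")
  if (file.exists(file.path(cache_dir, "meta.json")) && !force) {
    stop("a taxonomy cache already exists at ", cache_dir,
         " (use force = TRUE to rebuild)", call. = FALSE)
  }
  fetched <- fetcher(file.path(path, "raw"))
  store <- load_taxdump(fetched$dir, source_checksum = fetched$checksum)
  write_cache(store, cache_dir)
  invisible(store)
}
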