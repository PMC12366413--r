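CACHE_SCHEMA_VERSION <- 1L

# Canonical column order per table: keeps re-written caches byte-identical.
cache_tables <- list(
  names     = c("tax_id", "name_txt", "unique_name", "name_class"),
  nodes     = c("tax_id", "parent_tax_id", "rank", "embl_code", "division_id"),
  divisions = c("division_id", "code", "division_name"),
  merged    = c("old_tax_id", "new_tax_id")
)

#' Write / read the portable taxonomy cache
#'
#' The cache is one columnar text file (TSV) per table plus a small JSON
#' metadata file carrying the schema version, creation timestamp and source
#' checksum. A round-trip (`read_cache(write_cache(s))`) reproduces every
#' record, `created_at` and `source_checksum`; re-writing a read cache is
#' byte-identical. A cache written under a different schema version raises a
#' classed `tax_cache_version` error instructing a rebuild.
#'
#' @param store a `taxonomy_store`.
#' @param path cache directory (created if needed).
#' @return `write_cache`: `path`, invisibly. `read_cache`: a
#'   `taxonomy_store`.
#' @export
write_cache <- function(store, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (tab in names(cache_tables)) {
    cols <- cache_tables[[tab]]
    fwrite(store[[tab]][, cols, with = FALSE],
           file.path(path, paste0(tab, ".tsv")),
           sep = "\t", quote = FALSE, bom = FALSE, eol = "\n")
  }
  writeLines(as.character(store$deleted), file.path(path, "deleted.txt"),
             useBytes = TRUE)
  # epoch seconds as a fixed-precision decimal string: %.6f survives a
  # parse -> re-format round-trip bit-for-bit (ISO strings with %OS6 do
  # not, because formatting truncates fractional seconds)
  meta <- list(
    schema_version = CACHE_SCHEMA_VERSION,
    created_at_epoch = sprintf("%.6f", as.numeric(store$created_at)),
    source_checksum = store$source_checksum
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_cache
#' @export
read_cache <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop("no taxonomy cache found at ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path)
  if (!identical(as.integer(meta$schema_version), CACHE_SCHEMA_VERSION)) {
    stop(errorCondition(
      sprintf(paste0(
        "cache at %s was written with schema version %s (this version ",
        "reads %d); rebuild the taxonomy with build_taxonomy(force = TRUE)"),
        path, meta$schema_version, CACHE_SCHEMA_VERSION),
      class = c("tax_cache_version", "taxrecon_error")
    ))
  }
  read_tab <- function(tab) {
    cols <- cache_tables[[tab]]
    dt <- fread(file.path(path, paste0(tab, ".tsv")),
                sep = "\t", quote = "", colClasses = cache_colclasses[[tab]],
                encoding = "UTF-8")
    setnames(dt, cols)
    dt
  }
  deleted <- as.integer(readLines(file.path(path, "deleted.txt"),
                                  warn = FALSE))
  created_at <- as.POSIXct(as.numeric(meta$created_at_epoch),
                           origin = "1970-01-01", tz = "UTC")
  checksum <- if (is.null(meta$source_checksum)) NA_character_ else
    meta$source_checksum
  new_taxonomy_store(
    names = read_tab("names"), nodes = read_tab("nodes"),
    divisions = read_tab("divisions"), merged = read_tab("merged"),
    deleted = deleted, created_at = created_at, source_checksum = checksum
  )
}

cache_colclasses <- list(
  names = c("integer", "character", "character", "character"),
  nodes = c("integer", "integer", "character", "character", "integer"),
  divisions = c("integer", "character", "character"),
  merged = c("integer", "integer")
)
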