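#' Parse one record of an NCBI `*.dmp` file
#'
#' The taxdump dialect separates fields with the three-character sequence
#' `TAB | TAB` and terminates every record with `TAB |` immediately before
#' the newline. Field content (including internal whitespace) is preserved
#' exactly; only separators and the terminator are removed.
#'
#' @param line a single raw text line (no trailing newline).
#' @param file,line_no optional context used in error messages.
#' @return character vector of field strings.
#' @examples
#' parse_dmp_record("1\t|\t1\t|\tno rank\t|\t\t|")
#' @export
parse_dmp_record <- function(line, file = "<input>", line_no = NA_integer_) {
  if (length(line) != 1L || !is.character(line)) {
    stop("parse_dmp_record() expects a single character line")
  }
  if (!endsWith(line, "\t|")) {
    stop(sprintf(
      "malformed dmp record (missing '\\t|' terminator) at %s:%s",
      file, line_no
    ), call. = FALSE)
  }
  body <- substr(line, 1L, nchar(line) - 2L)
  fields <- strsplit(body, "\t|\t", fixed = TRUE)[[1L]]
  # strsplit drops trailing empty fields; pad to the separator count
  n_fields <- lengths(gregexpr("\t|\t", body, fixed = TRUE))
  n_fields <- if (attr(gregexpr("\t|\t", body, fixed = TRUE)[[1L]],
                       "match.length")[1L] == -1L) 1L else n_fields + 1L
  c(fields, rep("", n_fields - length(fields)))
}

# Read a whole .dmp file into a list of field vectors. Empty files give an
# empty list; every line must carry the record terminator.
read_dmp_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    parse_dmp_record(lines[[i]], file = basename(path), line_no = i)
  })
}

# Serialize field vectors back to the dmp dialect (inverse of read_dmp_file).
write_dmp_file <- function(records, path) {
  lines <- vapply(
    records,
    function(f) paste0(paste(f, collapse = "\t|\t"), "\t|"),
    character(1)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Column-wise extraction helper: field i of every record, or "" when absent.
dmp_field <- function(records, i) {
  vapply(records, function(f) if (length(f) >= i) f[[i]] else "", character(1))
}
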