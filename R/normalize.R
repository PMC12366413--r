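#' Normalize a name string into its comparison form
#'
#' All comparisons in the package run on normalized keys: Unicode canonical
#' composition (NFC), runs of internal whitespace collapsed to single
#' spaces, surrounding whitespace trimmed, and the ligatures "œ" /
#' "æ" expanded to "oe" / "ae" (these are frequent typographic variants
#' of the "oe"/"ae" diphthongs in Latin names, so a plain lookup should
#' survive them). Case folding is applied only when `fold_case = TRUE`;
#' diacritic folding is off by default and limited to an explicit opt-in.
#'
#' Normalization is idempotent.
#'
#' @param s character vector of raw name strings.
#' @param fold_case lowercase-fold the result.
#' @param fold_diacritics strip diacritical marks (e.g. "é" to "e").
#' @return character vector of normalized keys.
#' @examples
#' normalize_name("Isœtes  minima ")   # "Isoetes minima"
#' normalize_name("Boops Boops", fold_case = TRUE)
#' @export
normalize_name <- function(s, fold_case = FALSE, fold_diacritics = FALSE) {
  if (!is.character(s)) stop("name must be character", call. = FALSE)
  out <- stringi::stri_trans_nfc(enc2utf8(s))
  out <- gsub("\\s+", " ", out, perl = TRUE)
  out <- trimws(out)
  if (any(!nzchar(out))) {
    stop(errorCondition("empty name: input is empty or whitespace-only",
                        class = c("tax_empty_name", "taxrecon_error")))
  }
  out <- gsub("œ", "oe", out, fixed = TRUE)
  out <- gsub("æ", "ae", out, fixed = TRUE)
  out <- gsub("Œ", "Oe", out, fixed = TRUE)
  out <- gsub("Æ", "Ae", out, fixed = TRUE)
  if (fold_diacritics) {
    out <- stringi::stri_trans_general(out, "Latin-ASCII")
  }
  if (fold_case) out <- stringi::stri_trans_tolower(out)
  out
}

# Attach normalized key columns and lookup indexes to a store. Two exact
# lookup routes exist: case-preserving (key_cs) and case-folded (key_ci);
# both preserve multiplicity so homonyms surface as multiple records.
build_indexes <- function(store) {
  nm <- store$names
  nm[, key_cs := normalize_name(name_txt)]
  nm[, key_ci := normalize_name(name_txt, fold_case = TRUE)]
  setkey(nm, tax_id)
  setindex(nm, key_cs)
  setindex(nm, key_ci)
  setkey(store$nodes, tax_id)
  setindex(store$nodes, parent_tax_id)
  # merged remapping as a fast environment map (applied lazily at query time)
  mmap <- new.env(parent = emptyenv(), size = max(16L, nrow(store$merged)))
  if (nrow(store$merged)) {
    for (i in seq_len(nrow(store$merged))) {
      assign(as.character(store$merged$old_tax_id[i]),
             store$merged$new_tax_id[i], envir = mmap)
    }
  }
  store$merged_map <- mmap
  store
}

# Exact lookup of a normalized key; returns the matching name rows.
lookup_exact <- function(store, key, case_sensitive = TRUE) {
  if (case_sensitive) {
    store$names[key_cs == key]
  } else {
    store$names[key_ci == key]
  }
}
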