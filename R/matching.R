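# name classes suppressed by prefer_scientific
NON_SCIENTIFIC_CLASSES <- c("common name", "genbank common name",
                            "includes", "in-part")
VERNACULAR_CLASSES <- c("common name", "genbank common name")

# Typed, catchable failure value. Never an interactive prompt: callers in
# unattended pipelines test with is_match_failure() or tryCatch() on the
# condition classes.
match_failure <- function(kind = c("NO_DIRECT_MATCH", "MULTIPLE_MATCHES"),
                          query, candidates = list()) {
  kind <- match.arg(kind)
  cls <- switch(kind,
    NO_DIRECT_MATCH  = "tax_no_direct_match",
    MULTIPLE_MATCHES = "tax_multiple_matches"
  )
  msg <- switch(kind,
    NO_DIRECT_MATCH = sprintf(
      "'%s' has no direct match; similar_names() lists near misses", query),
    MULTIPLE_MATCHES = sprintf(
      "'%s' matches %d distinct taxa; alternative_taxa() lists them",
      query, length(unique(vapply(candidates, function(c) c$taxon$id, 1L))))
  )
  structure(
    class = c(cls, "match_failure", "condition"),
    list(message = msg, call = NULL, kind = kind, query = query,
         candidates = candidates)
  )
}

#' Test and inspect matching failures
#'
#' @param x an object returned by [resolve_name()].
#' @return `is_match_failure()`: logical. `failure_kind()`:
#'   `"NO_DIRECT_MATCH"` or `"MULTIPLE_MATCHES"` (or `NA` for successes).
#' @export
is_match_failure <- function(x) inherits(x, "match_failure")

#' @rdname is_match_failure
#' @export
failure_kind <- function(x) if (is_match_failure(x)) x$kind else NA_character_

#' @export
print.match_failure <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$kind, conditionMessage(x)))
  for (cand in x$candidates) {
    cat(sprintf("  - %s (%s, distance %d)\n", format(cand$taxon),
                cand$matched_class, cand$distance))
  }
  invisible(x)
}

# one candidate: the matched name record, its taxon, the ranking distance
new_candidate <- function(store, row, distance) {
  list(
    record = as.list(row[, .(tax_id, name_txt, unique_name, name_class)]),
    taxon = taxon_by_id(store, row$tax_id),
    distance = as.integer(distance),
    matched_class = row$name_class
  )
}

# rows of the names table restricted to a pool (or the whole store)
pool_names <- function(store, pool = NULL) {
  if (is.null(pool)) return(store$names)
  store$names[tax_id %in% pool$member_ids]
}

#' Resolve one name string to a taxon
#'
#' Staged resolution: (1) exact lookup of the normalized query, honouring
#' `case_sensitive`; (2) if nothing matched and `strict = FALSE`, a fuzzy
#' search over the pool keeps every candidate at the minimal Levenshtein
#' distance not exceeding `max_distance`. Fuzzy comparison always runs on
#' case-folded keys (case errors are treated as typos); `case_sensitive`
#' governs only the exact stage. At every stage candidates are filtered by
#' `rank` (if given), and under `prefer_scientific` vernacular-style classes
#' (common name, genbank common name, includes, in-part) are dropped and any
#' surviving "scientific name" record suppresses the rest.
#'
#' Distinct name records pointing to the same tax_id (a synonym plus the
#' scientific name, say) are one match, not an ambiguity. Exactly one
#' surviving tax_id yields its [taxon]; zero yields a `NO_DIRECT_MATCH` and
#' two or more a `MULTIPLE_MATCHES` failure value — typed conditions, never
#' prompts, so cluster runs proceed unattended.
#'
#' @param store a `taxonomy_store`.
#' @param query the name string to resolve.
#' @param pool optional [name_pool] restricting the search.
#' @param strict disable the fuzzy stage.
#' @param case_sensitive case sensitivity of the exact stage.
#' @param rank optional rank string; only taxa of that rank can match.
#' @param prefer_scientific suppress vernacular-style matches.
#' @param max_distance fuzzy threshold (edit operations).
#' @return a `taxon`, or a `match_failure` (see [is_match_failure()]).
#' @examples
#' \dontrun{
#' resolve_name(store, "Boops bops", strict = FALSE)   # typo -> Boops boops
#' resolve_name(store, "Io")                            # MULTIPLE_MATCHES
#' }
#' @export
resolve_name <- function(store, query, pool = NULL, strict = TRUE,
                         case_sensitive = TRUE, rank = NULL,
                         prefer_scientific = FALSE, max_distance = 2L) {
  stopifnot(is.character(query), length(query) == 1L)
  if (!strict && max_distance < 1L) {
    stop("max_distance must be >= 1 when strict = FALSE", call. = FALSE)
  }
  nm <- pool_names(store, pool)

  # stage 1: exact
  key <- normalize_name(query, fold_case = !case_sensitive)
  hits <- if (case_sensitive) nm[key_cs == key] else nm[key_ci == key]
  cands <- candidate_list(store, hits, distance = 0L)
  cands <- filter_candidates(cands, rank, prefer_scientific)

  # stage 2: fuzzy, only after the exact stage found nothing
  if (!length(cands) && !strict) {
    fz <- fuzzy_candidates(store, query, nm, max_distance)
    cands <- filter_candidates(fz, rank, prefer_scientific)
    if (length(cands)) {
      dmin <- min(vapply(cands, `[[`, 1L, "distance"))
      cands <- cands[vapply(cands, function(c) c$distance == dmin, TRUE)]
    }
  }

  ids <- unique(vapply(cands, function(c) c$taxon$id, 1L))
  if (length(ids) == 1L) return(cands[[1L]]$taxon)
  match_failure(
    if (length(ids)) "MULTIPLE_MATCHES" else "NO_DIRECT_MATCH",
    query = query, candidates = cands
  )
}

candidate_list <- function(store, rows, distance) {
  if (!nrow(rows)) return(list())
  lapply(seq_len(nrow(rows)), function(i) {
    new_candidate(store, rows[i], distance = distance[min(i, length(distance))])
  })
}

# Fuzzy scan: Levenshtein distance between the case-folded query key and
# every case-folded name key in scope. The number of comparisons equals the
# number of names in scope; it is recorded for the cost-monotonicity
# contract of restricted pools (see last_comparison_count()).
fuzzy_candidates <- function(store, query, nm, max_distance) {
  qkey <- normalize_name(query, fold_case = TRUE)
  d <- as.integer(utils::adist(qkey, nm$key_ci)[1L, ])
  .taxrecon_env$comparisons <- length(d)
  keep <- which(d <= max_distance)
  if (!length(keep)) return(list())
  candidate_list(store, nm[keep], distance = d[keep])
}

.taxrecon_env <- new.env(parent = emptyenv())
.taxrecon_env$comparisons <- NA_integer_

#' Number of candidate comparisons made by the last fuzzy search
#'
#' Instrumentation for the pool-restriction cost contract: a fuzzy search
#' compares the query against exactly the names in scope, so restricting
#' the pool reduces the count proportionally.
#' @return integer count (NA before any fuzzy search ran).
#' @export
last_comparison_count <- function() .taxrecon_env$comparisons

filter_candidates <- function(cands, rank, prefer_scientific) {
  if (!is.null(rank)) {
    cands <- cands[vapply(cands, function(c) identical(c$taxon$rank, rank),
                          TRUE)]
  }
  if (prefer_scientific && length(cands)) {
    cands <- cands[!vapply(cands, function(c)
      c$matched_class %in% NON_SCIENTIFIC_CLASSES, TRUE)]
    sci <- vapply(cands, function(c)
      identical(c$matched_class, "scientific name"), TRUE)
    if (any(sci)) cands <- cands[sci]
  }
  cands
}

#' Ranked near-matches for a query
#'
#' Candidates within `max_distance` edits of the query, sorted by distance
#' then name (C-locale radix order, so the ranking is identical on every
#' platform). All candidates tied at the last included distance are kept,
#' so the list can exceed `limit`.
#'
#' @inheritParams resolve_name
#' @param limit target number of candidates.
#' @return list of candidates (each with `record`, `taxon`, `distance`,
#'   `matched_class`), possibly empty; the comparison count is available
#'   via [last_comparison_count()].
#' @export
similar_names <- function(store, query, pool = NULL, limit = 10L,
                          max_distance = 2L) {
  stopifnot(is.character(query), length(query) == 1L, limit >= 1L)
  nm <- pool_names(store, pool)
  cands <- fuzzy_candidates(store, query, nm, max_distance)
  if (!length(cands)) return(cands)
  dist <- vapply(cands, `[[`, 1L, "distance")
  nms <- vapply(cands, function(c) c$record$name_txt, "")
  ord <- order(dist, nms, method = "radix")
  cands <- cands[ord]
  dist <- dist[ord]
  if (length(cands) > limit) {
    cutoff <- dist[limit]
    cands <- cands[dist <= cutoff]
  }
  cands
}

#' All taxa carrying a given name
#'
#' Every distinct taxon having any name record exactly equal (after
#' normalization, case-preserving) to `name`, ordered by tax_id. This is
#' the disambiguation companion to a `MULTIPLE_MATCHES` failure.
#'
#' @inheritParams resolve_name
#' @param name the (homonymous) name string.
#' @return list of [taxon] objects.
#' @export
alternative_taxa <- function(store, name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- normalize_name(name)
  ids <- sort(unique(store$names[key_cs == key, tax_id]))
  taxa_by_ids(store, ids)
}
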