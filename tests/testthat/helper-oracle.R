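# Independent quadratic dynamic-programming Levenshtein oracle. Kept
# deliberately separate from the implementation's distance routine so the
# ranking distances have a second, independent route in tests.
oracle_levenshtein <- function(a, b) {
  a <- strsplit(a, "", fixed = TRUE)[[1L]]
  b <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(a); m <- length(b)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(
        prev[j + 1L] + 1L,                       # deletion
        cur[j] + 1L,                             # insertion
        prev[j] + (a[i] != b[j])                 # substitution
      )
    }
    prev <- cur
  }
  as.integer(prev[m + 1L])
}
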