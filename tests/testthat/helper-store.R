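# Shared fixtures, built once per test run. All query operations are pure,
# so sharing one store across files is safe (and the immutability test
# verifies exactly that).
FIXTURE_SPEC <- fixture_taxonomy()
FIXTURE_DIR <- tempfile("taxdump-")
write_taxdump(FIXTURE_SPEC, FIXTURE_DIR)
STORE <- load_taxdump(FIXTURE_DIR)

# convenience handles for heavily used fixture taxa
fx <- list(
  boops = 36219L, squalius = 10000131L, s_squalus = 10000132L,
  rutilus_sp = 10000141L, bos = 10000212L, ovis = 10000214L,
  pan = 10000221L, mus_genus = 10000231L, mus_sub = 10000232L,
  mus_musculus = 10000233L, io_aster = 10000301L, io_gastropod = 10000311L,
  lisarda = 10000321L, lepidosauria = 10000330L, isoetes_minima = 10000342L,
  aav3b = 10000411L, root = 1L,
  merged_old = 10009001L, deleted_id = 10009002L
)

# deep snapshot of the store's tables, for immutability checks
store_snapshot <- function(store) {
  serialize(list(
    names = as.data.frame(store$names),
    nodes = as.data.frame(store$nodes),
    divisions = as.data.frame(store$divisions),
    merged = as.data.frame(store$merged),
    deleted = store$deleted
  ), connection = NULL)
}
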