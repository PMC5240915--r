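## Shared fixture constructors (built in code; nothing is stored on disk).

## Complete-scan PSSM record table for a native peptide: every non-native
## amino acid at every frame position, values from `value_fun(pos, aa)`.
full_scan_records <- function(native, value_fun) {
  chars <- strsplit(native, "")[[1]]
  L <- length(chars)
  recs <- expand.grid(frame_pos = seq_len(L), replacing_aa = AA_ALPHABET,
                      stringsAsFactors = FALSE)
  recs <- recs[recs$replacing_aa != chars[recs$frame_pos], ]
  recs$value <- mapply(value_fun, recs$frame_pos, recs$replacing_aa)
  recs
}

## Residue substitution matrix through the public API: all values sit in
## frame 1 of one covering peptide. `cols` is a named list aa -> values and
## must contain the native amino acid.
make_rsm <- function(cols, native_aa, pos = 10L, L = 15L,
                     inclusion_mode = "position") {
  stopifnot(native_aa %in% names(cols))
  subs <- data.table::rbindlist(lapply(names(cols), function(a) {
    if (a == native_aa) return(NULL)
    data.table::data.table(protein_id = "p", offset = pos, frame_pos = 1L,
                           native_aa = native_aa, replacing_aa = a,
                           value = cols[[a]])
  }))
  ratios <- data.table::data.table(protein_id = "p", offset = pos,
                                   ratio = cols[[native_aa]])
  data.table::setkey(ratios, protein_id, offset)
  calls <- data.table::data.table(offset = pos, frame_pos = 1L, flag = TRUE)
  build_residue_matrix(pos, subs, ratios, calls, length = L,
                       inclusion_mode = inclusion_mode)
}

## A small planted-epitope dataset used by several integration tests.
small_epitope_sim <- function(seed = 21) {
  generate_dataset(simulation_config(
    protein_length = 40, peptide_length = 10, native_copies = 3,
    epitopes = list(list(start = 18, end = 23, effect = 0.1)), seed = seed))
}

## In-memory pipeline core (no file I/O): mapping through region calling.
run_mem <- function(sim, length = 15L, alpha = 1e-4,
                    inclusion_mode = "position") {
  mapped <- map_peptides(sim$peptides, sim$protein, length = length)
  groups <- native_groups(mapped)
  subs <- substitution_records(mapped, groups)
  ratios <- native_copy_ratios(mapped, groups)
  pep <- peptide_epitope_calls(subs, groups, alpha = alpha)
  mode <- if (pep$n_callable == 0L) "all" else inclusion_mode
  res <- residue_selectivity_profiles(sim$protein, subs, ratios, pep$flags,
                                      length = length, alpha = alpha,
                                      inclusion_mode = mode)
  list(mapped = mapped, groups = groups, subs = subs, ratios = ratios,
       pep = pep, res = res)
}
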