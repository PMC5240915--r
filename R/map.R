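## Index of all L-windows of a protein set plus every Hamming-distance-1
## neighbour of each window, for linear-time peptide classification.
build_window_index <- function(proteins, length = 15L) {
  L <- as.integer(length)
  win_list <- lapply(seq_len(nrow(proteins)), function(k) {
    s <- proteins$sequence[k]
    n <- nchar(s) - L + 1L
    if (n < 1L) return(NULL)
    data.table::data.table(
      protein_id = proteins$id[k],
      offset = seq_len(n),
      window = substring(s, seq_len(n), seq_len(n) + L - 1L)
    )
  })
  windows <- data.table::rbindlist(win_list)
  if (nrow(windows) == 0L) {
    stop("no protein is long enough to contain a window of length ", L, call. = FALSE)
  }
  ## one-substitution neighbours: for each frame position and replacing aa,
  ## rewrite that character of every window (vectorised over windows)
  nb <- vector("list", L * 19L)
  idx <- 0L
  for (j in seq_len(L)) {
    left <- substring(windows$window, 1L, j - 1L)
    right <- substring(windows$window, j + 1L, L)
    nat <- substring(windows$window, j, j)
    for (a in AA_ALPHABET) {
      keep <- nat != a
      if (!any(keep)) next
      idx <- idx + 1L
      nb[[idx]] <- data.table::data.table(
        variant = paste0(left[keep], a, right[keep]),
        protein_id = windows$protein_id[keep],
        offset = windows$offset[keep],
        frame_pos = j,
        native_aa = nat[keep],
        replacing_aa = a
      )
    }
  }
  neighbours <- data.table::rbindlist(nb[seq_len(idx)])
  ## native precedence: a variant string identical to some native window is
  ## never reported as a substitution
  neighbours <- neighbours[!(variant %in% windows$window)]
  list(windows = windows, neighbours = neighbours, L = L)
}

#' Map measured peptides onto target proteins
#'
#' Classifies every peptide as a `native` window (exact substring match, with
#' its 1-based protein offset), a single-amino-acid `substitution` derivative
#' of one window (with the substituted frame position, the native and the
#' replacing amino acid), `ambiguous` (equally valid against more than one
#' window, e.g. in repeat-containing proteins), or `unmapped`. Native matches
#' take precedence over substitution matches. Ambiguous peptides are excluded
#' from all downstream statistics.
#'
#' @param measurements A `data.table`/`data.frame` with columns `peptide`,
#'   `intensity`, optionally `replicate_id` (as from [read_peptide_table()]).
#' @param proteins A `data.frame` with columns `id`, `sequence`
#'   (as from [read_protein_fasta()]).
#' @param length Peptide length L (default 15).
#'
#' @return A `data.table`, one row per measurement, with added columns
#'   `protein_id`, `offset`, `variant_kind` (factor-like character:
#'   `"native"`, `"substitution"`, `"ambiguous"`, `"unmapped"`),
#'   `frame_pos`, `native_aa`, `replacing_aa`.
#' @export
map_peptides <- function(measurements, proteins, length = 15L) {
  stopifnot(nrow(proteins) >= 1L)
  dt <- data.table::as.data.table(measurements)
  if (!("replicate_id" %in% names(dt))) dt[, replicate_id := NA_character_]
  dt <- dt[, .(peptide = toupper(peptide), intensity = as.numeric(intensity),
               replicate_id = as.character(replicate_id))]
  wrong <- nchar(dt$peptide) != length
  if (any(wrong)) {
    message(sprintf("map_peptides: ignoring %d peptide(s) of wrong length", sum(wrong)))
  }
  index <- build_window_index(proteins, length)

  ## native matches; a window sequence present at >1 location is ambiguous
  win_n <- index$windows[, .(n_windows = .N,
                             protein_id = protein_id[1L],
                             offset = offset[1L]), by = .(window)]
  dt[, `:=`(protein_id = NA_character_, offset = NA_integer_,
            variant_kind = "unmapped", frame_pos = NA_integer_,
            native_aa = NA_character_, replacing_aa = NA_character_)]
  dt[wrong, variant_kind := "unmapped"]

  m <- win_n[dt[!wrong], on = c(window = "peptide"), which = FALSE,
             .(n_windows, protein_id, offset)]
  hit <- which(!wrong)
  is_nat <- !is.na(m$n_windows)
  dt[hit[is_nat & m$n_windows == 1L],
     `:=`(variant_kind = "native",
          protein_id = m$protein_id[is_nat & m$n_windows == 1L],
          offset = m$offset[is_nat & m$n_windows == 1L])]
  dt[hit[is_nat & m$n_windows > 1L], variant_kind := "ambiguous"]

  ## substitution matches among the remaining unmapped, correct-length rows
  rest <- which(dt$variant_kind == "unmapped" & !wrong)
  if (length(rest) > 0L && nrow(index$neighbours) > 0L) {
    nb_n <- index$neighbours[, .(n_windows = .N,
                                 protein_id = protein_id[1L],
                                 offset = offset[1L],
                                 frame_pos = frame_pos[1L],
                                 native_aa = native_aa[1L],
                                 replacing_aa = replacing_aa[1L]),
                             by = .(variant)]
    m2 <- nb_n[dt[rest], on = c(variant = "peptide"),
               .(n_windows, protein_id, offset, frame_pos, native_aa, replacing_aa)]
    is_sub <- !is.na(m2$n_windows)
    one <- is_sub & m2$n_windows == 1L
    dt[rest[one],
       `:=`(variant_kind = "substitution",
            protein_id = m2$protein_id[one], offset = m2$offset[one],
            frame_pos = m2$frame_pos[one], native_aa = m2$native_aa[one],
            replacing_aa = m2$replacing_aa[one])]
    dt[rest[is_sub & m2$n_windows > 1L], variant_kind := "ambiguous"]
  }
  dt[]
}
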