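#' Configuration for a synthetic peptide-microarray experiment
#'
#' Describes an array design in the style of a full single-amino-acid
#' substitution scan: overlapping L-mer windows of a random protein at a given
#' step, `native_copies` replicate copies of each native window and (in
#' `"full"` coverage) one copy of each of the 19 substitutions at every
#' position, or one alanine variant per non-alanine position
#' (`"alanine_only"`). Planted epitopes multiply the intensity of any variant
#' that substitutes an epitope residue with a non-tolerated amino acid by
#' `effect` (< 1); peptides overlapping an epitope carry an additive signal
#' gain over baseline; optional heteroclitic pairs multiply specific
#' substitutions by a factor > 1. Noise is multiplicative log-normal with the
#' given coefficient of variation.
#'
#' @param protein_length Protein length P.
#' @param peptide_length Peptide length L (default 15).
#' @param step Tiling step (default 1).
#' @param native_copies Replicate copies R of each native peptide (default 5;
#'   the motivating full-scale design used 50).
#' @param coverage `"full"` or `"alanine_only"`.
#' @param epitopes List of epitopes, each a list with `start`, `end`,
#'   optional `tolerated` (character vector of replacing amino acids that do
#'   NOT disrupt binding, applied at every epitope position, or a named list
#'   keyed by position), and `effect` in [0, 1) (default 0.1).
#' @param baseline Baseline native intensity in Au (default 100).
#' @param epitope_gain Additive intensity gain of peptides overlapping an
#'   epitope (default 400, putting epitope natives near 500 Au).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   noise (default 0.1; 0 = noise-free).
#' @param heteroclitic Optional list of lists with `pos`, `aa`, `factor` > 1.
#' @param seed Integer seed (default 1).
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(protein_length, peptide_length = 15L, step = 1L,
                              native_copies = 5L,
                              coverage = c("full", "alanine_only"),
                              epitopes = list(), baseline = 100,
                              epitope_gain = 400, noise_cv = 0.1,
                              heteroclitic = NULL, seed = 1L) {
  coverage <- match.arg(coverage)
  stopifnot(protein_length >= peptide_length, step >= 1L,
            native_copies >= 1L, baseline > 0, epitope_gain >= 0,
            noise_cv >= 0)
  for (e in epitopes) {
    stopifnot(e$start >= 1L, e$end <= protein_length, e$start <= e$end,
              is.null(e$effect) || (e$effect >= 0 && e$effect < 1))
  }
  structure(list(protein_length = as.integer(protein_length),
                 peptide_length = as.integer(peptide_length),
                 step = as.integer(step),
                 native_copies = as.integer(native_copies),
                 coverage = coverage, epitopes = epitopes,
                 baseline = baseline, epitope_gain = epitope_gain,
                 noise_cv = noise_cv, heteroclitic = heteroclitic,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic peptide-microarray dataset with known ground truth
#'
#' @param config A [simulation_config()] object.
#' @return A list with elements `protein` (`data.frame` of `id`, `sequence`),
#'   `peptides` (`data.table` of `peptide`, `intensity`, `replicate_id`), and
#'   `truth` (list: `residues` -- `data.table` of epitope `pos`, `native_aa`,
#'   `effect`, `tolerated` collapsed to a string -- and the `config`).
#'   Identical configs (including seed) give byte-identical tables.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  P <- config$protein_length; L <- config$peptide_length
  sequence <- paste(sample(AA_ALPHABET, P, replace = TRUE), collapse = "")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]

  ## per-residue epitope effect and tolerated sets
  effect <- rep(NA_real_, P)
  tolerated <- vector("list", P)
  for (e in config$epitopes) {
    for (p in e$start:e$end) {
      effect[p] <- if (is.null(e$effect)) 0.1 else e$effect
      tolerated[[p]] <- if (is.null(e$tolerated)) character(0)
        else if (is.list(e$tolerated)) {
          tp <- e$tolerated[[as.character(p)]]
          if (is.null(tp)) character(0) else tp
        } else e$tolerated
    }
  }
  is_epi <- !is.na(effect)

  offsets <- seq.int(1L, P - L + 1L, by = config$step)
  windows <- substring(sequence, offsets, offsets + L - 1L)
  overlaps <- vapply(offsets, function(o) any(is_epi[o:(o + L - 1L)]), logical(1L))
  nat_expected <- config$baseline + config$epitope_gain * overlaps

  R <- config$native_copies
  natives <- data.table::data.table(
    peptide = rep(windows, each = R),
    expected = rep(nat_expected, each = R),
    replicate_id = paste0("nat_", rep(offsets, each = R), "_c",
                          rep(seq_len(R), times = length(offsets)))
  )

  ## variant peptides
  oi <- rep(seq_along(offsets), each = L)
  frames <- rep(seq_len(L), times = length(offsets))
  nat_at_pair <- chars[offsets[oi] + frames - 1L]
  if (config$coverage == "full") {
    n_pairs <- length(oi)
    keep <- rep(AA_ALPHABET, times = n_pairs) != rep(nat_at_pair, each = 20L)
    oi <- rep(oi, each = 20L)[keep]
    fr <- rep(frames, each = 20L)[keep]
    rep_aa <- rep(AA_ALPHABET, times = n_pairs)[keep]
  } else {
    keep <- nat_at_pair != "A"
    oi <- oi[keep]; fr <- frames[keep]
    rep_aa <- rep("A", length(oi))
  }
  vo <- offsets[oi]
  vwin <- windows[oi]
  variants <- data.table::data.table(
    peptide = paste0(substring(vwin, 1L, fr - 1L), rep_aa,
                     substring(vwin, fr + 1L, L)),
    expected = nat_expected[oi],
    replicate_id = paste0("sub_", vo, "_p", fr, "_", rep_aa)
  )
  ppos <- vo + fr - 1L
  hit <- is_epi[ppos] & !mapply(function(p, a) a %in% tolerated[[p]],
                                ppos, rep_aa)
  variants[hit, expected := expected * effect[ppos[hit]]]
  for (h in config$heteroclitic) {
    sel <- ppos == h$pos & rep_aa == h$aa
    variants[sel, expected := expected * h$factor]
  }

  tbl <- data.table::rbindlist(list(natives, variants))
  if (config$noise_cv > 0) {
    sigma <- sqrt(log(1 + config$noise_cv^2))
    tbl[, intensity := expected * exp(rnorm(.N, 0, sigma))]
  } else {
    tbl[, intensity := expected]
  }
  tbl[, expected := NULL]
  data.table::setcolorder(tbl, c("peptide", "intensity", "replicate_id"))

  truth_res <- data.table::data.table(
    pos = which(is_epi),
    native_aa = chars[is_epi],
    effect = effect[is_epi],
    tolerated = vapply(tolerated[is_epi], paste, character(1L), collapse = "")
  )
  list(protein = data.frame(id = "synthetic_protein", sequence = sequence,
                            stringsAsFactors = FALSE),
       peptides = tbl[],
       truth = list(residues = truth_res, config = config))
}

#' Compare pipeline calls against the planted ground truth
#'
#' @param selective_flags Logical vector over protein positions (residue-level
#'   selectivity calls).
#' @param regions Output of [call_epitope_regions()].
#' @param truth The `truth` element of [generate_dataset()].
#' @return A list: `tp`, `fp`, `fn` (residue counts), `sensitivity`,
#'   `fp_positions`, `fp_beyond_1` (false positives farther than 1 residue
#'   from any true epitope residue), and `region_matches` (number of planted
#'   epitopes overlapped by a called region within a +/-1 residue tolerance).
#' @export
truth_comparison <- function(selective_flags, regions, truth) {
  true_pos <- truth$residues$pos
  called <- which(selective_flags %in% TRUE)
  tp <- sum(called %in% true_pos)
  fp_positions <- setdiff(called, true_pos)
  fn <- sum(!(true_pos %in% called))
  near <- function(p) any(abs(p - true_pos) <= 1L)
  fp_beyond_1 <- if (length(fp_positions)) sum(!vapply(fp_positions, near, logical(1L))) else 0L
  epi <- truth$config$epitopes
  region_matches <- 0L
  for (e in epi) {
    ok <- nrow(regions) > 0L &&
      any(regions$start <= e$end + 1L & regions$end >= e$start - 1L)
    region_matches <- region_matches + as.integer(ok)
  }
  list(tp = tp, fp = length(fp_positions), fn = fn,
       sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
       fp_positions = fp_positions, fp_beyond_1 = fp_beyond_1,
       region_matches = region_matches)
}
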