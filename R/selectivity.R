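#' Native-peptide replicate ratios
#'
#' The native-amino-acid column of a residue substitution matrix is filled
#' with each covering peptide's replicate intensities divided by their median,
#' a distribution centred on 1 that carries the native signal variability.
#'
#' @param mapped Output of [map_peptides()].
#' @param groups Output of [native_groups()].
#' @param floor Intensity floor, as in [substitution_value()].
#' @return A `data.table` with columns `protein_id`, `offset`, `ratio`.
#' @export
native_copy_ratios <- function(mapped, groups, floor = 1) {
  nat <- mapped[variant_kind == "native"]
  nat <- groups[nat, on = c("protein_id", "offset"), nomatch = NULL,
                .(protein_id, offset,
                  ratio = substitution_value(intensity, reference, floor))]
  data.table::setkey(nat, protein_id, offset)
  nat[]
}

#' Build the substitution matrix of one protein residue
#'
#' Pools substitution values of a single protein residue across the
#' overlapping peptides that cover it, indexed by the replacing amino acid
#' (columns) and the frame position the residue occupies in each peptide
#' (rows). Only peptides in which the residue was identified as epitopic
#' (`inclusion_mode = "position"`, default) -- or that carry any epitope flag
#' (`inclusion_mode = "peptide"`) -- contribute rows. The native amino acid's
#' column holds each included peptide's replicate ratios around 1.
#'
#' @param protein_pos 1-based residue position in the protein.
#' @param subs [substitution_records()] for the protein (one `protein_id`).
#' @param native_ratios [native_copy_ratios()] for the protein.
#' @param calls A `data.table` of per-peptide epitope flags in long form:
#'   columns `offset`, `frame_pos`, `flag` (as from [peptide_epitope_calls()]).
#' @param length Peptide length L.
#' @param inclusion_mode `"position"` or `"peptide"`.
#' @return An object of class `"residue_matrix"`: list with `protein_pos`,
#'   `native_aa`, `data` (`data.table` of `frame`, `aa`, `value`),
#'   `frames_included`, `frames_covered`.
#' @export
build_residue_matrix <- function(protein_pos, subs, native_ratios, calls,
                                 length = 15L,
                                 inclusion_mode = c("position", "peptide")) {
  inclusion_mode <- match.arg(inclusion_mode)
  L <- as.integer(length)
  sub_here <- subs[offset + frame_pos - 1L == protein_pos]
  covered <- sort(unique(c(sub_here$offset,
                           native_ratios[offset > protein_pos - L &
                                           offset <= protein_pos, offset])))
  covered <- covered[covered > protein_pos - L & covered <= protein_pos]
  native_aa <- if (nrow(sub_here) > 0L) sub_here$native_aa[1L] else NA_character_
  if (inclusion_mode == "position") {
    inc <- calls[offset + frame_pos - 1L == protein_pos & flag %in% TRUE, offset]
  } else {
    inc <- calls[flag %in% TRUE, unique(offset)]
  }
  included <- intersect(covered, inc)
  if (length(included) == 0L) {
    return(structure(list(protein_pos = protein_pos, native_aa = native_aa,
                          data = data.table::data.table(frame = integer(),
                                                        aa = character(),
                                                        value = numeric()),
                          frames_included = integer(),
                          frames_covered = protein_pos - covered + 1L),
                     class = "residue_matrix"))
  }
  frames <- protein_pos - included + 1L
  sub_part <- sub_here[offset %in% included,
                       .(frame = protein_pos - offset + 1L,
                         aa = replacing_aa, value = value)]
  nat_part <- native_ratios[offset %in% included,
                            .(frame = protein_pos - offset + 1L,
                              aa = native_aa, value = ratio)]
  structure(list(protein_pos = protein_pos, native_aa = native_aa,
                 data = data.table::rbindlist(list(sub_part, nat_part)),
                 frames_included = sort(frames),
                 frames_covered = protein_pos - covered + 1L),
            class = "residue_matrix")
}

#' @export
print.residue_matrix <- function(x, ...) {
  cat(sprintf("Residue %d (%s): %d values, %d/%d frames included\n",
              x$protein_pos, x$native_aa, nrow(x$data),
              length(x$frames_included), length(x$frames_covered)))
  invisible(x)
}

#' Selectivity statistics of one protein residue
#'
#' Tests each amino-acid column mean `mu_i` of the residue substitution
#' matrix against the global matrix mean `mu_g`. With `S^2` the pooled
#' within-column variance (df = N - K over K columns with data), the standard
#' error of the contrast `mu_i - mu_g` is
#' `SE_i = S * sqrt((1 - n_i/N)^2 / n_i + (N - n_i) / N^2)`
#' (the covariance between `mu_i` and `mu_g` is accounted for, so with only a
#' native and one replacing column the statistic is EXACTLY the two-sample
#' pooled t-statistic and the procedure condenses to a Student t-test).
#' `t_i = (mu_i - mu_g) / SE_i`; `p_i` is the one-sided upper tail of the
#' Dunnett max-t distribution at `|t_i|` with `m` = number of replacing amino
#' acids with data and `df = N - K`. The residue is selective when any
#' replacing amino acid has `p_i < alpha`.
#'
#' @param rsm A [build_residue_matrix()] object.
#' @param alpha Significance level (default 1e-4).
#' @param rho Dunnett correlation (default 0.5).
#' @return An object of class `"selectivity_profile"`: list with `stats`
#'   (`data.table` of `aa`, `n`, `mu`, `se`, `t`, `p`), `mu_g`, `m`, `df`,
#'   `s2`, `selective`, `native_aa`, `protein_pos`, `alpha`.
#' @export
selectivity_stats <- function(rsm, alpha = 1e-4, rho = 0.5) {
  stopifnot(inherits(rsm, "residue_matrix"), alpha > 0, alpha < 1)
  d <- rsm$data
  empty <- function(sel) structure(
    list(stats = data.table::data.table(aa = character(), n = integer(),
                                        mu = numeric(), se = numeric(),
                                        t = numeric(), p = numeric()),
         mu_g = NA_real_, m = 0L, df = NA_real_, s2 = NA_real_,
         selective = sel, native_aa = rsm$native_aa,
         protein_pos = rsm$protein_pos, alpha = alpha),
    class = "selectivity_profile")
  if (nrow(d) == 0L) return(empty(FALSE))
  st <- d[, .(n = .N, mu = mean(value)), by = .(aa)]
  data.table::setorder(st, aa)
  N <- nrow(d)
  K <- nrow(st)
  mu_g <- mean(d$value)
  m <- sum(st$aa != rsm$native_aa)
  if (K < 2L || N - K < 1L || m < 1L) return(empty(FALSE))
  s2 <- d[st, on = "aa"][, sum((value - mu)^2)] / (N - K)
  st[, se := sqrt(s2 * ((1 - n / N)^2 / n + (N - n) / N^2))]
  if (s2 <= 0) {
    st[, `:=`(t = 0, p = 1)]
  } else {
    st[, t := (mu - mu_g) / se]
    dp <- dunnett_params(m = m, df = N - K, rho = rho)
    st[, p := 1 - dunnett_cdf(abs(t), dp)]
  }
  selective <- any(st[aa != rsm$native_aa, p] < alpha)
  structure(list(stats = st[], mu_g = mu_g, m = m, df = N - K, s2 = s2,
                 selective = selective, native_aa = rsm$native_aa,
                 protein_pos = rsm$protein_pos, alpha = alpha),
            class = "selectivity_profile")
}

#' @export
print.selectivity_profile <- function(x, ...) {
  cat(sprintf("Residue %d (%s): mu_g = %s, %s (alpha = %g)\n",
              x$protein_pos, x$native_aa,
              if (is.na(x$mu_g)) "NA" else sprintf("%.3f", x$mu_g),
              if (x$selective) "SELECTIVE" else "not selective", x$alpha))
  invisible(x)
}

#' Signed, rescaled logo scores of a residue
#'
#' Each amino acid is scored `raw_i = -sign(t_i) * log10(p_i)` and the scores
#' are rescaled so that `sum_i |s_i| = 1 - mu_g`: the total letter height of a
#' logo column equals the mean relative signal change caused by substituting
#' the native residue. Positive letters have `mu_i > mu_g` (favoured),
#' negative letters `mu_i < mu_g` (disfavoured).
#'
#' @param profile A [selectivity_stats()] object.
#' @param p_min Numerical clamp for p-values of 0 (default 1e-300).
#' @return Named numeric vector over [AA_ALPHABET] (0 for amino acids without
#'   data or in the degenerate all-p-equal-1 case).
#' @export
logo_scores <- function(profile, p_min = 1e-300) {
  stopifnot(inherits(profile, "selectivity_profile"))
  s <- setNames(numeric(20L), AA_ALPHABET)
  st <- profile$stats
  if (nrow(st) == 0L) return(s)
  raw <- -sign(st$t) * log10(pmax(st$p, p_min))
  tot <- sum(abs(raw))
  if (tot > 0) s[st$aa] <- raw * (1 - profile$mu_g) / tot
  s
}

#' Call gap-tolerant epitope regions along a protein
#'
#' Merges selective residues into maximal regions allowing internal gaps of at
#' most `max_gap` non-selective residues, then keeps regions containing at
#' least `min_residues` selective residues. The region string prints the
#' native letter at selective positions and `'-'` in gaps.
#'
#' @param flags Logical vector over protein positions (`NA` = not selective).
#' @param min_residues Minimum number of selective residues (default 4).
#' @param max_gap Maximum internal gap length (default 2).
#' @param sequence Optional protein sequence for the region strings.
#' @return A `data.table` with columns `start`, `end`, `n_selective`,
#'   `region` (string; `NA` if `sequence` is missing).
#' @export
call_epitope_regions <- function(flags, min_residues = 4L, max_gap = 2L,
                                 sequence = NULL) {
  pos <- which(flags %in% TRUE)
  out <- data.table::data.table(start = integer(), end = integer(),
                                n_selective = integer(), region = character())
  if (length(pos) == 0L) return(out)
  grp <- cumsum(c(1L, diff(pos) > max_gap + 1L))
  regions <- data.table::data.table(pos = pos, grp = grp)[
    , .(start = min(pos), end = max(pos), n_selective = .N), by = grp][
      n_selective >= min_residues][, grp := NULL]
  if (nrow(regions) == 0L) return(out)
  regions[, region := NA_character_]
  if (!is.null(sequence)) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    regions[, region := vapply(seq_len(.N), function(k) {
      span <- start[k]:end[k]
      letters <- chars[span]
      letters[!(span %in% pos)] <- "-"
      paste(letters, collapse = "")
    }, character(1L))]
  }
  regions[]
}
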