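#' Reference intensity of a native peptide
#'
#' The median of the replicate copy intensities; for an even number of copies,
#' the midpoint of the two central order statistics.
#'
#' @param copy_intensities Numeric vector of replicate intensities (length >= 1).
#' @return The median intensity.
#' @export
native_reference <- function(copy_intensities) {
  if (length(copy_intensities) == 0L) {
    stop("native_reference: no copy intensities", call. = FALSE)
  }
  stats::median(copy_intensities)
}

#' Substitution value of a measured variant peptide
#'
#' The intensity of the variant divided by the (floored) reference intensity
#' of its parent native peptide: 1 means no effect, values below 1 signal
#' loss upon substitution, values above 1 a heteroclitic gain. The result is
#' canonicalized to 7 significant digits so that every downstream statistic is
#' invariant, at the bit level, to the absolute scale (units) of the
#' intensities; fluorescence readouts carry far fewer meaningful digits.
#'
#' @param intensity Variant intensity (Au), non-negative.
#' @param reference Native reference intensity (Au), from [native_reference()].
#' @param floor Intensity floor (Au, default 1) guarding against ratios
#'   against near-zero references. Note the floor is an absolute quantity.
#' @return intensity / max(reference, floor), rounded to 7 significant digits.
#' @export
substitution_value <- function(intensity, reference, floor = 1) {
  den <- pmax(reference, floor)
  if (any(den <= 0)) {
    stop("substitution_value: reference and floor are both zero", call. = FALSE)
  }
  signif(intensity / den, 7L)
}

#' Bootstrap standard error of the native reference
#'
#' Resamples the N replicate copies with replacement `n_reps` times and
#' returns the standard deviation of the resampled medians. A quality-control
#' statistic for native-signal stability; it does not enter the Dunnett LSD.
#'
#' @param copy_intensities Numeric vector of replicate intensities.
#' @param n_reps Number of bootstrap resamples (default 10000).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return The bootstrap SE, or `NA_real_` when fewer than 2 copies exist.
#' @export
bootstrap_native_se <- function(copy_intensities, n_reps = 10000L, seed) {
  n <- length(copy_intensities)
  if (n < 2L) return(NA_real_)
  stopifnot(n_reps >= 1L)
  if (missing(seed)) stop("bootstrap_native_se: seed is required", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draws <- matrix(sample(copy_intensities, n * n_reps, replace = TRUE),
                  nrow = n_reps, ncol = n)
  meds <- apply(draws, 1L, stats::median)
  stats::sd(meds)
}

#' Group native peptide copies and compute references
#'
#' @param mapped Output of [map_peptides()].
#' @param bootstrap_reps Bootstrap resamples for the QC standard error;
#'   `0` skips the bootstrap (SE reported as `NA`).
#' @param seed Integer seed for the bootstrap.
#' @return A `data.table`, one row per native peptide, with columns
#'   `protein_id`, `offset`, `native_sequence`, `n_copies`, `reference`
#'   (median intensity), `bootstrap_se`.
#' @export
native_groups <- function(mapped, bootstrap_reps = 0L, seed = 1L) {
  nat <- mapped[variant_kind == "native"]
  if (nrow(nat) == 0L) stop("no native peptides mapped", call. = FALSE)
  grp <- nat[, .(native_sequence = peptide[1L],
                 n_copies = .N,
                 reference = native_reference(intensity),
                 bootstrap_se = if (bootstrap_reps > 0L && .N >= 2L)
                   bootstrap_native_se(intensity, bootstrap_reps,
                                       seed + offset[1L])
                 else NA_real_),
             by = .(protein_id, offset)]
  data.table::setkey(grp, protein_id, offset)
  grp[]
}

#' Substitution values for all mapped single-substitution peptides
#'
#' @param mapped Output of [map_peptides()].
#' @param groups Output of [native_groups()].
#' @param floor Intensity floor passed to [substitution_value()].
#' @param min_native_intensity Optional filter: substitution records whose
#'   parent native reference falls below this value are dropped (default 0,
#'   i.e. off; weak natives legitimately carry no epitope calls).
#' @return A `data.table` with columns `protein_id`, `offset`, `frame_pos`,
#'   `native_aa`, `replacing_aa`, `value` (dimensionless ratio).
#' @export
substitution_records <- function(mapped, groups, floor = 1,
                                 min_native_intensity = 0) {
  sub <- mapped[variant_kind == "substitution"]
  if (nrow(sub) == 0L) stop("no substitution peptides mapped", call. = FALSE)
  sub <- groups[sub, on = c("protein_id", "offset"), nomatch = NULL,
                .(protein_id, offset, frame_pos = i.frame_pos,
                  native_aa = i.native_aa, replacing_aa = i.replacing_aa,
                  intensity = intensity, reference = reference)]
  if (min_native_intensity > 0) sub <- sub[reference >= min_native_intensity]
  sub[, value := substitution_value(intensity, reference, floor)]
  sub[, c("intensity", "reference") := NULL]
  sub[]
}
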