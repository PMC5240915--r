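#' Build the position-specific scoring matrix of one native peptide
#'
#' Substitution values are arranged as a 20 x L matrix: rows are the replacing
#' amino acids, columns the peptide frame positions. The cell of the native
#' amino acid in each column is structurally absent (`NA`), as are unmeasured
#' spots; duplicate measurements of the same (amino acid, position) cell are
#' averaged.
#'
#' @param records A `data.frame`/`data.table` with columns `frame_pos`,
#'   `replacing_aa`, `value` for one native peptide (e.g. the relevant subset
#'   of [substitution_records()]).
#' @param native_sequence The native peptide sequence (length L).
#' @return An object of class `"pssm"`: list with `native_sequence`, `values`
#'   (20 x L numeric matrix, `NA` for absent cells), `mu` (column means),
#'   `n` (present cells per column).
#' @export
build_pssm <- function(records, native_sequence) {
  L <- nchar(native_sequence)
  records <- data.table::as.data.table(records)
  stopifnot(nrow(records) >= 1L,
            all(records$frame_pos >= 1L), all(records$frame_pos <= L),
            all(records$replacing_aa %in% AA_ALPHABET))
  nat <- strsplit(native_sequence, "", fixed = TRUE)[[1L]]
  clash <- records$replacing_aa == nat[records$frame_pos]
  if (any(clash)) {
    stop(sprintf("build_pssm: %d record(s) whose replacing amino acid equals the native (mapping bug)",
                 sum(clash)), call. = FALSE)
  }
  agg <- records[, .(value = mean(value)), by = .(frame_pos, replacing_aa)]
  values <- matrix(NA_real_, nrow = 20L, ncol = L,
                   dimnames = list(AA_ALPHABET, seq_len(L)))
  values[cbind(match(agg$replacing_aa, AA_ALPHABET), agg$frame_pos)] <- agg$value
  structure(list(
    native_sequence = native_sequence,
    values = values,
    mu = unname(colMeans(values, na.rm = TRUE)),
    n = unname(colSums(!is.na(values)))
  ), class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM for %s: %d/%d cells present, mean mu_i = %.3f\n",
              x$native_sequence, sum(x$n), 19L * nchar(x$native_sequence),
              mean(x$mu, na.rm = TRUE)))
  invisible(x)
}

#' Pooled variance of a PSSM
#'
#' Within-column squared deviations from the column means, pooled over all L
#' columns: `S^2 = sum_ij (x_ij - mu_i)^2 / (sum_i n_i - L)`.
#'
#' @param pssm A [build_pssm()] object.
#' @return The pooled variance S^2.
#' @export
pooled_variance <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  L <- ncol(pssm$values)
  n_tot <- sum(pssm$n)
  if (n_tot <= L) {
    stop(sprintf("pooled_variance: insufficient data (sum n_i = %d <= L = %d); %s",
                 n_tot, L,
                 "single-substitution (e.g. alanine-scan) data has no per-peptide test"),
         call. = FALSE)
  }
  dev <- sweep(pssm$values, 2L, pssm$mu, "-")
  sum(dev^2, na.rm = TRUE) / (n_tot - L)
}

#' Call epitope positions within one native peptide
#'
#' One-tailed many-to-one Dunnett test of every peptide position against the
#' no-selectivity value 1: with `S^2` the pooled PSSM variance,
#' `SE_i = sqrt(S^2 / n_i)` and `LSD_i = t_d * SE_i`, where `t_d` is the
#' `1 - alpha` quantile of the central Dunnett max-t distribution with
#' `m = L - 1` comparisons and `df = sum_i n_i - L`. Position i is part of the
#' epitope iff `1 - mu_i > LSD_i`; only signal LOSS can trigger a call
#' (heteroclitic increases never do).
#'
#' @param pssm A [build_pssm()] object.
#' @param alpha Significance level in (0, 1); default 1e-4.
#' @param rho Dunnett correlation (default 0.5, balanced design).
#' @return An object of class `"epitope_call"`: list with `flags` (logical,
#'   length L; `NA` for columns with no data), `lsd`, `mu`, `n`, `s2`, `t_d`,
#'   `alpha`, `callable` (FALSE when `sum n_i <= L`, in which case all flags
#'   are `NA`), `native_sequence`.
#' @export
call_epitope_positions <- function(pssm, alpha = 1e-4, rho = 0.5) {
  stopifnot(inherits(pssm, "pssm"), alpha > 0, alpha < 1)
  L <- ncol(pssm$values)
  n_tot <- sum(pssm$n)
  if (n_tot <= L || L < 2L) {
    return(structure(list(
      flags = rep(NA, L), lsd = rep(NA_real_, L), mu = pssm$mu, n = pssm$n,
      s2 = NA_real_, t_d = NA_real_, alpha = alpha, callable = FALSE,
      native_sequence = pssm$native_sequence
    ), class = "epitope_call"))
  }
  s2 <- pooled_variance(pssm)
  t_d <- dunnett_quantile_cached(1 - alpha,
                                 dunnett_params(m = L - 1L, df = n_tot - L,
                                                rho = rho))
  se <- sqrt(s2 / pssm$n)
  lsd <- t_d * se
  flags <- (1 - pssm$mu) > lsd
  flags[pssm$n == 0L] <- NA   # uncallable columns are never flagged
  structure(list(
    flags = flags, lsd = lsd, mu = pssm$mu, n = pssm$n, s2 = s2, t_d = t_d,
    alpha = alpha, callable = TRUE, native_sequence = pssm$native_sequence
  ), class = "epitope_call")
}

#' @export
print.epitope_call <- function(x, ...) {
  if (!x$callable) {
    cat(sprintf("%s: not callable (insufficient substitution data)\n",
                x$native_sequence))
  } else {
    cat(sprintf("%s\n%s   (alpha = %g, t_d = %.3f)\n", x$native_sequence,
                format_epitope_string(x$native_sequence, x$flags),
                x$alpha, x$t_d))
  }
  invisible(x)
}

#' Format the dashed epitope string of a peptide
#'
#' The reporting dialect of the per-peptide output table: the native letter at
#' every flagged position, `'-'` elsewhere.
#'
#' @param native_sequence Native peptide sequence (length L).
#' @param flags Logical vector of length L (`NA` treated as unflagged).
#' @return A character scalar of length-L.
#' @export
#' @examples
#' format_epitope_string("DHVKLVNEVTEFAKT", seq_len(15) %in% 5:12)
format_epitope_string <- function(native_sequence, flags) {
  L <- nchar(native_sequence)
  stopifnot(length(flags) == L)
  chars <- strsplit(native_sequence, "", fixed = TRUE)[[1L]]
  chars[!(flags %in% TRUE)] <- "-"
  paste(chars, collapse = "")
}
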