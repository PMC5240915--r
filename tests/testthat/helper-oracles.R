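## Independent oracles and small utilities shared across the test files.
## Everything here deliberately avoids the package's own code paths.

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## Brute-force epitope-position rule: direct transcription of
## "flag i iff 1 - mu_i > t_d * sqrt(S^2 / n_i)" with plain loops.
## `values` is a 20 x L matrix with NA for absent cells.
brute_force_epitope_flags <- function(values, alpha, rho = 0.5) {
  L <- ncol(values)
  mu <- numeric(L); n <- integer(L)
  for (i in seq_len(L)) {
    col <- values[, i][!is.na(values[, i])]
    n[i] <- length(col)
    mu[i] <- mean(col)
  }
  ss <- 0
  for (i in seq_len(L)) {
    col <- values[, i][!is.na(values[, i])]
    if (length(col)) ss <- ss + sum((col - mean(col))^2)
  }
  s2 <- ss / (sum(n) - L)
  t_d <- dunnett_quantile(1 - alpha,
                          dunnett_params(m = L - 1L, df = sum(n) - L, rho = rho))
  flags <- logical(L)
  for (i in seq_len(L)) flags[i] <- (1 - mu[i]) > t_d * sqrt(s2 / n[i])
  flags
}

## Brute-force region enumerator: regex on the 0/1 string. A region is a
## maximal run "1(0{0,2}1)*" (gaps of at most `max_gap` zeros strictly inside),
## kept when it contains at least `min_residues` ones.
brute_force_regions <- function(flags, min_residues = 4L, max_gap = 2L) {
  s <- paste(as.integer(flags %in% TRUE), collapse = "")
  pat <- sprintf("1(0{0,%d}1)*", max_gap)
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(),
                      n_selective = integer()))
  }
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  ones <- vapply(seq_along(starts), function(k) {
    sum(strsplit(substr(s, starts[k], ends[k]), "")[[1]] == "1")
  }, integer(1))
  keep <- ones >= min_residues
  data.frame(start = starts[keep], end = ends[keep], n_selective = ones[keep])
}

## Exhaustive bootstrap over all N^N equally likely resamples: population SD
## of the resampled medians, plus the approximate Monte-Carlo standard error
## of a sample SD of `n_reps` draws (delta method on the 2nd/4th moments).
exhaustive_bootstrap <- function(x, n_reps) {
  n <- length(x)
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n)))
  meds <- apply(idx, 1L, function(i) median(x[i]))
  mu <- mean(meds)
  m2 <- mean((meds - mu)^2)
  m4 <- mean((meds - mu)^4)
  list(sd = sqrt(m2), se_of_sd = sqrt(max(m4 - m2^2, 0) / (4 * m2 * n_reps)))
}

## Write a generated dataset to FASTA + TSV and return the paths.
write_sim <- function(sim, dir = tempfile("sim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "protein.fasta")
  writeLines(c(paste0(">", sim$protein$id), sim$protein$sequence), fasta)
  peptides <- file.path(dir, "peptides.tsv")
  data.table::fwrite(sim$peptides, peptides, sep = "\t")
  list(fasta = fasta, peptides = peptides, dir = dir)
}

## Run the full pipeline on a generated dataset; returns run_pipeline output.
run_sim <- function(sim, outdir = tempfile("out"), ...) {
  paths <- write_sim(sim)
  run_pipeline(run_config(fasta = paths$fasta, peptides = paths$peptides,
                          outdir = outdir, verbose = FALSE, ...))
}
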