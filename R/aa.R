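#' The 20 canonical amino acids
#'
#' One-letter codes in alphabetical order; the row/column universe for every
#' substitution matrix in the package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

## Validate a protein sequence: uppercase, canonical alphabet.
## strict: stop on offending characters; otherwise warn and mask them to "X"
## (masked positions never match any peptide window).
validate_protein_sequence <- function(seq, id = "?", strict = TRUE) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad)) {
    offending <- unique(chars[bad])
    if (strict) {
      stop(sprintf(
        "protein '%s': non-amino-acid character(s) %s at position(s) %s",
        id, paste(sQuote(offending), collapse = ", "),
        paste(head(which(bad), 10L), collapse = ", ")
      ), call. = FALSE)
    }
    warning(sprintf(
      "protein '%s': masking %d non-amino-acid character(s) (%s)",
      id, sum(bad), paste(sQuote(offending), collapse = ", ")
    ), call. = FALSE)
    chars[bad] <- "X"
    seq <- paste(chars, collapse = "")
  }
  if (nchar(seq) == 0L) {
    stop(sprintf("protein '%s': empty sequence", id), call. = FALSE)
  }
  seq
}
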