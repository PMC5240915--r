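#' Read target protein sequences from a FASTA file
#'
#' @param path Path to a (multi-record) amino-acid FASTA file.
#' @param strict If `TRUE` (default) any non-canonical amino-acid character is
#'   an error; otherwise offending characters are masked to `"X"` with a
#'   warning (masked positions can never match a peptide).
#'
#' @return A `data.frame` with columns `id` (first whitespace-delimited token
#'   of the header) and `sequence`, one row per record, input order preserved.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "ACDEFGHIKL"), fa)
#' read_protein_fasta(fa)
read_protein_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ## BStringSet keeps the raw characters so that strict validation can name
  ## offending ones (the AA reader silently drops invalid letters)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  seqs <- as.character(set)
  seqs <- mapply(validate_protein_sequence, seqs, ids,
                 MoreArgs = list(strict = strict), USE.NAMES = FALSE)
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Read a quantitative peptide table
#'
#' Reads a delimited (tab or comma; auto-detected) text file with a header and
#' at least the columns `peptide` and `intensity`; an optional `replicate_id`
#' column is carried through. Rows whose peptide length differs from `length`
#' are dropped with a message reporting the count, mirroring the array-design
#' convention that a single peptide length is analysed per run.
#'
#' @param path Path to the peptide table.
#' @param length Expected peptide length L (default 15).
#' @param on_bad_intensity `"error"` (default) or `"drop"` for rows whose
#'   intensity is missing or not a non-negative number.
#'
#' @return A `data.table` with columns `peptide`, `intensity`,
#'   `replicate_id` (NA if absent), and attribute `dropped_length` holding the
#'   number of wrong-length rows removed.
#' @export
read_peptide_table <- function(path, length = 15L,
                               on_bad_intensity = c("error", "drop")) {
  on_bad_intensity <- match.arg(on_bad_intensity)
  if (!file.exists(path)) stop("peptide table not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = "peptide"))
  need <- c("peptide", "intensity")
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0L) {
    stop("peptide table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!("replicate_id" %in% names(dt))) dt[, replicate_id := NA_character_]
  dt <- dt[, .(peptide = toupper(peptide),
               intensity = suppressWarnings(as.numeric(intensity)),
               replicate_id = as.character(replicate_id))]
  bad_int <- is.na(dt$intensity) | dt$intensity < 0
  if (any(bad_int)) {
    if (on_bad_intensity == "error") {
      stop(sprintf("%d row(s) with missing/negative intensity (first at row %d)",
                   sum(bad_int), which(bad_int)[1L]), call. = FALSE)
    }
    message(sprintf("dropping %d row(s) with missing/negative intensity", sum(bad_int)))
    dt <- dt[!bad_int]
  }
  wrong_len <- nchar(dt$peptide) != length
  if (any(wrong_len)) {
    message(sprintf("dropping %d peptide(s) with length != %d", sum(wrong_len), length))
    dt <- dt[!wrong_len]
  }
  if (nrow(dt) == 0L) stop("no usable peptide rows after filtering", call. = FALSE)
  data.table::setattr(dt, "dropped_length", sum(wrong_len))
  dt[]
}
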