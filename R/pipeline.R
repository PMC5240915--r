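## Cache for Dunnett critical values: the same (p, m, df, rho) recurs for
## every peptide of a given design, and the quantile is deterministic.
.dunnett_cache <- new.env(parent = emptyenv())

dunnett_quantile_cached <- function(p, params) {
  key <- paste(format(p, digits = 17), params$m, format(params$df),
               params$rho, sep = "|")
  got <- get0(key, envir = .dunnett_cache, inherits = FALSE)
  if (!is.null(got)) return(got)
  val <- dunnett_quantile(p, params)
  assign(key, val, envir = .dunnett_cache)
  val
}

#' Per-peptide epitope calls for all native peptides
#'
#' Builds the PSSM of every native peptide with substitution data and applies
#' [call_epitope_positions()]. Peptides with too few substitution values for a
#' pooled variance (the alanine-scan degenerate case) are reported as not
#' callable.
#'
#' @param subs Output of [substitution_records()].
#' @param groups Output of [native_groups()].
#' @param alpha Significance level (default 1e-4).
#' @param rho Dunnett correlation (default 0.5).
#' @return A list: `table` (`data.table` with `protein_id`, `position`,
#'   `peptide`, `epitope` dashed string, `native_median`, `callable`),
#'   `flags` (long `data.table` of `protein_id`, `offset`, `frame_pos`,
#'   `flag`), `calls` (named list of `"epitope_call"` objects keyed
#'   `"<protein_id>:<offset>"`), and `n_callable`.
#' @export
peptide_epitope_calls <- function(subs, groups, alpha = 1e-4, rho = 0.5) {
  keys <- unique(subs[, .(protein_id, offset)])
  data.table::setkey(keys, protein_id, offset)
  calls <- vector("list", nrow(keys))
  names(calls) <- paste0(keys$protein_id, ":", keys$offset)
  tab <- vector("list", nrow(keys))
  flg <- vector("list", nrow(keys))
  sub_split <- split(subs, by = c("protein_id", "offset"), sorted = TRUE)
  for (k in seq_len(nrow(keys))) {
    pid <- keys$protein_id[k]; off <- keys$offset[k]
    g <- groups[.(pid, off)]
    recs <- sub_split[[paste(pid, off, sep = ".")]]
    pssm <- build_pssm(recs, g$native_sequence)
    L <- nchar(g$native_sequence)
    call <- call_epitope_positions(pssm, alpha = alpha, rho = rho)
    calls[[k]] <- call
    tab[[k]] <- data.table::data.table(
      protein_id = pid, position = off, peptide = g$native_sequence,
      epitope = if (call$callable)
        format_epitope_string(g$native_sequence, call$flags) else NA_character_,
      native_median = g$reference, callable = call$callable)
    flg[[k]] <- data.table::data.table(
      protein_id = pid, offset = off, frame_pos = seq_len(L),
      flag = call$flags)
  }
  list(table = data.table::rbindlist(tab),
       flags = data.table::rbindlist(flg),
       calls = calls,
       n_callable = sum(vapply(calls, `[[`, logical(1L), "callable")))
}

#' Residue-level selectivity across a whole protein
#'
#' Runs [build_residue_matrix()], [selectivity_stats()] and [logo_scores()]
#' for every residue of one protein and calls gap-tolerant epitope regions.
#'
#' @param protein One row of [read_protein_fasta()] output (`id`, `sequence`).
#' @param subs [substitution_records()] rows for this protein.
#' @param native_ratios [native_copy_ratios()] rows for this protein.
#' @param calls_flags The `flags` table from [peptide_epitope_calls()] for
#'   this protein (ignored when `inclusion_mode = "all"`).
#' @param length Peptide length L.
#' @param alpha Significance level (default 1e-4).
#' @param rho Dunnett correlation (default 0.5).
#' @param inclusion_mode `"position"` (default), `"peptide"`, or `"all"`
#'   (used automatically for alanine-scan data, which has no per-peptide
#'   calls).
#' @param min_region_length,max_gap Region-calling thresholds (defaults 4, 2).
#' @return A list: `table` (per-residue `data.table`: `protein_id`, `position`,
#'   `native_aa`, `mu_g`, `selective`, `m`, `df`), `logo` (P x 20 matrix of
#'   rescaled scores, zero rows at non-selective positions), `p_values`
#'   (P x 20 matrix), `selective` (logical vector), `regions`
#'   ([call_epitope_regions()] table), `profiles` (list of
#'   `"selectivity_profile"`).
#' @export
residue_selectivity_profiles <- function(protein, subs, native_ratios,
                                         calls_flags, length = 15L,
                                         alpha = 1e-4, rho = 0.5,
                                         inclusion_mode = c("position", "peptide", "all"),
                                         min_region_length = 4L, max_gap = 2L) {
  inclusion_mode <- match.arg(inclusion_mode)
  P <- nchar(protein$sequence)
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1L]]
  if (inclusion_mode == "all") {
    ## every covering peptide is included: synthesise all-TRUE flags
    offs <- sort(unique(c(subs$offset, native_ratios$offset)))
    calls_flags <- data.table::CJ(offset = offs, frame_pos = seq_len(length))
    calls_flags[, flag := TRUE]
    mode_used <- "position"
  } else {
    calls_flags <- calls_flags[, .(offset, frame_pos, flag)]
    mode_used <- inclusion_mode
  }
  logo <- matrix(0, nrow = P, ncol = 20L,
                 dimnames = list(seq_len(P), AA_ALPHABET))
  pv <- matrix(NA_real_, nrow = P, ncol = 20L,
               dimnames = list(seq_len(P), AA_ALPHABET))
  selective <- logical(P)
  profiles <- vector("list", P)
  tab <- vector("list", P)
  for (pos in seq_len(P)) {
    rsm <- build_residue_matrix(pos, subs, native_ratios, calls_flags,
                                length = length, inclusion_mode = mode_used)
    prof <- selectivity_stats(rsm, alpha = alpha, rho = rho)
    profiles[[pos]] <- prof
    selective[pos] <- prof$selective
    if (prof$selective) {
      logo[pos, ] <- logo_scores(prof)
    }
    if (nrow(prof$stats) > 0L) {
      pv[pos, prof$stats$aa] <- prof$stats$p
    }
    tab[[pos]] <- data.table::data.table(
      protein_id = protein$id, position = pos, native_aa = chars[pos],
      mu_g = prof$mu_g, selective = prof$selective,
      m = prof$m, df = prof$df)
  }
  regions <- call_epitope_regions(selective, min_residues = min_region_length,
                                  max_gap = max_gap,
                                  sequence = protein$sequence)
  list(table = data.table::rbindlist(tab), logo = logo, p_values = pv,
       selective = selective, regions = regions, profiles = profiles)
}

#' Run configuration for the full analysis pipeline
#'
#' @param fasta Path to the protein FASTA file.
#' @param peptides Path to the peptide intensity table.
#' @param outdir Output directory (created if missing).
#' @param alpha Significance level (default 1e-4).
#' @param length Peptide length L (default 15).
#' @param inclusion_mode Frame-inclusion rule for residue matrices
#'   (default `"position"`).
#' @param min_region_length,max_gap Region thresholds (defaults 4, 2).
#' @param floor Intensity floor in Au (default 1).
#' @param min_native_intensity Optional native-reference filter (default 0 = off).
#' @param bootstrap_reps Bootstrap resamples for the native-signal QC SE
#'   (default 0 = off).
#' @param seed Integer seed for the bootstrap (default 1).
#' @param strict_fasta Passed to [read_protein_fasta()].
#' @param verbose Emit progress messages (default TRUE).
#' @return An object of class `"run_config"` (a list).
#' @export
run_config <- function(fasta, peptides, outdir, alpha = 1e-4, length = 15L,
                       inclusion_mode = "position", min_region_length = 4L,
                       max_gap = 2L, floor = 1, min_native_intensity = 0,
                       bootstrap_reps = 0L, seed = 1L, strict_fasta = TRUE,
                       verbose = TRUE) {
  stopifnot(alpha > 0, alpha < 1, length >= 2L)
  structure(list(fasta = fasta, peptides = peptides, outdir = outdir,
                 alpha = alpha, length = as.integer(length),
                 inclusion_mode = inclusion_mode,
                 min_region_length = as.integer(min_region_length),
                 max_gap = as.integer(max_gap), floor = floor,
                 min_native_intensity = min_native_intensity,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed), strict_fasta = strict_fasta,
                 verbose = verbose),
            class = "run_config")
}

#' Run the full epitope-mapping pipeline
#'
#' Executes mapping, substitution-value rescaling, per-peptide epitope
#' calling, residue-level selectivity analysis and region calling, and writes
#' the report files to `config$outdir`:
#' \describe{
#'   \item{peptide_calls.tsv}{per-peptide dashed epitope strings with native
#'     median intensities (omitted for alanine-scan data, with a log note)}
#'   \item{selectivity.tsv}{per-residue global mean, selectivity call, and
#'     per-amino-acid logo score and p-value}
#'   \item{logo_matrix.tsv}{P x 20 rescaled logo-score matrix per protein}
#'   \item{regions.tsv}{gap-tolerant epitope regions (Range, Region)}
#'   \item{run_log.txt}{parameter echo, drop and ambiguity counts}
#' }
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with per-protein results (`peptide_calls`,
#'   `selectivity`, `regions`, `groups`, `mapped` counts) and `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  log_lines <- c(sprintf("episcan run %s", format(Sys.time())),
                 sprintf("alpha=%g length=%d inclusion_mode=%s floor=%g seed=%d",
                         config$alpha, config$length, config$inclusion_mode,
                         config$floor, config$seed),
                 sprintf("min_region_length=%d max_gap=%d min_native_intensity=%g bootstrap_reps=%d",
                         config$min_region_length, config$max_gap,
                         config$min_native_intensity, config$bootstrap_reps))

  proteins <- read_protein_fasta(config$fasta, strict = config$strict_fasta)
  peptides <- read_peptide_table(config$peptides, length = config$length)
  log_lines <- c(log_lines,
                 sprintf("proteins=%d peptides=%d dropped_wrong_length=%d",
                         nrow(proteins), nrow(peptides),
                         attr(peptides, "dropped_length")))

  mapped <- map_peptides(peptides, proteins, length = config$length)
  counts <- table(factor(mapped$variant_kind,
                         levels = c("native", "substitution", "ambiguous", "unmapped")))
  log_lines <- c(log_lines, sprintf(
    "mapped: native=%d substitution=%d ambiguous=%d unmapped=%d",
    counts["native"], counts["substitution"], counts["ambiguous"], counts["unmapped"]))
  if (counts["native"] + counts["substitution"] == 0L) {
    stop("run_pipeline: no peptide could be mapped to the supplied proteins",
         call. = FALSE)
  }

  groups <- native_groups(mapped, bootstrap_reps = config$bootstrap_reps,
                          seed = config$seed)
  subs <- substitution_records(mapped, groups, floor = config$floor,
                               min_native_intensity = config$min_native_intensity)
  ratios <- native_copy_ratios(mapped, groups, floor = config$floor)

  pep <- peptide_epitope_calls(subs, groups, alpha = config$alpha)
  alanine_like <- pep$n_callable == 0L
  if (alanine_like) {
    say("single-substitution (alanine-scan-like) data: per-peptide epitope table not produced")
    log_lines <- c(log_lines,
                   "single-substitution data detected: peptide_calls.tsv omitted; all covering frames enter the residue matrices")
  }

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (!alanine_like) {
    f <- file.path(config$outdir, "peptide_calls.tsv")
    data.table::fwrite(pep$table[callable == TRUE,
                                 .(protein_id, position, peptide, epitope,
                                   native_median)],
                       f, sep = "\t")
    files <- c(files, peptide_calls = f)
  }

  sel_tabs <- list(); logo_tabs <- list(); region_tabs <- list()
  results <- list()
  for (k in seq_len(nrow(proteins))) {
    pid <- proteins$id[k]
    res <- residue_selectivity_profiles(
      proteins[k, ], subs[protein_id == pid], ratios[protein_id == pid],
      pep$flags[protein_id == pid], length = config$length,
      alpha = config$alpha,
      inclusion_mode = if (alanine_like) "all" else config$inclusion_mode,
      min_region_length = config$min_region_length, max_gap = config$max_gap)
    sel <- res$table
    ## attach logo scores and p-values as aa-named columns
    logo_dt <- data.table::as.data.table(res$logo)
    data.table::setnames(logo_dt, paste0("s_", AA_ALPHABET))
    p_dt <- data.table::as.data.table(res$p_values)
    data.table::setnames(p_dt, paste0("p_", AA_ALPHABET))
    sel_tabs[[k]] <- cbind(sel, logo_dt, p_dt)
    lt <- data.table::data.table(protein_id = pid,
                                 position = seq_len(nrow(res$logo)))
    logo_tabs[[k]] <- cbind(lt, data.table::as.data.table(res$logo))
    if (nrow(res$regions) > 0L) {
      region_tabs[[k]] <- data.table::data.table(
        protein_id = pid,
        range = sprintf("%d-%d", res$regions$start, res$regions$end),
        region = res$regions$region)
    }
    results[[pid]] <- res
    log_lines <- c(log_lines, sprintf(
      "%s: selective_residues=%d regions=%d", pid, sum(res$selective),
      nrow(res$regions)))
  }
  f_sel <- file.path(config$outdir, "selectivity.tsv")
  data.table::fwrite(data.table::rbindlist(sel_tabs), f_sel, sep = "\t")
  f_logo <- file.path(config$outdir, "logo_matrix.tsv")
  data.table::fwrite(data.table::rbindlist(logo_tabs), f_logo, sep = "\t")
  f_reg <- file.path(config$outdir, "regions.tsv")
  reg_all <- if (length(region_tabs)) data.table::rbindlist(region_tabs) else
    data.table::data.table(protein_id = character(), range = character(),
                           region = character())
  data.table::fwrite(reg_all, f_reg, sep = "\t")
  f_log <- file.path(config$outdir, "run_log.txt")
  writeLines(log_lines, f_log)
  files <- c(files, selectivity = f_sel, logo_matrix = f_logo,
             regions = f_reg, run_log = f_log)

  invisible(list(proteins = proteins, mapped_counts = as.list(counts),
                 groups = groups, peptide_calls = pep, residues = results,
                 regions = reg_all, alanine_like = alanine_like,
                 files = files, config = config))
}
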