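## PSM tables: the score-table interface between search engines and the
## validation machinery. A PSM table is a data.frame with one row per
## candidate peptide-spectrum match:
##   spectrum_id  character, one id per query/spectrum
##   peptide      amino-acid string
##   proteins     semicolon-separated accessions the peptide maps to
##   score        numeric, higher is better
##   is_decoy     logical, TRUE iff all mapped accessions are decoys
##   rank         integer pretty rank (1 after prefiltering)
## Metadata (database identifier, search label) travels in attributes.

#' Construct a PSM table
#'
#' A candidate match whose protein list mixes target and decoy accessions
#' is classified as a target and its decoy accessions are dropped:
#' reversed tryptic peptides occasionally coincide with target sequences,
#' and counting such matches as decoys would inflate the decoy count used
#' by target-decoy competition.
#'
#' @param spectrum_id character vector of spectrum/query identifiers.
#' @param peptide character vector of peptide sequences.
#' @param proteins character vector of semicolon-separated accessions.
#' @param score numeric vector of search scores (finite, higher is better).
#' @param is_decoy optional logical; when `NULL`, inferred from
#'   `decoy_prefix` on every mapped accession.
#' @param rank optional integer pretty rank (default 1).
#' @param decoy_prefix accession prefix marking decoys.
#' @param database,label optional metadata strings.
#' @return a `psm_table` data.frame.
#' @export
psm_table <- function(spectrum_id, peptide, proteins, score,
                      is_decoy = NULL, rank = 1L, decoy_prefix = "rev_",
                      database = NA_character_, label = NA_character_) {
  n <- length(spectrum_id)
  spectrum_id <- as.character(spectrum_id)
  peptide <- as.character(peptide)
  proteins <- as.character(proteins)
  score <- as.numeric(score)
  if (length(peptide) == 1L) peptide <- rep_len(peptide, n)
  if (length(proteins) == 1L) proteins <- rep_len(proteins, n)
  if (length(peptide) != n || length(proteins) != n || length(score) != n)
    stop_("spectrum_id, peptide, proteins and score must have equal length")
  if (any(!is.finite(score)))
    stop_("non-finite score at row(s): ",
          paste(utils::head(which(!is.finite(score)), 5L), collapse = ", "))
  if (any(!nzchar(peptide)))
    stop_("empty peptide sequence at row(s): ",
          paste(utils::head(which(!nzchar(peptide)), 5L), collapse = ", "))
  if (any(!nzchar(proteins)))
    stop_("empty protein field at row(s): ",
          paste(utils::head(which(!nzchar(proteins)), 5L), collapse = ", "))
  prot_list <- strsplit(proteins, ";", fixed = TRUE)
  if (is.null(is_decoy)) {
    dec <- lapply(prot_list, startsWith, prefix = decoy_prefix)
    is_decoy <- vapply(dec, all, NA)
    mixed <- vapply(dec, any, NA) & !is_decoy
    if (any(mixed)) {
      # target/decoy mixture: resolve to target, drop decoy accessions
      prot_list[mixed] <- Map(function(p, d) p[!d],
                              prot_list[mixed], dec[mixed])
      proteins[mixed] <- vapply(prot_list[mixed], paste, "", collapse = ";")
    }
  } else {
    is_decoy <- rep_len(as.logical(is_decoy), n)
  }
  out <- data.frame(
    spectrum_id = spectrum_id, peptide = peptide, proteins = proteins,
    score = score, is_decoy = is_decoy,
    rank = rep_len(as.integer(rank), n),
    stringsAsFactors = FALSE
  )
  attr(out, "database") <- database
  attr(out, "label") <- label
  class(out) <- c("psm_table", "data.frame")
  out
}

#' Read a PSM table from TSV
#'
#' Expected header columns: `spectrum_id`, `peptide`, `proteins`
#' (semicolon-separated accessions), `score`, and optionally `is_decoy`.
#' Gzip-compressed files are read transparently.
#'
#' @param path path to the TSV file.
#' @param decoy_prefix accession prefix used to infer `is_decoy` when the
#'   column is absent.
#' @return a [psm_table].
#' @export
read_psm_table <- function(path, decoy_prefix = "rev_") {
  if (!file.exists(path)) stop_("PSM table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  required <- c("spectrum_id", "peptide", "proteins", "score")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_("missing required column(s) in ", path, ": ",
          paste(missing, collapse = ", "))
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score) & nzchar(df$score))
  bad <- union(bad, which(!nzchar(df$score)))
  if (length(bad))
    stop_("unparseable score at data row(s): ",
          paste(utils::head(sort(bad), 5L), collapse = ", "))
  is_decoy <- NULL
  if ("is_decoy" %in% names(df))
    is_decoy <- toupper(df$is_decoy) %in% c("TRUE", "T", "1")
  rank <- if ("rank" %in% names(df)) as.integer(df$rank) else 1L
  psm_table(df$spectrum_id, df$peptide, df$proteins, score,
            is_decoy = is_decoy, rank = rank, decoy_prefix = decoy_prefix)
}

#' Write a PSM table to TSV
#'
#' UTF-8, tab-separated, `.` decimal mark, with header; round-trips
#' through [read_psm_table()].
#'
#' @param table a [psm_table].
#' @param path output file path (use a `.gz` suffix to compress).
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(table, path) {
  stopifnot(inherits(table, "psm_table"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", dec = ".")
  invisible(path)
}

#' Apply PSM validation prefilters
#'
#' Reproduces the standard post-search validation sequence: (i) candidate
#' PSMs of a spectrum whose score lies strictly within `tie_tolerance` of
#' the spectrum's best score share "pretty rank" 1; (ii) a single
#' rank-1 PSM is retained per spectrum, chosen uniformly at random among
#' the rank-1 ties (seeded, hence reproducible; preferring targets would
#' bias the target-decoy competition); (iii) spectra whose retained
#' peptide is shorter than `min_len` residues are removed entirely.
#'
#' The operation is idempotent: a table with one rank-1 PSM per spectrum
#' and all peptides of length at least `min_len` passes unchanged.
#'
#' @param table a [psm_table], possibly with several candidates per
#'   spectrum.
#' @param tie_tolerance score difference below which two candidates are
#'   considered of equal score (default 0.1, strict comparison).
#' @param min_len minimum retained peptide length (default 7).
#' @param seed integer seed for the tie-break draw.
#' @return a [psm_table] with at most one PSM per spectrum, all with
#'   `rank == 1`.
#' @export
apply_prefilters <- function(table, tie_tolerance = 0.1, min_len = 7L,
                             seed = 1L) {
  stopifnot(inherits(table, "psm_table"))
  if (tie_tolerance < 0) stop_("'tie_tolerance' must be >= 0")
  if (min_len < 1) stop_("'min_len' must be >= 1")
  if (nrow(table) == 0L) return(table)
  keep <- with_seed(seed, {
    idx <- split(seq_len(nrow(table)), table$spectrum_id)
    vapply(idx, function(i) {
      best <- max(table$score[i])
      rank1 <- i[best - table$score[i] < tie_tolerance]
      if (length(rank1) == 1L) rank1 else rank1[sample.int(length(rank1), 1L)]
    }, 0L)
  })
  out <- table[sort(keep), , drop = FALSE]
  out <- out[nchar(out$peptide) >= min_len, , drop = FALSE]
  out$rank <- 1L
  rownames(out) <- NULL
  attr(out, "database") <- attr(table, "database")
  attr(out, "label") <- attr(table, "label")
  class(out) <- c("psm_table", "data.frame")
  out
}

#' @export
print.psm_table <- function(x, ...) {
  cat(sprintf("psm_table: %d PSMs, %d spectra (%d decoy PSMs)\n",
              nrow(x), length(unique(x$spectrum_id)), sum(x$is_decoy)))
  NextMethod()
}
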