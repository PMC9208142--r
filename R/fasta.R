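## Protein database I/O and decoy generation.
##
## A protein database is represented as a plain data.frame with columns
## accession, sequence, is_decoy, is_contaminant, one row per record.
## FASTA parsing and writing are delegated to Biostrings; validation of
## the database invariants (unique accessions, amino-acid alphabet) is
## performed here.

#' Amino-acid letters accepted in database sequences
#'
#' The 20 canonical residues plus the ambiguity/extension codes X, B, Z
#' and U (selenocysteine), which occur in Ensembl protein dumps.
#' @keywords internal
.aa_alphabet <- "ACDEFGHIKLMNPQRSTVWYXBZU"

#' Construct a protein database
#'
#' @param accession character vector of unique, non-empty accessions.
#' @param sequence character vector of amino-acid sequences (uppercased).
#' @param is_decoy,is_contaminant logical vectors (recycled if length 1).
#' @return a `protein_db` data.frame with columns `accession`, `sequence`,
#'   `is_decoy`, `is_contaminant`.
#' @export
protein_db <- function(accession, sequence, is_decoy = FALSE,
                       is_contaminant = FALSE) {
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  if (length(accession) != length(sequence))
    stop_("'accession' and 'sequence' must have the same length")
  if (any(!nzchar(accession)))
    stop_("empty accession in protein database")
  dup <- accession[duplicated(accession)]
  if (length(dup))
    stop_("duplicate accession(s) in protein database: ",
          paste(unique(dup), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop_("zero-length sequence for accession(s): ",
          paste(accession[!nzchar(sequence)], collapse = ", "))
  bad <- grepl(sprintf("[^%s]", .aa_alphabet), sequence)
  if (any(bad))
    stop_("non-amino-acid characters in sequence of: ",
          paste(accession[bad], collapse = ", "))
  db <- data.frame(
    accession = accession,
    sequence = sequence,
    is_decoy = rep_len(as.logical(is_decoy), length(accession)),
    is_contaminant = rep_len(as.logical(is_contaminant), length(accession)),
    stringsAsFactors = FALSE
  )
  class(db) <- c("protein_db", "data.frame")
  db
}

#' Read a protein database from a FASTA file
#'
#' The accession is the first whitespace-delimited token of each header.
#' Decoy and contaminant status are inferred from configurable accession
#' prefixes. Gzip-compressed files are read transparently.
#'
#' @param path path to a (possibly gzipped) FASTA file.
#' @param decoy_prefix accession prefix marking decoy records.
#' @param contaminant_prefix accession prefix marking contaminant records.
#' @return a [protein_db] data.frame.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 example", "MKV", ">P2", "AAAA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, decoy_prefix = "rev_",
                       contaminant_prefix = "CON_") {
  if (!file.exists(path)) stop_("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop_("empty FASTA file: ", path)
  acc <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[`, "", 1L)
  protein_db(
    accession = acc,
    sequence = as.character(seqs),
    is_decoy = startsWith(acc, decoy_prefix),
    is_contaminant = startsWith(acc, contaminant_prefix)
  )
}

#' Write a protein database to FASTA
#'
#' Sequences are wrapped at 60 characters per line.
#'
#' @param db a [protein_db].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  stopifnot(inherits(db, "protein_db"))
  x <- Biostrings::BStringSet(db$sequence)
  names(x) <- db$accession
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Generate a reversed-sequence decoy database
#'
#' One decoy per target record; the decoy sequence is the full reversal of
#' the target sequence and the decoy accession is `prefix` prepended to the
#' target accession, so the output has exactly as many records as the
#' input. Reversal preserves length and amino-acid composition, and
#' applying it twice recovers the target.
#'
#' @param db a [protein_db] containing only target records.
#' @param prefix decoy accession prefix (default `"rev_"`).
#' @return a [protein_db] of decoy records.
#' @examples
#' db <- protein_db("P1", "MKVR")
#' generate_decoys(db)$sequence  # "RVKM"
#' @export
generate_decoys <- function(db, prefix = "rev_") {
  stopifnot(inherits(db, "protein_db"))
  if (any(db$is_decoy))
    stop_("database already contains decoy records")
  rev_seq <- as.character(Biostrings::reverse(Biostrings::BStringSet(db$sequence)))
  protein_db(
    accession = paste0(prefix, db$accession),
    sequence = rev_seq,
    is_decoy = TRUE,
    is_contaminant = db$is_contaminant
  )
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("protein_db: %d records (%d decoy, %d contaminant)\n",
              nrow(x), sum(x$is_decoy), sum(x$is_contaminant)))
  NextMethod()
}
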