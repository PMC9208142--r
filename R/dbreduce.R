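## Transcriptome-informed reduction of protein databases: subset a
## reference FASTA to the proteins whose transcript is expressed above an
## FPKM threshold in the sample-matched transcriptome.

#' Strip Ensembl-style version suffixes from identifiers
#'
#' `ENST00000456328.2` becomes `ENST00000456328`. Applied to both
#' expression tables and mapping tables before matching, since Ensembl
#' dumps are inconsistent about versions across releases.
#'
#' @param id character vector of identifiers.
#' @return character vector without trailing `.<digits>`.
#' @export
strip_id_version <- function(id) sub("\\.\\d+$", "", id)

#' Read a transcript expression table
#'
#' Two tab-separated columns with header: `transcript_id` and `fpkm`
#' (case-insensitive; `FPKM` accepted). Identifier versions are stripped.
#'
#' @param path path to the (possibly gzipped) TSV file.
#' @return a data.frame with columns `transcript_id`, `fpkm`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_("expression table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE)
  names(df) <- tolower(names(df))
  if (!all(c("transcript_id", "fpkm") %in% names(df)))
    stop_("expression table must have columns transcript_id and fpkm")
  df$transcript_id <- strip_id_version(as.character(df$transcript_id))
  df$fpkm <- as.numeric(df$fpkm)
  if (any(!is.finite(df$fpkm)) || any(df$fpkm < 0))
    stop_("FPKM values must be finite and non-negative")
  if (anyDuplicated(df$transcript_id))
    stop_("duplicate transcript_id in expression table")
  df[c("transcript_id", "fpkm")]
}

#' Read a protein-to-transcript mapping table
#'
#' Tab-separated with header columns `protein_id`, `transcript_id` and
#' optionally `gene_id`. A protein may map to several transcripts (one
#' pair per row). Identifier versions are stripped.
#'
#' @param path path to the (possibly gzipped) TSV file.
#' @return a data.frame with columns `protein_id`, `transcript_id` and,
#'   when present, `gene_id`.
#' @export
read_protein_map <- function(path) {
  if (!file.exists(path)) stop_("mapping table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  names(df) <- tolower(names(df))
  if (!all(c("protein_id", "transcript_id") %in% names(df)))
    stop_("mapping table must have columns protein_id and transcript_id")
  df$protein_id <- strip_id_version(df$protein_id)
  df$transcript_id <- strip_id_version(df$transcript_id)
  df[intersect(c("protein_id", "transcript_id", "gene_id"), names(df))]
}

#' Transcripts expressed above an FPKM threshold
#'
#' Strictly greater-than comparison: a transcript at exactly the
#' threshold is not called expressed.
#'
#' @param expr expression data.frame as from [read_expression()].
#' @param threshold FPKM threshold (default 1).
#' @return character vector of expressed transcript identifiers.
#' @export
expressed_transcripts <- function(expr, threshold = 1) {
  stopifnot(is.data.frame(expr),
            all(c("transcript_id", "fpkm") %in% names(expr)))
  expr$transcript_id[expr$fpkm > threshold]
}

#' Proteins with at least one expressed transcript
#'
#' @param expr expression data.frame ([read_expression()]).
#' @param map protein-to-transcript mapping ([read_protein_map()]).
#' @param threshold FPKM threshold (default 1, strict).
#' @return character vector of protein accessions with transcript support.
#' @export
expressed_proteins <- function(expr, map, threshold = 1) {
  tids <- expressed_transcripts(expr, threshold)
  unique(map$protein_id[map$transcript_id %in% tids])
}

#' Build a reduced transcriptome-informed protein database
#'
#' Retains from a reference (target-only) database the proteins for which
#' at least one mapped transcript is expressed above the FPKM threshold.
#' The output is a plain subset of the input: record identity, including
#' sequences, is untouched, so decoys for the reduced database are meant
#' to be generated afterwards from the reduced set. Proteins absent from
#' the mapping table are dropped, with a message reporting how many.
#'
#' @param db a [protein_db] of target records.
#' @param expr expression data.frame ([read_expression()]).
#' @param map protein-to-transcript mapping ([read_protein_map()]).
#' @param threshold FPKM threshold (default 1, strict).
#' @return a [protein_db] subset of `db`; error if nothing is retained.
#' @export
reduce_database <- function(db, expr, map, threshold = 1) {
  stopifnot(inherits(db, "protein_db"))
  if (any(db$is_decoy))
    stop_("reduce the target database before generating decoys")
  supported <- expressed_proteins(expr, map, threshold)
  unmapped <- !(db$accession %in% map$protein_id)
  if (any(unmapped))
    message(sum(unmapped),
            " protein(s) absent from the mapping table were dropped")
  keep <- db$accession %in% supported
  if (!any(keep))
    stop_("reduced database is empty: no protein has an expressed transcript")
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_db", "data.frame")
  out
}
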