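## Transcriptome-informed post hoc filtering of full-database
## identifications. Instead of searching a reduced database, the full
## search's peptide-protein incidence is pruned of proteins lacking
## transcript support, under one of three rules of increasing caution:
##
##  option 1: remove proteins with no expressed transcript, then remove
##            the peptides left mapping only to removed proteins;
##  option 2: remove proteins with no expressed transcript AND no
##            specific peptide, then remove the peptides only shared
##            between removed proteins;
##  option 3: as option 2, but a protein is only removed if every one of
##            its peptides is shared with at least one retained protein,
##            so no peptide identification is ever lost.
##
## Option 3's "retained" is self-referential; it is resolved as a
## deterministic fixed point (see posthoc_filter).

#' Transcriptome-informed post hoc filter
#'
#' Prunes a peptide-protein incidence matrix of proteins without
#' transcript support. Specificity (a peptide mapping to exactly one
#' protein) is always evaluated on the unfiltered input matrix. Under
#' option 3 the removable set is computed as a fixed point: all
#' no-transcript/no-specific candidates start marked for removal, and any
#' marked protein owning a peptide whose other parents are all currently
#' marked is unmarked; the pass repeats until stable. Each pass unmarks
#' every violator simultaneously, so the result does not depend on
#' protein order. All three options are idempotent, their removal sets
#' are nested (option 1 >= option 2 >= option 3), and option 3 never
#' removes a peptide.
#'
#' @param I incidence matrix from [build_incidence()].
#' @param expressed character vector of protein accessions with
#'   transcript support (see [expressed_proteins()]).
#' @param option filtering rule, 1, 2 or 3 (default 2, the most common
#'   compromise: transcript evidence or a specific peptide rescues a
#'   protein).
#' @return a list of class `posthoc_filter` with elements `option`,
#'   `removed_proteins`, `removed_peptides` and `incidence` (the retained
#'   matrix).
#' @export
posthoc_filter <- function(I, expressed, option = 2L) {
  option <- as.integer(option)
  if (!option %in% 1:3) stop_("'option' must be 1, 2 or 3")
  prot <- colnames(I)
  pep <- rownames(I)
  no_expr <- !(prot %in% expressed)
  specific <- Matrix::rowSums(I) == 1
  has_specific <- Matrix::colSums(I[specific, , drop = FALSE]) > 0

  removed <- if (option == 1L) {
    no_expr
  } else if (option == 2L) {
    no_expr & !has_specific
  } else {
    cand <- no_expr & !has_specific
    marked <- cand
    repeat {
      if (!any(marked)) break
      # peptides whose every parent is currently marked for removal
      orphan <- Matrix::rowSums(I[, marked, drop = FALSE]) ==
        Matrix::rowSums(I)
      if (!any(orphan)) break
      # unmark, simultaneously, every marked protein owning such a peptide
      violator <- marked &
        Matrix::colSums(I[orphan, , drop = FALSE]) > 0
      if (!any(violator)) break
      marked <- marked & !violator
    }
    marked
  }

  if (option == 3L) {
    removed_pep <- logical(length(pep))
  } else {
    removed_pep <- Matrix::rowSums(I[, removed, drop = FALSE]) ==
      Matrix::rowSums(I)
  }
  out <- I[!removed_pep, !removed, drop = FALSE]
  structure(
    list(option = option,
         removed_proteins = prot[removed],
         removed_peptides = pep[removed_pep],
         incidence = out),
    class = "posthoc_filter"
  )
}

#' @export
print.posthoc_filter <- function(x, ...) {
  cat(sprintf(
    "posthoc_filter (option %d): removed %d protein(s), %d peptide(s); retained %d x %d incidence\n",
    x$option, length(x$removed_proteins), length(x$removed_peptides),
    nrow(x$incidence), ncol(x$incidence)))
  invisible(x)
}
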