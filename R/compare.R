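## Spectrum-level comparison of two searches of the same spectra against
## a full and a reduced protein database: classify per-spectrum match
## pairs, count reallocations, decompose the reduced search's additional
## identifications into lower-cutoff effects versus "pure reallocations",
## and account for the loss of valid decoys under a transferred cutoff.

#' Pair the PSMs of two searches spectrum by spectrum
#'
#' Each spectrum appearing in either prefiltered table yields one row;
#' the side where the spectrum found no match is `NO_MATCH`. A pair is a
#' reallocation when both sides matched but to different peptides.
#'
#' @param full,reduced prefiltered [psm_table]s (at most one PSM per
#'   spectrum each).
#' @return a data.frame of class `match_pairs` with columns
#'   `spectrum_id`, `full_kind`, `full_peptide`, `full_score`,
#'   `reduced_kind`, `reduced_peptide`, `reduced_score`, `reallocated`.
#' @export
pair_searches <- function(full, reduced) {
  stopifnot(inherits(full, "psm_table"), inherits(reduced, "psm_table"))
  for (nm in c("full", "reduced")) {
    tab <- get(nm)
    if (anyDuplicated(tab$spectrum_id))
      stop_("duplicate spectrum_id in '", nm, "' table; apply prefilters first")
  }
  side <- function(tab, prefix) {
    out <- data.frame(
      spectrum_id = tab$spectrum_id,
      kind = ifelse(tab$is_decoy, "DECOY", "TARGET"),
      peptide = tab$peptide,
      score = tab$score,
      stringsAsFactors = FALSE
    )
    names(out)[-1L] <- paste0(prefix, "_", names(out)[-1L])
    out
  }
  pairs <- merge(side(full, "full"), side(reduced, "reduced"),
                 by = "spectrum_id", all = TRUE, sort = TRUE)
  pairs$full_kind[is.na(pairs$full_kind)] <- "NO_MATCH"
  pairs$reduced_kind[is.na(pairs$reduced_kind)] <- "NO_MATCH"
  pairs$reallocated <- pairs$full_kind != "NO_MATCH" &
    pairs$reduced_kind != "NO_MATCH" &
    pairs$full_peptide != pairs$reduced_peptide
  class(pairs) <- c("match_pairs", "data.frame")
  pairs
}

#' Summarise reallocation score changes
#'
#' Counts reallocations whose reduced-search score is lower than, equal
#' to, or higher than the full-search score, split by the kind of match
#' in the reduced search, and flags reallocations onto targets with a
#' score increase. When the reduced database is a subset of the full one,
#' no target reallocation can gain score, so the flagged set is expected
#' to be empty in that regime.
#'
#' @param pairs a `match_pairs` data.frame.
#' @return a list with the count matrix `counts`
#'   (rows lower/equal/higher, columns TARGET/DECOY) and
#'   `n_target_score_gain`.
#' @export
reallocation_score_check <- function(pairs) {
  stopifnot(inherits(pairs, "match_pairs"))
  re <- pairs[pairs$reallocated, , drop = FALSE]
  dir <- with(re, ifelse(reduced_score < full_score, "lower",
                         ifelse(reduced_score > full_score, "higher", "equal")))
  counts <- table(factor(dir, levels = c("lower", "equal", "higher")),
                  factor(re$reduced_kind, levels = c("TARGET", "DECOY")))
  list(counts = unclass(counts),
       n_target_score_gain = sum(dir == "higher" & re$reduced_kind == "TARGET"))
}

#' Decompose the reduced search's additional identifications
#'
#' An additional identification is a spectrum whose reduced-search PSM is
#' a valid target (score at or above `cutoff_reduced`) while its
#' full-search PSM is not a valid target (below `cutoff_full`, a decoy,
#' or absent). It is a "pure reallocation" when it is a reallocation onto
#' a target whose reduced score also passes `cutoff_full` - an
#' identification owed to reallocation alone, not to the lower cutoff.
#' All other additional identifications are attributed to the lower
#' cutoff and sub-classified by the full-search side: same peptide (no
#' reallocation), or reallocation from a target, a decoy, or no match.
#'
#' Peptide-level counts keep only additional spectra whose reduced
#' peptide is absent from the full search's valid peptide set, deduplicate
#' by peptide sequence, and attribute each peptide to the category of its
#' best-scoring additional spectrum. Categories are disjoint and sum to
#' the total at both granularities.
#'
#' @param pairs a `match_pairs` data.frame.
#' @param cutoff_full score cutoff estimated on the full search.
#' @param cutoff_reduced score cutoff estimated on the reduced search.
#' @return a list of class `additional_breakdown`; see Details.
#' @export
decompose_additional <- function(pairs, cutoff_full, cutoff_reduced) {
  stopifnot(inherits(pairs, "match_pairs"))
  red_valid <- pairs$reduced_kind == "TARGET" &
    pairs$reduced_score >= cutoff_reduced
  full_valid <- pairs$full_kind == "TARGET" &
    !is.na(pairs$full_score) & pairs$full_score >= cutoff_full
  red_valid[is.na(red_valid)] <- FALSE
  additional <- red_valid & !full_valid

  realloc_to_target <- additional &
    (pairs$full_kind %in% c("DECOY", "NO_MATCH") |
       (pairs$full_kind == "TARGET" &
          pairs$full_peptide != pairs$reduced_peptide))
  pure <- realloc_to_target & pairs$reduced_score >= cutoff_full

  category <- rep(NA_character_, nrow(pairs))
  category[additional & pure] <- "pure_reallocation"
  low <- additional & !pure
  category[low & !realloc_to_target] <- "lower_cutoff_no_realloc"
  category[low & realloc_to_target & pairs$full_kind == "TARGET"] <-
    "lower_cutoff_realloc_from_target"
  category[low & realloc_to_target & pairs$full_kind == "DECOY"] <-
    "lower_cutoff_realloc_from_decoy"
  category[low & realloc_to_target & pairs$full_kind == "NO_MATCH"] <-
    "lower_cutoff_realloc_from_no_match"
  levels <- c("lower_cutoff_no_realloc", "lower_cutoff_realloc_from_target",
              "lower_cutoff_realloc_from_decoy",
              "lower_cutoff_realloc_from_no_match", "pure_reallocation")
  spectra <- table(factor(category[additional], levels = levels))

  # peptide granularity: peptides not in the full search's valid set
  full_valid_peptides <- unique(pairs$full_peptide[full_valid])
  pep_rows <- which(additional &
                      !(pairs$reduced_peptide %in% full_valid_peptides))
  add_pep <- pairs[pep_rows, , drop = FALSE]
  add_pep$category <- category[pep_rows]
  if (nrow(add_pep)) {
    ord <- order(add_pep$reduced_peptide, -add_pep$reduced_score)
    add_pep <- add_pep[ord, , drop = FALSE]
    add_pep <- add_pep[!duplicated(add_pep$reduced_peptide), , drop = FALSE]
  }
  peptides <- table(factor(add_pep$category, levels = levels))

  structure(
    list(cutoff_full = cutoff_full, cutoff_reduced = cutoff_reduced,
         n_additional_spectra = sum(additional),
         spectra = c(spectra),
         n_additional_peptides = nrow(add_pep),
         peptides = c(peptides),
         pct_additional_spectra_lower_cutoff =
           if (sum(additional) > 0)
             100 * sum(spectra[startsWith(levels, "lower")]) / sum(additional)
           else NA_real_),
    class = "additional_breakdown"
  )
}

#' @export
print.additional_breakdown <- function(x, ...) {
  cat(sprintf(
    "additional identifications in the reduced search: %d spectra, %d peptides\n",
    x$n_additional_spectra, x$n_additional_peptides))
  print(rbind(spectra = x$spectra, peptides = x$peptides))
  if (!is.na(x$pct_additional_spectra_lower_cutoff))
    cat(sprintf("  %.1f%% of additional spectra due to the lower cutoff\n",
                x$pct_additional_spectra_lower_cutoff))
  invisible(x)
}

#' Fate of the full search's valid matches under a transferred cutoff
#'
#' For spectra whose full-search PSM passes `cutoff_full`, cross-tabulates
#' (separately for valid targets and valid decoys) what became of them in
#' the reduced search when the same cutoff is applied there: same match
#' still valid, same match invalid, reallocated to a valid or invalid
#' match of the same or the other kind, or no match at all. Also reports
#' the net percentage loss of valid targets and valid decoys - net,
#' because spectra may also newly enter the valid set of a kind in the
#' reduced search.
#'
#' @param pairs a `match_pairs` data.frame.
#' @param cutoff_full score cutoff estimated on the full search,
#'   transferred to the reduced search.
#' @return a list of class `decoy_loss` with the fate matrix `fate`
#'   (rows: categories, columns: TARGET/DECOY), full/reduced valid
#'   counts, and `net_loss_pct` per kind.
#' @export
decoy_loss_analysis <- function(pairs, cutoff_full) {
  stopifnot(inherits(pairs, "match_pairs"))
  levels <- c("same_valid", "same_invalid",
              "realloc_valid_same_kind", "realloc_valid_cross_kind",
              "realloc_invalid", "no_match")
  out_fate <- matrix(0L, length(levels), 2L,
                     dimnames = list(levels, c("TARGET", "DECOY")))
  n_full_valid <- n_red_valid <- c(TARGET = 0L, DECOY = 0L)
  red_valid <- !is.na(pairs$reduced_score) &
    pairs$reduced_score >= cutoff_full
  for (kind in c("TARGET", "DECOY")) {
    fv <- pairs$full_kind == kind & !is.na(pairs$full_score) &
      pairs$full_score >= cutoff_full
    n_full_valid[kind] <- sum(fv)
    n_red_valid[kind] <- sum(pairs$reduced_kind == kind & red_valid)
    p <- pairs[fv, , drop = FALSE]
    rv <- red_valid[fv]
    fate <- rep("no_match", nrow(p))
    matched <- p$reduced_kind != "NO_MATCH"
    same <- matched & p$reduced_peptide == p$full_peptide
    fate[same & rv] <- "same_valid"
    fate[same & !rv] <- "same_invalid"
    realloc <- matched & !same
    fate[realloc & rv & p$reduced_kind == kind] <- "realloc_valid_same_kind"
    fate[realloc & rv & p$reduced_kind != kind] <- "realloc_valid_cross_kind"
    fate[realloc & !rv] <- "realloc_invalid"
    out_fate[, kind] <- c(table(factor(fate, levels = levels)))
  }
  structure(
    list(cutoff_full = cutoff_full,
         fate = out_fate,
         n_full_valid = n_full_valid,
         n_reduced_valid = n_red_valid,
         net_loss_pct = ifelse(n_full_valid > 0,
                               100 * (n_full_valid - n_red_valid) / n_full_valid,
                               NA_real_)),
    class = "decoy_loss"
  )
}

#' @export
print.decoy_loss <- function(x, ...) {
  cat(sprintf("fate of full-search valid matches at transferred cutoff %g:\n",
              x$cutoff_full))
  print(x$fate)
  cat(sprintf("net loss: targets %.1f%%, decoys %.1f%%\n",
              x$net_loss_pct["TARGET"], x$net_loss_pct["DECOY"]))
  invisible(x)
}
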