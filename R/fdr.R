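## Score-cutoff estimation for FDR control of PSM lists.
##
## Two estimators are provided. Target-decoy competition (TDC) picks the
## most lenient score cutoff whose acceptance set keeps the nominal FDR
## estimate (d+1)/t at or below the requested level, where t and d count
## valid targets and valid decoys. The Benjamini-Hochberg (BH) step-up
## procedure operates on p-values derived from target-only search scores
## and needs no decoys.

#' Nominal FDR of an acceptance set
#'
#' The target-decoy estimate `(d + 1) / t`, where `t` valid targets and
#' `d` valid decoys pass the score cutoff. The `+ 1` guards against the
#' downward bias of the naive `d / t` estimate when few decoys pass.
#'
#' @param t number of valid targets (>= 1).
#' @param d number of valid decoys (>= 0).
#' @return the nominal FDR as a plain number.
#' @examples
#' nominal_fdr(100, 0)  # 0.01
#' @export
nominal_fdr <- function(t, d) {
  if (any(t < 1)) stop_("nominal FDR undefined for t < 1")
  if (any(d < 0)) stop_("'d' must be >= 0")
  (d + 1) / t
}

#' An FDR validation result
#' @keywords internal
fdr_result <- function(alpha, cutoff, t, d, nominal, method) {
  structure(
    list(alpha = alpha, cutoff = cutoff,
         n_valid_targets = as.integer(t), n_valid_decoys = as.integer(d),
         nominal_fdr = nominal, method = method),
    class = "fdr_result"
  )
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf(
    "%s validation at alpha = %g\n  cutoff = %g, t = %d, d = %d, nominal FDR = %g\n",
    x$method, x$alpha, x$cutoff, x$n_valid_targets, x$n_valid_decoys,
    x$nominal_fdr))
  invisible(x)
}

#' Estimate a score cutoff by target-decoy competition
#'
#' Finds the smallest score cutoff `c` such that the acceptance set
#' (all PSMs with `score >= c`, inclusive) maximises the number of valid
#' targets subject to `(d + 1) / t <= alpha`. Among acceptance sets with
#' the same target count, the most lenient (lowest) feasible cutoff is
#' reported. If no acceptance set is feasible the result is empty, with
#' `cutoff = Inf`.
#'
#' @param table a prefiltered [psm_table] (one PSM per spectrum) holding
#'   target and decoy PSMs.
#' @param alpha requested FDR level, in (0, 1).
#' @return an `fdr_result` with the cutoff, `t`, `d` and the nominal FDR
#'   of the accepted set.
#' @export
tdc_cutoff <- function(table, alpha) {
  stopifnot(inherits(table, "psm_table"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_("'alpha' must be a single number in (0, 1)")
  if (nrow(table) == 0L)
    return(fdr_result(alpha, Inf, 0L, 0L, NA_real_, "TDC"))
  if (!any(table$is_decoy))
    warning("no decoy PSMs present; nominal FDR uses the (0 + 1)/t estimate",
            call. = FALSE)
  ord <- order(table$score, decreasing = TRUE)
  score <- table$score[ord]
  decoy <- table$is_decoy[ord]
  n <- length(score)
  t_cum <- cumsum(!decoy)
  d_cum <- cumsum(decoy)
  # candidate cutoffs: positions where the next score is strictly lower
  boundary <- which(c(score[-n] > score[-1], TRUE))
  t_b <- t_cum[boundary]
  d_b <- d_cum[boundary]
  feasible <- t_b >= 1L & (d_b + 1) / t_b <= alpha
  if (!any(feasible))
    return(fdr_result(alpha, Inf, 0L, 0L, NA_real_, "TDC"))
  t_max <- max(t_b[feasible])
  pick <- max(which(feasible & t_b == t_max))  # lowest feasible cutoff
  i <- boundary[pick]
  fdr_result(alpha, score[i], t_cum[i], d_cum[i],
             nominal_fdr(t_cum[i], d_cum[i]), "TDC")
}

#' Describe a score-to-p-value convention
#'
#' `"mascot"` interprets scores on the `-10 log10(P)` scale, so
#' `p = 10^(-score / 10)`, clipped to (0, 1]. `"empirical"` estimates
#' `p = (1 + #\{decoy scores >= s\}) / (1 + #decoys)` from an observed
#' decoy score distribution, which must be supplied either here or via
#' the decoy PSMs of the table handed to [bh_cutoff()].
#'
#' @param kind `"mascot"` or `"empirical"`.
#' @param decoy_scores numeric vector of decoy scores (empirical kind).
#' @return a `pvalue_convention` object.
#' @export
pvalue_convention <- function(kind = c("mascot", "empirical"),
                              decoy_scores = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, decoy_scores = decoy_scores),
            class = "pvalue_convention")
}

#' Convert search scores to p-values
#'
#' @param score numeric vector of finite scores.
#' @param convention a [pvalue_convention()].
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' score_to_pvalue(20, pvalue_convention("mascot"))  # 0.01
#' @export
score_to_pvalue <- function(score, convention = pvalue_convention("mascot")) {
  stopifnot(inherits(convention, "pvalue_convention"))
  if (any(!is.finite(score))) stop_("scores must be finite")
  if (convention$kind == "mascot") {
    p <- 10^(-score / 10)
    return(pmin(1, pmax(p, .Machine$double.xmin)))
  }
  d <- convention$decoy_scores
  if (is.null(d) || length(d) == 0L)
    stop_("empirical p-value convention requires decoy scores")
  ds <- sort(d)
  n_ge <- length(ds) - findInterval(score, ds, left.open = TRUE)
  (1 + n_ge) / (1 + length(ds))
}

#' Estimate a score cutoff by the Benjamini-Hochberg procedure
#'
#' Target PSM scores are converted to p-values under `convention` and the
#' BH step-up rule is applied: with sorted p-values `p(1) <= ... <= p(m)`,
#' the `k` smallest are rejected where `k = max\{i : p(i) <= i * alpha / m\}`.
#' Decoy PSMs in `table` are ignored, except that under the empirical
#' convention they supply the decoy score distribution when the convention
#' object carries none. The reported cutoff is the score of the lowest
#' scoring rejected PSM; the decoy count is reported as 0 and the
#' `nominal_fdr` field carries `alpha`.
#'
#' @param table a [psm_table] with target PSMs.
#' @param alpha requested FDR level, in (0, 1).
#' @param convention a [pvalue_convention()].
#' @return an `fdr_result` with `method = "BH"`.
#' @export
bh_cutoff <- function(table, alpha, convention = pvalue_convention("mascot")) {
  stopifnot(inherits(table, "psm_table"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_("'alpha' must be a single number in (0, 1)")
  if (convention$kind == "empirical" && is.null(convention$decoy_scores))
    convention$decoy_scores <- table$score[table$is_decoy]
  targets <- table[!table$is_decoy, , drop = FALSE]
  if (nrow(targets) == 0L) stop_("no target PSMs to validate")
  p <- score_to_pvalue(targets$score, convention)
  rejected <- stats::p.adjust(p, method = "BH") <= alpha
  if (!any(rejected))
    return(fdr_result(alpha, Inf, 0L, 0L, alpha, "BH"))
  cutoff <- min(targets$score[rejected])
  fdr_result(alpha, cutoff, sum(targets$score >= cutoff), 0L, alpha, "BH")
}

#' Apply an externally estimated score cutoff to a PSM table
#'
#' Used to transfer the cutoff estimated on one search to the results of
#' another (for instance, applying the full-database cutoff to a reduced
#' database search) and to report the valid target/decoy counts and the
#' nominal FDR that would result. Acceptance is inclusive
#' (`score >= cutoff`).
#'
#' @param table a prefiltered [psm_table].
#' @param cutoff finite score threshold.
#' @return an `fdr_result` with `method = "transfer"` and `alpha = NA`;
#'   its `nominal_fdr` may exceed any previously requested level.
#' @export
transfer_cutoff <- function(table, cutoff) {
  stopifnot(inherits(table, "psm_table"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff))
    stop_("'cutoff' must be a single finite number")
  valid <- table$score >= cutoff
  t <- sum(valid & !table$is_decoy)
  d <- sum(valid & table$is_decoy)
  fdr_result(NA_real_, cutoff, t, d,
             if (t >= 1) nominal_fdr(t, d) else NA_real_, "transfer")
}

#' Subset a PSM table to the PSMs accepted by a validation result
#'
#' @param table a [psm_table].
#' @param result an `fdr_result`.
#' @param targets_only drop decoy PSMs from the accepted set
#'   (default TRUE).
#' @return a [psm_table] of accepted PSMs.
#' @export
valid_psms <- function(table, result, targets_only = TRUE) {
  stopifnot(inherits(table, "psm_table"), inherits(result, "fdr_result"))
  keep <- table$score >= result$cutoff
  if (targets_only) keep <- keep & !table$is_decoy
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("psm_table", "data.frame")
  out
}
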