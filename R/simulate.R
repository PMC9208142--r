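## Ground-truth simulator for paired full/reduced database searches.
##
## Score model. Every candidate match of a spectrum carries a latent
## per-candidate p-value u ~ U(0, 1); the search score is the Mascot-like
## transform s = -10 log10(u), so the best of k candidates scores
## s = -10 log10(min of k uniforms). "Database size" enters purely as the
## candidate count k. A spectrum whose true peptide is in the database
## (probability pi1) additionally has a correct candidate whose score is
## drawn once from a Gaussian on the same scale and reused in both
## searches. Per search, target-decoy competition retains the single best
## of {correct target, best incorrect target, best decoy}.
##
## Reduction. The reduced database drops a fraction r of sequences but
## never a spectrum's correct sequence. Decoys are random, so their
## candidate count shrinks by the full factor: k_d = ceil((1 - r) k).
## Incorrect target matches, in contrast, concentrate on sequences of
## expressed proteins - homologs and near-misses of what is actually in
## the sample - which is precisely what a transcriptome-informed
## reduction retains. The mismatch_retention parameter m gives the
## fraction of a spectrum's incorrect-target matching capacity that
## survives reduction for this reason: k_t = ceil(((1 - r) + m r) k).
## With m = 0 targets and decoys shrink equally and the equal-chance
## assumption of TDC holds in both searches; with m > 0 the reduced
## search under-samples incorrect-match scores with decoys, the
## documented small-database failure mode of TDC.
##
## Reduced candidates are an exact subset of full candidates (the best
## surviving candidate is the best of a subset of the full draws), so a
## spectrum's reduced-search score can never exceed its full-search
## score.

#' Simulation configuration
#'
#' @param n_spectra number of spectra per search.
#' @param pi1 fraction of spectra whose correct peptide is in the
#'   database, in \[0, 1).
#' @param k_full incorrect-candidate count per spectrum in the full
#'   database (targets and decoys alike).
#' @param reduction_rate fraction r of sequences absent from the reduced
#'   database, in \[0, 1); the correct sequence of a spectrum is never
#'   removed.
#' @param mismatch_retention fraction of incorrect-target matching
#'   capacity that survives reduction because mis-assignments concentrate
#'   on expressed-protein sequences (see source header); 0 reduces
#'   targets and decoys equally.
#' @param mu_correct,sd_correct mean and standard deviation of the
#'   correct-match score (on the -10 log10 p scale).
#' @param seed integer seed; the same seed and configuration reproduce
#'   the simulation exactly.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_spectra = 2000L, pi1 = 0.6, k_full = 1000L,
                       reduction_rate = 0.9, mismatch_retention = 0.5,
                       mu_correct = 75, sd_correct = 10, seed = 1L) {
  stopifnot(n_spectra >= 1, k_full >= 1,
            pi1 >= 0 && pi1 < 1,
            reduction_rate >= 0 && reduction_rate < 1,
            mismatch_retention >= 0 && mismatch_retention <= 1,
            sd_correct > 0)
  structure(
    list(n_spectra = as.integer(n_spectra), pi1 = pi1,
         k_full = as.integer(k_full), reduction_rate = reduction_rate,
         mismatch_retention = mismatch_retention,
         mu_correct = mu_correct, sd_correct = sd_correct,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

## Deterministic peptide sequence for stream `kind`, index i: the index
## is written in base 20 over the amino-acid alphabet, padded to 8
## letters, prefixed with a stream letter and suffixed with K (length 10,
## always passing the default length prefilter).
.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
pep_seq <- function(i, kind) {
  digits <- matrix("A", nrow = 8L, ncol = length(i))
  v <- i
  for (row in 8:1) {
    digits[row, ] <- .aa20[(v %% 20L) + 1L]
    v <- v %/% 20L
  }
  paste0(kind, apply(digits, 2L, paste, collapse = ""), "K")
}

## min of k iid U(0,1) ~ Beta(1, k); joint subset draw: the full-pool
## minimum is the min of the surviving-subset minimum and the removed
## -part minimum, which preserves both marginals and the subset ordering.
.rmin_unif <- function(n, k) {
  k <- rep_len(k, n)
  u <- stats::rbeta(n, 1, k)
  pmax(u, 1e-300)
}

.score <- function(u) -10 * log10(u)

#' Simulate a paired full/reduced database search
#'
#' Generates, per spectrum, the competition outcome of a full-database
#' and a reduced-database search (see the score model in the package
#' source), plus target-only search tables for Benjamini-Hochberg
#' validation and a ground-truth table for empirical false discovery
#' proportion computation.
#'
#' The target-only tables carry scores on a database-size-calibrated
#' scale: `-10 log10` of the spectrum-level p-value of the best candidate
#' match (the probability that a spectrum with no correct match would
#' score at least as high in a database of that size). Under the
#' `"mascot"` p-value convention these scores therefore decode to valid,
#' uniformly distributed p-values for incorrect matches, whatever the
#' database size.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_pair` with elements `full`, `reduced`,
#'   `full_target_only`, `reduced_target_only` (all [psm_table]s with one
#'   PSM per spectrum), `truth` (a data.frame) and `config`.
#' @export
simulate_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_spectra
  k_full <- config$k_full
  r <- config$reduction_rate
  m <- config$mismatch_retention
  k_d_red <- max(1L, as.integer(ceiling((1 - r) * k_full)))
  k_t_red <- max(k_d_red,
                 as.integer(ceiling(((1 - r) + m * r) * k_full)))

  with_seed(config$seed, {
    available <- stats::runif(n) < config$pi1
    s_corr <- stats::rnorm(n, config$mu_correct, config$sd_correct)
    u_corr <- 10^(-s_corr / 10)

    # incorrect targets: surviving subset of size k_t_red, removed rest
    u_t_red <- .rmin_unif(n, k_t_red)
    u_t_rest <- if (k_full > k_t_red) .rmin_unif(n, k_full - k_t_red)
                else rep(1, n)
    u_t_full <- pmin(u_t_red, u_t_rest)
    t_survived <- u_t_red <= u_t_rest
    # decoys: surviving subset of size k_d_red
    u_d_red <- .rmin_unif(n, k_d_red)
    u_d_rest <- if (k_full > k_d_red) .rmin_unif(n, k_full - k_d_red)
                else rep(1, n)
    u_d_full <- pmin(u_d_red, u_d_rest)
    d_survived <- u_d_red <= u_d_rest

    idx <- seq_len(n)
    spectrum_id <- sprintf("spec%06d", idx)
    pep_c <- pep_seq(idx, "A")
    pep_tf <- pep_seq(idx, "C")
    pep_tr <- ifelse(t_survived, pep_tf, pep_seq(idx, "D"))
    pep_df <- pep_seq(idx, "E")
    pep_dr <- ifelse(d_survived, pep_df, pep_seq(idx, "F"))

    one_search <- function(u_inc, pep_inc, u_dec, pep_dec, label) {
      s_inc <- .score(u_inc)
      s_dec <- .score(u_dec)
      target_corr <- available & s_corr >= s_inc
      s_target <- ifelse(target_corr, s_corr, s_inc)
      pep_target <- ifelse(target_corr, pep_c, pep_inc)
      decoy_wins <- s_dec > s_target
      tab <- psm_table(
        spectrum_id = spectrum_id,
        peptide = ifelse(decoy_wins, pep_dec, pep_target),
        proteins = ifelse(decoy_wins, paste0("rev_PR_", pep_dec),
                          paste0("PR_", pep_target)),
        score = ifelse(decoy_wins, s_dec, s_target),
        is_decoy = decoy_wins,
        label = label
      )
      list(table = tab,
           accepted_correct = !decoy_wins & target_corr,
           accepted_kind = ifelse(decoy_wins, "DECOY", "TARGET"))
    }
    full <- one_search(u_t_full, pep_tf, u_d_full, pep_df, "full")
    reduced <- one_search(u_t_red, pep_tr, u_d_red, pep_dr, "reduced")

    # target-only searches on the size-calibrated score scale
    target_only <- function(u_inc, pep_inc, k, label) {
      corr_wins <- available & u_corr < u_inc
      u_best <- ifelse(corr_wins, u_corr, u_inc)
      p_spec <- pmax(-expm1(k * log1p(-u_best)), 1e-300)
      psm <- psm_table(
        spectrum_id = spectrum_id,
        peptide = ifelse(corr_wins, pep_c, pep_inc),
        proteins = paste0("PR_", ifelse(corr_wins, pep_c, pep_inc)),
        score = -10 * log10(p_spec),
        is_decoy = FALSE,
        label = label
      )
      list(table = psm, correct = corr_wins)
    }
    to_full <- target_only(u_t_full, pep_tf, k_full, "full_target_only")
    to_red <- target_only(u_t_red, pep_tr, k_t_red, "reduced_target_only")

    truth <- data.frame(
      spectrum_id = spectrum_id,
      correct_available = available,
      score_correct = s_corr,
      full_target_score = pmax(.score(u_t_full),
                               ifelse(available, s_corr, -Inf)),
      full_decoy_score = .score(u_d_full),
      full_accepted_kind = full$accepted_kind,
      full_accepted_correct = full$accepted_correct,
      reduced_target_score = pmax(.score(u_t_red),
                                  ifelse(available, s_corr, -Inf)),
      reduced_decoy_score = .score(u_d_red),
      reduced_accepted_kind = reduced$accepted_kind,
      reduced_accepted_correct = reduced$accepted_correct,
      full_target_only_score = to_full$table$score,
      full_target_only_correct = to_full$correct,
      reduced_target_only_score = to_red$table$score,
      reduced_target_only_correct = to_red$correct,
      stringsAsFactors = FALSE
    )
    structure(
      list(full = full$table, reduced = reduced$table,
           full_target_only = to_full$table,
           reduced_target_only = to_red$table,
           truth = truth, config = config,
           k_target_reduced = k_t_red, k_decoy_reduced = k_d_red),
      class = "sim_pair"
    )
  })
}

#' Empirical false discovery proportion of an accepted set
#'
#' Ground-truth counterpart of the nominal FDR: the fraction of accepted
#' target PSMs whose match is incorrect. An empty acceptance set has FDP
#' 0 by convention.
#'
#' @param valid character vector of accepted spectrum ids (for instance
#'   from [valid_psms()]).
#' @param truth the `truth` component of a [simulate_pair()] result.
#' @param search which simulated search the acceptance refers to.
#' @return the empirical FDP, a number in \[0, 1\].
#' @export
empirical_fdp <- function(valid, truth,
                          search = c("full", "reduced",
                                     "full_target_only",
                                     "reduced_target_only")) {
  search <- match.arg(search)
  if (!all(valid %in% truth$spectrum_id))
    stop_("'valid' contains spectrum ids absent from the simulation")
  rows <- truth$spectrum_id %in% valid
  if (search %in% c("full", "reduced")) {
    kind <- truth[[paste0(search, "_accepted_kind")]]
    correct <- truth[[paste0(search, "_accepted_correct")]]
    rows <- rows & kind == "TARGET"
  } else {
    correct <- truth[[paste0(search, "_correct")]]
  }
  if (!any(rows)) return(0)
  mean(!correct[rows])
}

#' Calibration experiment: nominal versus empirical FDR across searches
#'
#' Replicates [simulate_pair()] and, for each requested FDR level,
#' validates the full and reduced competition searches by TDC and the
#' full and reduced target-only searches by BH (under the `"mascot"`
#' p-value convention, which decodes the simulator's size-calibrated
#' scores into valid p-values). Per replicate, level, method and search
#' it records the estimated cutoff, the valid counts and the empirical
#' FDP.
#'
#' @param config a [sim_config()]; its seed is the master seed from which
#'   one child seed per replicate is derived.
#' @param alphas FDR levels to validate at.
#' @param n_reps number of replicates.
#' @return a tidy data.frame with columns `rep`, `alpha`, `method`,
#'   `search`, `cutoff`, `t`, `d`, `nominal_fdr`, `fdp`.
#' @seealso [calibration_summary()]
#' @export
calibration_experiment <- function(config = sim_config(),
                                   alphas = c(0.005, 0.01, 0.05),
                                   n_reps = 200L) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  seeds <- derive_seeds(config$seed, n_reps)
  rows <- vector("list", n_reps)
  for (rep_i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- seeds[rep_i]
    sim <- simulate_pair(cfg)
    recs <- list()
    for (alpha in alphas) {
      for (search in c("full", "reduced")) {
        res <- tdc_cutoff(sim[[search]], alpha)
        ids <- valid_psms(sim[[search]], res)$spectrum_id
        recs[[length(recs) + 1L]] <- data.frame(
          rep = rep_i, alpha = alpha, method = "TDC", search = search,
          cutoff = res$cutoff, t = res$n_valid_targets,
          d = res$n_valid_decoys, nominal_fdr = res$nominal_fdr,
          fdp = empirical_fdp(ids, sim$truth, search),
          stringsAsFactors = FALSE
        )
      }
      for (search in c("full_target_only", "reduced_target_only")) {
        res <- bh_cutoff(sim[[search]], alpha, pvalue_convention("mascot"))
        ids <- valid_psms(sim[[search]], res)$spectrum_id
        recs[[length(recs) + 1L]] <- data.frame(
          rep = rep_i, alpha = alpha, method = "BH",
          search = sub("_target_only", "", search),
          cutoff = res$cutoff, t = res$n_valid_targets,
          d = res$n_valid_decoys, nominal_fdr = res$nominal_fdr,
          fdp = empirical_fdp(ids, sim$truth, search),
          stringsAsFactors = FALSE
        )
      }
    }
    rows[[rep_i]] <- do.call(rbind, recs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a calibration experiment
#'
#' Aggregates a [calibration_experiment()] table per level and method:
#' mean and standard deviation of the empirical FDP in the full and
#' reduced searches, mean cutoffs, the mean absolute relative cutoff
#' change between the two searches, and, per level, the fraction of
#' replicate pairs in which BH's relative cutoff change is smaller than
#' TDC's.
#'
#' @param tab output of [calibration_experiment()].
#' @return a list with data.frame `by_method` and data.frame
#'   `stability` (column `pct_bh_shift_smaller`).
#' @export
calibration_summary <- function(tab) {
  stopifnot(all(c("rep", "alpha", "method", "search", "cutoff", "fdp")
                %in% names(tab)))
  wide <- merge(
    tab[tab$search == "full",
        c("rep", "alpha", "method", "cutoff", "fdp")],
    tab[tab$search == "reduced",
        c("rep", "alpha", "method", "cutoff", "fdp")],
    by = c("rep", "alpha", "method"), suffixes = c("_full", "_reduced")
  )
  wide$rel_shift <- abs(wide$cutoff_reduced - wide$cutoff_full) /
    abs(wide$cutoff_full)
  agg <- function(x) c(mean = mean(x), sd = stats::sd(x))
  by_method <- do.call(rbind, lapply(
    split(wide, list(wide$alpha, wide$method), drop = TRUE),
    function(g) data.frame(
      alpha = g$alpha[1], method = g$method[1],
      fdp_full_mean = mean(g$fdp_full), fdp_full_sd = stats::sd(g$fdp_full),
      fdp_reduced_mean = mean(g$fdp_reduced),
      fdp_reduced_sd = stats::sd(g$fdp_reduced),
      cutoff_full_mean = mean(g$cutoff_full),
      cutoff_reduced_mean = mean(g$cutoff_reduced),
      rel_shift_mean = mean(g$rel_shift),
      stringsAsFactors = FALSE
    )))
  rownames(by_method) <- NULL
  shift <- merge(
    wide[wide$method == "TDC", c("rep", "alpha", "rel_shift")],
    wide[wide$method == "BH", c("rep", "alpha", "rel_shift")],
    by = c("rep", "alpha"), suffixes = c("_tdc", "_bh")
  )
  stability <- do.call(rbind, lapply(split(shift, shift$alpha), function(g)
    data.frame(alpha = g$alpha[1],
               pct_bh_shift_smaller =
                 100 * mean(g$rel_shift_bh < g$rel_shift_tdc))))
  rownames(stability) <- NULL
  list(by_method = by_method, stability = stability)
}

#' Simulate peptide-protein identifications with transcript support
#'
#' Generates a random bipartite identification structure for ambiguity
#' analyses. Proteins with transcript support receive a Poisson number
#' of observed specific peptides; proteins without transcript support
#' receive specific peptides at a reduced rate
#' (`unexpressed_specific_rate` times the expressed rate), reflecting
#' that a protein absent from the sample is rarely identified by a
#' peptide of its own - unsupported proteins are typically dragged into
#' the identification list through peptides shared with expressed
#' homologs or isoforms. Shared peptides connect small random protein
#' subsets irrespective of expression (homology does not follow
#' transcription), and proteins are annotated to genes, with some genes
#' encoding several proteins.
#'
#' @param n_proteins number of proteins.
#' @param avg_specific mean number of observed specific peptides per
#'   transcript-supported protein.
#' @param n_shared number of shared peptides.
#' @param max_share maximal number of proteins a shared peptide maps to.
#' @param expressed_frac fraction of proteins with transcript support.
#' @param unexpressed_specific_rate relative rate at which proteins
#'   without transcript support still show specific peptides (proteins
#'   can outlive their mRNA; polyA selection misses some transcripts).
#' @param genes_per_protein mean proteins-per-gene compression (values
#'   below 1 make some genes encode several proteins).
#' @param seed integer seed.
#' @return a list with `incidence` (sparse matrix), `expressed`
#'   (character vector of supported accessions), and `gene_map` (named
#'   character vector accession -> gene).
#' @export
simulate_identifications <- function(n_proteins = 80L, avg_specific = 1.5,
                                     n_shared = 60L, max_share = 3L,
                                     expressed_frac = 0.7,
                                     unexpressed_specific_rate = 0.2,
                                     genes_per_protein = 0.75,
                                     seed = 1L) {
  stopifnot(n_proteins >= 2, max_share >= 2, n_shared >= 1,
            expressed_frac > 0 && expressed_frac <= 1,
            unexpressed_specific_rate >= 0,
            unexpressed_specific_rate <= 1)
  with_seed(seed, {
    prot <- sprintf("PROT%04d", seq_len(n_proteins))
    expressed_flag <- stats::runif(n_proteins) < expressed_frac
    rate <- ifelse(expressed_flag, avg_specific,
                   avg_specific * unexpressed_specific_rate)
    n_spec <- stats::rpois(n_proteins, rate)
    pairs <- data.frame(peptide = character(0), protein = character(0))
    if (sum(n_spec) > 0)
      pairs <- data.frame(
        peptide = sprintf("SPEC%05d", seq_len(sum(n_spec))),
        protein = rep(prot, n_spec),
        stringsAsFactors = FALSE
      )
    shared <- do.call(rbind, lapply(seq_len(n_shared), function(i) {
      size <- sample(2:max_share, 1L)
      data.frame(peptide = sprintf("SHAR%05d", i),
                 protein = sample(prot, size),
                 stringsAsFactors = FALSE)
    }))
    pairs <- rbind(pairs, shared)
    expressed <- prot[expressed_flag]
    n_genes <- max(1L, round(genes_per_protein * n_proteins))
    gene_map <- stats::setNames(
      sprintf("GENE%04d", sample.int(n_genes, n_proteins, replace = TRUE)),
      prot
    )
    list(incidence = build_incidence(pairs), expressed = expressed,
         gene_map = gene_map)
  })
}
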