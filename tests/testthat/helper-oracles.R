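# Independent oracles and fixture generators. Each oracle re-derives the
# expected result by brute force or via an unrelated library routine, so
# the implementation and its check never share code.

# Brute-force TDC: try every distinct observed score as the cutoff,
# keep feasible acceptance sets ((d+1)/t <= alpha), return the one with
# the most targets, breaking ties toward the lowest cutoff.
oracle_tdc <- function(score, is_decoy, alpha) {
  best <- list(cutoff = Inf, t = 0L, d = 0L)
  for (c in sort(unique(score))) {
    t <- sum(score >= c & !is_decoy)
    d <- sum(score >= c & is_decoy)
    if (t >= 1 && (d + 1) / t <= alpha) {
      if (t > best$t || (t == best$t && c < best$cutoff))
        best <- list(cutoff = c, t = t, d = d)
    }
  }
  best
}

# Direct BH step-up on a p-value vector: number of rejections.
oracle_bh_rejections <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * alpha / m) k <- i
  k
}

# Protein partition of the bipartite graph via igraph's component
# finder, as a canonical set-of-sets (sorted protein name vectors).
oracle_protein_partition <- function(I) {
  tri <- Matrix::summary(methods::as(I, "TsparseMatrix"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("pep.", tri$i), to = paste0("prot.", tri$j)),
    directed = FALSE)
  memb <- igraph::components(g)$membership
  prot_v <- grep("^prot\\.", names(memb), value = TRUE)
  parts <- split(as.integer(sub("^prot\\.", "", prot_v)), memb[prot_v])
  canon <- lapply(parts, function(j) sort(colnames(I)[j]))
  unname(canon[order(vapply(canon, `[`, "", 1L))])
}

canonical_cc_proteins <- function(ccs) {
  parts <- lapply(ccs, function(cc) sort(cc$proteins))
  parts[order(vapply(parts, `[`, "", 1L))]
}

# Random PSM table: scores from a mixture, random decoy labels.
random_psm_table <- function(n, seed) {
  set.seed(seed)
  psm_table(
    spectrum_id = sprintf("s%04d", seq_len(n)),
    peptide = replicate(n, paste(sample(LETTERS[1:20], 8, TRUE), collapse = "")),
    proteins = "P1",
    score = round(stats::rnorm(n, 30, 10) + stats::rexp(n, 0.2), 3),
    is_decoy = stats::runif(n) < 0.4
  )
}

# Random bipartite incidence matrix with up to n_pep + n_prot vertices;
# every peptide maps to 1-3 proteins, every protein keeps >= 1 peptide.
random_incidence <- function(n_pep, n_prot, seed) {
  set.seed(seed)
  pairs <- do.call(rbind, lapply(seq_len(n_pep), function(i) {
    data.frame(peptide = sprintf("p%03d", i),
               protein = sprintf("q%03d",
                                 sample.int(n_prot,
                                            sample(seq_len(min(3, n_prot)), 1))),
               stringsAsFactors = FALSE)
  }))
  build_incidence(pairs)
}

# Random identification structure plus expression for post hoc tests.
random_posthoc_instance <- function(seed) {
  set.seed(seed)
  n_prot <- sample(5:25, 1)
  n_pep <- sample(8:50, 1)
  I <- random_incidence(n_pep, n_prot, seed = seed + 7919L)
  expressed <- colnames(I)[stats::runif(ncol(I)) < 0.6]
  list(I = I, expressed = expressed)
}
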