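toy_pairs <- data.frame(
  peptide = c("p1", "p2", "p2", "p3"),
  protein = c("A", "A", "B", "C"),
  stringsAsFactors = FALSE
)

test_that("incidence matrices deduplicate and keep first-appearance order", {
  I <- build_incidence(toy_pairs)
  expect_equal(dim(I), c(3L, 3L))
  expect_equal(rownames(I), c("p1", "p2", "p3"))
  expect_equal(colnames(I), c("A", "B", "C"))
  expect_equal(sum(I), 4)
  # duplicated pair collapses
  I2 <- build_incidence(rbind(toy_pairs, toy_pairs[1, ]))
  expect_equal(as.matrix(I2), as.matrix(I))
  I3 <- build_incidence(data.frame(peptide = "p", protein = "Q"))
  expect_equal(dim(I3), c(1L, 1L))
  expect_error(build_incidence(toy_pairs[0, ]), "empty")
})

test_that("adjacency is the integer cross-product of the incidence", {
  I <- build_incidence(data.frame(peptide = c("p1", "p1", "p2"),
                                  protein = c("A", "B", "A")))
  A <- adjacency_from_incidence(I)
  expect_equal(as.matrix(A),
               matrix(c(2, 1, 1, 1), 2, 2,
                      dimnames = list(c("A", "B"), c("A", "B"))))
  # no sharing: diagonal matrix
  I0 <- build_incidence(data.frame(peptide = c("p1", "p2"),
                                   protein = c("A", "B")))
  A0 <- as.matrix(adjacency_from_incidence(I0))
  expect_equal(A0[1, 2], 0)
  expect_equal(diag(A0), c(A = 1, B = 1))
  # one protein, k peptides
  Ik <- build_incidence(data.frame(peptide = paste0("p", 1:4),
                                   protein = "A"))
  expect_equal(as.numeric(adjacency_from_incidence(Ik)), 4)
})

test_that("connected components partition proteins and peptides", {
  I <- build_incidence(toy_pairs)
  ccs <- connected_components(I = I)
  expect_length(ccs, 2L)
  expect_setequal(ccs[[1]]$proteins, c("A", "B"))
  expect_setequal(ccs[[1]]$peptides, c("p1", "p2"))
  expect_equal(ccs[[1]]$kind, "MULTI_PROTEIN")
  expect_equal(ccs[[2]]$proteins, "C")
  expect_equal(ccs[[2]]$kind, "SINGLE_PROTEIN")
  # transitivity: A-p-B, B-q-C in one component
  chain <- build_incidence(data.frame(peptide = c("p", "p", "q", "q"),
                                      protein = c("A", "B", "B", "C")))
  ccs <- connected_components(I = chain)
  expect_length(ccs, 1L)
  expect_setequal(ccs[[1]]$proteins, c("A", "B", "C"))
  # isolated proteins: one single-protein CC each
  iso <- build_incidence(data.frame(peptide = paste0("p", 1:5),
                                    protein = paste0("Q", 1:5)))
  ccs <- connected_components(I = iso)
  expect_length(ccs, 5L)
  expect_true(all(vapply(ccs, `[[`, "", "kind") == "SINGLE_PROTEIN"))
})

test_that("components agree with an igraph oracle on random graphs", {
  for (seed in 1:500) {
    set.seed(seed)
    n_prot <- sample(2:30, 1)
    n_pep <- sample(2:min(30, 60 - n_prot), 1)
    I <- random_incidence(n_pep, n_prot, seed = seed)
    ccs <- connected_components(I = I)
    expect_equal(canonical_cc_proteins(ccs), oracle_protein_partition(I))
    # partition property: every protein and peptide exactly once
    expect_setequal(unlist(lapply(ccs, `[[`, "proteins")), colnames(I))
    prots <- unlist(lapply(ccs, `[[`, "proteins"))
    peps <- unlist(lapply(ccs, `[[`, "peptides"))
    expect_equal(length(prots), ncol(I))
    expect_equal(length(peps), nrow(I))
  }
})

test_that("the reduced-matrix strategy returns exactly the multi-protein CCs", {
  for (seed in c(1:100)) {
    set.seed(seed + 1000)
    n_prot <- sample(2:25, 1)
    n_pep <- sample(2:30, 1)
    I <- random_incidence(n_pep, n_prot, seed = seed + 1000)
    full <- connected_components(I = I)
    multi <- full[vapply(full, `[[`, "", "kind") == "MULTI_PROTEIN"]
    red <- reduced_cc(I)
    expect_equal(canonical_cc_proteins(red),
                 canonical_cc_proteins(structure(multi, class = "cc_list")))
    peps_multi <- sort(vapply(multi, function(cc)
      paste(sort(cc$peptides), collapse = "|"), ""))
    peps_red <- sort(vapply(red, function(cc)
      paste(sort(cc$peptides), collapse = "|"), ""))
    expect_equal(peps_red, peps_multi)
  }
  # no shared peptides at all
  iso <- build_incidence(data.frame(peptide = c("p1", "p2"),
                                    protein = c("A", "B")))
  expect_length(reduced_cc(iso), 0L)
})

test_that("protein groups use exact peptide-set equality", {
  I <- build_incidence(data.frame(
    peptide = c("p1", "p2", "p1", "p2", "p3"),
    protein = c("A", "A", "B", "B", "C")))
  g <- protein_groups(I)
  expect_length(g, 2L)
  expect_setequal(g[[1]]$proteins, c("A", "B"))
  expect_equal(g[[1]]$kind, "MULTI")
  expect_equal(g[[2]]$proteins, "C")
  # subset is not equality
  I2 <- build_incidence(data.frame(peptide = c("p1", "p2", "p1"),
                                   protein = c("A", "A", "B")))
  g2 <- protein_groups(I2)
  expect_length(g2, 2L)
  expect_true(all(vapply(g2, `[[`, "", "kind") == "SINGLE"))
  # all identical
  I3 <- build_incidence(data.frame(peptide = rep(c("p1", "p2"), 3),
                                   protein = rep(c("A", "B", "C"), each = 2)))
  expect_length(protein_groups(I3), 1L)
})

test_that("every protein group lies within one connected component", {
  for (seed in 1:50) {
    I <- random_incidence(sample(5:25, 1), sample(3:15, 1),
                          seed = seed + 555)
    ccs <- connected_components(I = I)
    cc_of <- unlist(lapply(seq_along(ccs), function(k)
      stats::setNames(rep(k, length(ccs[[k]]$proteins)),
                      ccs[[k]]$proteins)))
    for (g in protein_groups(I))
      expect_length(unique(cc_of[g$proteins]), 1L)
  }
})

test_that("ambiguity metrics compute the documented percentages", {
  I <- build_incidence(toy_pairs)
  ccs <- connected_components(I = I)
  met <- ambiguity_metrics(ccs, I)
  expect_equal(met$n_cc, 2L)
  expect_equal(met$pct_single_protein_cc, 50)
  expect_equal(met$pct_specific_peptides, 100 * 2 / 3, tolerance = 1e-10)
  # 4 proteins from 2 genes in one multi CC: ratio 2
  I4 <- build_incidence(data.frame(
    peptide = rep("p1", 4), protein = c("A", "B", "C", "D")))
  cc4 <- connected_components(I = I4)
  met4 <- ambiguity_metrics(cc4, I4,
                            gene_map = c(A = "g1", B = "g1",
                                         C = "g2", D = "g2"))
  expect_equal(met4$protein_to_gene_ratios, 2)
  # unannotated proteins count as their own gene, with a message
  expect_message(
    met5 <- ambiguity_metrics(cc4, I4, gene_map = c(A = "g1", B = "g1")),
    "own gene")
  expect_equal(met5$protein_to_gene_ratios, 4 / 3)
})

test_that("exported bipartite graphs round-trip their edge set", {
  I <- build_incidence(toy_pairs)
  ccs <- connected_components(I = I)
  out <- withr::local_tempfile(fileext = ".graphml")
  export_cc(ccs[[1]], I, out, format = "graphml", expressed = "A")
  g <- igraph::read_graph(out, format = "graphml")
  expect_equal(igraph::gsize(g), 3)  # p1-A, p2-A, p2-B
  expect_setequal(igraph::V(g)$kind[igraph::V(g)$name %in% c("A", "B")],
                  "protein")
  el <- igraph::as_edgelist(g)
  got <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  expect_equal(got, sort(c("A p1", "A p2", "B p2")))
  # single-protein CC: k peptides, k edges
  out2 <- withr::local_tempfile(fileext = ".dot")
  export_cc(ccs[[2]], I, out2, format = "dot")
  expect_true(any(grepl("p3", readLines(out2))))
  expect_error(export_cc(ccs[[1]], I, out, format = "gexf"))
})
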