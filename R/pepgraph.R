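## Bipartite peptide-protein graphs.
##
## Peptide-to-protein mappings are held as a sparse 0/1 incidence matrix
## (peptides along the rows, proteins along the columns). Its
## cross-product gives the protein adjacency matrix, whose entry (i, j)
## counts peptides shared by proteins i and j (diagonal: peptides per
## protein). Connected components of the protein graph bundle proteins
## linked - possibly transitively - by shared peptides; a single-protein
## component is an unambiguous identification.

#' Build a peptide-protein incidence matrix
#'
#' @param pairs data.frame whose first two columns are peptide sequence
#'   and protein accession ("one protein per line" dialect); duplicated
#'   pairs collapse to a single membership.
#' @return a sparse 0/1 `dgCMatrix` with peptides as rows and proteins as
#'   columns, both in first-appearance order.
#' @examples
#' I <- build_incidence(data.frame(peptide = c("p1", "p2", "p2"),
#'                                 protein = c("A", "A", "B")))
#' @export
build_incidence <- function(pairs) {
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2L)
  pep <- as.character(pairs[[1L]])
  prot <- as.character(pairs[[2L]])
  if (length(pep) == 0L) stop_("'pairs' is empty")
  if (any(!nzchar(pep)) || any(!nzchar(prot)))
    stop_("empty peptide or protein identifier in 'pairs'")
  pep_lev <- unique(pep)
  prot_lev <- unique(prot)
  I <- Matrix::sparseMatrix(
    i = match(pep, pep_lev), j = match(prot, prot_lev), x = 1,
    dims = c(length(pep_lev), length(prot_lev)),
    dimnames = list(pep_lev, prot_lev),
    use.last.ij = TRUE
  )
  methods::as(I, "CsparseMatrix")
}

#' Restrict an incidence matrix to a set of proteins
#'
#' Keeps the given protein columns and drops peptides left with no
#' parent, which is exactly the incidence a search against the restricted
#' database would produce.
#'
#' @param I incidence matrix from [build_incidence()].
#' @param proteins character vector of accessions to keep.
#' @return the restricted sparse incidence matrix.
#' @export
restrict_incidence <- function(I, proteins) {
  keep <- colnames(I) %in% proteins
  if (!any(keep)) stop_("no protein of 'I' is in 'proteins'")
  out <- I[, keep, drop = FALSE]
  out[Matrix::rowSums(out) > 0, , drop = FALSE]
}

#' Protein adjacency matrix from an incidence matrix
#'
#' The cross-product `t(I) %*% I` over the integers: off-diagonal entry
#' (i, j) is the number of peptides shared by proteins i and j, the
#' diagonal holds each protein's peptide count.
#'
#' @param I incidence matrix from [build_incidence()].
#' @return a symmetric sparse matrix with the proteins of `I`.
#' @export
adjacency_from_incidence <- function(I) {
  Matrix::crossprod(I)
}

## Union-find with path halving; returns root per element.
.union_find <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(edges_i)) {
    ri <- find(edges_i[k]); rj <- find(edges_j[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), find, 0L)
}

#' Connected components of the peptide-protein graph
#'
#' Partitions the proteins using union-find over the nonzero off-diagonal
#' entries of the adjacency matrix, then annotates each component with
#' all peptides mapping to its proteins. Every protein and every peptide
#' of `I` lands in exactly one component. Components are reported in
#' first-appearance order of their first protein and classified
#' `SINGLE_PROTEIN` or `MULTI_PROTEIN`.
#'
#' @param A adjacency matrix from [adjacency_from_incidence()]; computed
#'   from `I` when omitted.
#' @param I the incidence matrix the adjacency was derived from.
#' @return an object of class `cc_list`: a list of components, each with
#'   elements `proteins`, `peptides` and `kind`.
#' @export
connected_components <- function(A = NULL, I) {
  if (is.null(A)) A <- adjacency_from_incidence(I)
  stopifnot(ncol(A) == ncol(I))
  n <- ncol(A)
  tri <- Matrix::summary(methods::as(methods::as(A, "generalMatrix"),
                                     "TsparseMatrix"))
  off <- tri$i != tri$j & tri$x != 0
  root <- .union_find(n, tri$i[off], tri$j[off])
  comp_id <- match(root, unique(root))  # first-appearance order
  pep_tri <- Matrix::summary(methods::as(I, "TsparseMatrix"))
  pep_first <- pep_tri[!duplicated(pep_tri$i), , drop = FALSE]
  pep_comp <- comp_id[pep_first$j[order(pep_first$i)]]
  prot_names <- colnames(I)
  pep_names <- rownames(I)
  ccs <- lapply(seq_len(max(comp_id)), function(k) {
    prots <- prot_names[comp_id == k]
    list(proteins = prots,
         peptides = pep_names[pep_comp == k],
         kind = if (length(prots) == 1L) "SINGLE_PROTEIN" else "MULTI_PROTEIN")
  })
  structure(ccs, class = "cc_list")
}

#' @export
print.cc_list <- function(x, ...) {
  kinds <- vapply(x, `[[`, "", "kind")
  cat(sprintf("cc_list: %d connected components (%d single-protein, %d multi-protein)\n",
              length(x), sum(kinds == "SINGLE_PROTEIN"),
              sum(kinds == "MULTI_PROTEIN")))
  invisible(x)
}

#' Multi-protein connected components via the reduced-matrix strategy
#'
#' For large datasets the incidence matrix is first pruned: proteins
#' sharing no peptide are removed together with the peptides unique to
#' them, and components are computed on the pruned matrix. This returns
#' exactly the multi-protein components of the full computation at a
#' fraction of the cost; single-protein components remain recoverable
#' from the original matrix.
#'
#' @param I incidence matrix from [build_incidence()].
#' @return a `cc_list` containing only `MULTI_PROTEIN` components
#'   (possibly empty).
#' @export
reduced_cc <- function(I) {
  shared_rows <- Matrix::rowSums(I) >= 2
  if (!any(shared_rows)) return(structure(list(), class = "cc_list"))
  sharing_prot <- Matrix::colSums(I[shared_rows, , drop = FALSE]) > 0
  Ir <- I[, sharing_prot, drop = FALSE]
  Ir <- Ir[Matrix::rowSums(Ir) > 0, , drop = FALSE]
  connected_components(I = Ir)
}

#' Group proteins identified by identical peptide sets
#'
#' Proteins are partitioned by exact equality of their mapped peptide
#' sets; a multi-protein group holds indistinguishable proteins. A
#' peptide set strictly contained in another's does not merge the two
#' groups. Every group lies within exactly one connected component.
#'
#' @param I incidence matrix from [build_incidence()].
#' @return a list of class `protein_groups`; each group has `proteins`,
#'   `peptides` and `kind` (`SINGLE` or `MULTI`).
#' @export
protein_groups <- function(I) {
  tri <- Matrix::summary(methods::as(I, "TsparseMatrix"))
  rows_by_prot <- split(tri$i, tri$j)
  key <- vapply(rows_by_prot, function(r) paste(sort(r), collapse = ","), "")
  groups <- split(as.integer(names(rows_by_prot)), key)
  # first-appearance order of each group's first protein
  groups <- groups[order(vapply(groups, min, 0L))]
  out <- lapply(groups, function(cols) {
    peps <- rownames(I)[sort(unique(unlist(rows_by_prot[as.character(cols)])))]
    list(proteins = colnames(I)[cols], peptides = peps,
         kind = if (length(cols) == 1L) "SINGLE" else "MULTI")
  })
  names(out) <- NULL
  structure(out, class = "protein_groups")
}

#' @export
print.protein_groups <- function(x, ...) {
  kinds <- vapply(x, `[[`, "", "kind")
  cat(sprintf("protein_groups: %d groups (%d single-protein, %d multi-protein)\n",
              length(x), sum(kinds == "SINGLE"), sum(kinds == "MULTI")))
  invisible(x)
}

#' Ambiguity metrics of a set of connected components
#'
#' Summarises protein-inference ambiguity: the number of components, the
#' percentage of single-protein components, the percentage of specific
#' peptides (peptides mapping to exactly one protein of `I`), and, per
#' multi-protein component, the ratio between its number of proteins and
#' the number of distinct genes encoding them. Proteins without a gene
#' annotation count as their own gene; a message reports how many.
#'
#' @param ccs a `cc_list` partitioning the proteins of `I`.
#' @param I the incidence matrix the components were computed from.
#' @param gene_map optional named character vector, accession -> gene id.
#' @return a list of class `ambiguity_metrics` with fields `n_cc`,
#'   `n_single_protein_cc`, `pct_single_protein_cc`,
#'   `pct_specific_peptides` and `protein_to_gene_ratios`.
#' @export
ambiguity_metrics <- function(ccs, I, gene_map = NULL) {
  stopifnot(inherits(ccs, "cc_list"))
  kinds <- vapply(ccs, `[[`, "", "kind")
  n_cc <- length(ccs)
  n_single <- sum(kinds == "SINGLE_PROTEIN")
  specific <- Matrix::rowSums(I) == 1
  ratios <- numeric(0)
  if (any(kinds == "MULTI_PROTEIN")) {
    multi <- ccs[kinds == "MULTI_PROTEIN"]
    unannotated <- 0L
    ratios <- vapply(multi, function(cc) {
      g <- if (is.null(gene_map)) rep(NA_character_, length(cc$proteins))
           else unname(gene_map[cc$proteins])
      miss <- is.na(g)
      unannotated <<- unannotated + sum(miss)
      g[miss] <- paste0(".self.", cc$proteins[miss])
      length(cc$proteins) / length(unique(g))
    }, 0)
    if (!is.null(gene_map) && unannotated > 0L)
      message(unannotated,
              " protein(s) without gene annotation counted as their own gene")
  }
  structure(
    list(n_cc = n_cc,
         n_single_protein_cc = n_single,
         pct_single_protein_cc = if (n_cc > 0) 100 * n_single / n_cc else NA_real_,
         pct_specific_peptides = 100 * mean(specific),
         protein_to_gene_ratios = unname(ratios)),
    class = "ambiguity_metrics"
  )
}

#' @export
print.ambiguity_metrics <- function(x, ...) {
  cat(sprintf(
    "ambiguity_metrics: %d CCs | %.1f%% single-protein | %.1f%% specific peptides\n",
    x$n_cc, x$pct_single_protein_cc, x$pct_specific_peptides))
  if (length(x$protein_to_gene_ratios))
    cat(sprintf("  protein-to-gene ratio in multi-protein CCs: mean %.2f\n",
                mean(x$protein_to_gene_ratios)))
  invisible(x)
}

#' Export a connected component as a bipartite graph file
#'
#' Writes the component's peptide-protein subgraph in GraphML or DOT
#' format. Vertices carry a `kind` attribute (`"peptide"` or
#' `"protein"`); peptides carry `specific` ("yes"/"no", evaluated on the
#' full incidence matrix) and proteins optionally `expressed`
#' ("yes"/"no") when a vector of transcript-supported accessions is
#' given.
#'
#' @param cc one element of a `cc_list`.
#' @param I the incidence matrix the component belongs to.
#' @param path output file path.
#' @param format `"graphml"` or `"dot"`.
#' @param expressed optional character vector of accessions with
#'   transcript support.
#' @return `path`, invisibly.
#' @export
export_cc <- function(cc, I, path, format = c("graphml", "dot"),
                      expressed = NULL) {
  format <- match.arg(format)
  if (!all(cc$proteins %in% colnames(I)) || !all(cc$peptides %in% rownames(I)))
    stop_("component does not belong to this incidence matrix")
  sub <- I[cc$peptides, cc$proteins, drop = FALSE]
  tri <- Matrix::summary(methods::as(sub, "TsparseMatrix"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = rownames(sub)[tri$i], to = colnames(sub)[tri$j]),
    directed = FALSE,
    vertices = data.frame(
      name = c(rownames(sub), colnames(sub)),
      kind = c(rep("peptide", nrow(sub)), rep("protein", ncol(sub))),
      stringsAsFactors = FALSE
    )
  )
  specific <- Matrix::rowSums(I) == 1
  v_kind <- igraph::V(g)$kind
  spec_attr <- rep(NA_character_, length(v_kind))
  spec_attr[v_kind == "peptide"] <-
    ifelse(specific[igraph::V(g)$name[v_kind == "peptide"]], "yes", "no")
  g <- igraph::set_vertex_attr(g, "specific", value = spec_attr)
  if (!is.null(expressed)) {
    expr_attr <- rep(NA_character_, length(v_kind))
    expr_attr[v_kind == "protein"] <-
      ifelse(igraph::V(g)$name[v_kind == "protein"] %in% expressed,
             "yes", "no")
    g <- igraph::set_vertex_attr(g, "expressed", value = expr_attr)
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
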