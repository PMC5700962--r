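# Mutual-exclusivity mutation network: binary mutation matrix A integrating
# CNV calls and somatic mutations, vertex weights h_i = m_i / m, edge weights
# V_ij = #(exactly one mutated) / #(at least one mutated), and candidate
# modulator selection by vertex clustering.

#' Build the binary mutation matrix A
#'
#' \code{a_{sj} = 1} iff sample \code{s} carries a called CNV (state +1/-1)
#' or a somatic mutation in gene \code{j}; restricted to the retained gene
#' set. Per-gene provenance (cnv / somatic / both) is recorded.
#'
#' @param cnv_states Gene x sample CNV state matrix over \{-1, 0, 1\}.
#' @param somatic Binary gene x sample somatic-call matrix.
#' @param gene_filter Character vector of retained genes.
#' @return Binary samples x genes matrix with attribute \code{provenance}.
#' @export
build_mutation_matrix <- function(cnv_states, somatic, gene_filter) {
  samples <- colnames(cnv_states)
  if (!setequal(samples, colnames(somatic)))
    stop_value("build_mutation_matrix: CNV and somatic sample sets differ")
  cn <- align_matrix(abs(cnv_states), gene_filter, samples)
  so <- align_matrix(somatic, gene_filter, samples)
  A <- t((cn == 1) | (so == 1)) * 1L
  prov <- ifelse(rowSums(cn == 1) > 0,
                 ifelse(rowSums(so == 1) > 0, "both", "cnv"),
                 ifelse(rowSums(so == 1) > 0, "somatic", "none"))
  structure(A, provenance = stats::setNames(prov, gene_filter))
}

#' Vertex weights h_i = m_i / m
#'
#' Per-gene mutation count over the sample count.
#' @param A Binary samples x genes mutation matrix.
#' @return Named numeric vector in [0, 1].
#' @export
vertex_weights <- function(A) {
  assert_that(nrow(A) > 0, "vertex_weights: no samples")
  colSums(A) / nrow(A)
}

#' Mutual-exclusivity edge weight between two genes
#'
#' Number of samples in which exactly one of the pair is mutated divided by
#' the number of samples in which at least one is mutated. 0 means perfect
#' co-occurrence, 1 perfect mutual exclusivity.
#'
#' @param col_i,col_j Binary mutation columns of equal length.
#' @return Weight in [0, 1], or \code{NA} if no sample mutates either gene
#'   (no edge).
#' @export
edge_weight <- function(col_i, col_j) {
  assert_that(length(col_i) == length(col_j), "edge_weight: unequal lengths")
  s <- col_i + col_j
  atleast <- sum(s >= 1)
  if (atleast == 0) return(NA_real_)
  sum(s == 1) / atleast
}

#' Build the weighted mutation network
#'
#' Vertices are genes with \code{h >= min_vertex_weight}; all pairwise edge
#' weights V are computed jointly from co-occurrence counts. Pairs with no
#' mutated sample have no edge (\code{NA} in the V matrix).
#'
#' @param A Binary samples x genes mutation matrix.
#' @param min_vertex_weight Minimum vertex weight (default 0.02, mirroring
#'   the 2\% mutation-frequency screen).
#' @return List of class \code{mutation_network}: \code{genes}, \code{h},
#'   \code{V} (symmetric matrix), \code{provenance}.
#' @export
build_network <- function(A, min_vertex_weight = 0.02) {
  h <- vertex_weights(A)
  keep <- names(h)[h >= min_vertex_weight]
  prov <- attr(A, "provenance")
  A2 <- A[, keep, drop = FALSE]
  cooc <- crossprod(A2)                    # co-mutation counts
  mi <- diag(cooc)
  union <- outer(mi, mi, "+") - cooc
  V <- (union - cooc) / union              # NA where union == 0
  V[union == 0] <- NA_real_
  diag(V) <- 0
  structure(list(genes = keep, h = h[keep], V = V,
                 provenance = if (!is.null(prov)) prov[keep] else NULL),
            class = "mutation_network")
}

#' @export
print.mutation_network <- function(x, ...) {
  cat(sprintf("mutation_network: %d vertices, mean h = %.3f, mean V = %.3f\n",
              length(x$genes), mean(x$h), mean(x$V[upper.tri(x$V)], na.rm = TRUE)))
  invisible(x)
}

#' Select candidate modulators by vertex clustering
#'
#' Average-linkage hierarchical clustering of network vertices with pairwise
#' distance V (co-occurring genes cluster together); within each of
#' \code{n_clusters} clusters, genes are ranked by vertex weight h (gene id
#' as tie-break) and the top \code{top_per_cluster} are taken.
#'
#' @param net A \code{mutation_network}.
#' @param n_clusters Number of vertex clusters (default 20).
#' @param top_per_cluster Genes taken per cluster (default 40).
#' @return data.frame of class \code{modulator_pool} with columns gene, h,
#'   cluster, provenance, ordered by decreasing h (gene id tie-break).
#' @export
select_candidate_modulators <- function(net, n_clusters = 20L,
                                        top_per_cluster = 40L) {
  nv <- length(net$genes)
  assert_that(nv > 0, "select_candidate_modulators: empty network")
  assert_that(n_clusters <= nv,
              "select_candidate_modulators: n_clusters (%d) exceeds vertex count (%d)",
              n_clusters, nv)
  D <- net$V
  D[is.na(D)] <- 1
  if (nv == 1L) {
    cl <- stats::setNames(1L, net$genes)
  } else {
    tree <- stats::hclust(stats::as.dist(D), method = "average")
    cl <- stats::cutree(tree, k = n_clusters)
  }
  picked <- unlist(lapply(split(net$genes, cl[net$genes]), function(gs) {
    gs[order(-net$h[gs], gs)][seq_len(min(top_per_cluster, length(gs)))]
  }), use.names = FALSE)
  picked <- picked[order(-net$h[picked], picked)]
  out <- data.frame(gene = picked, h = unname(net$h[picked]),
                    cluster = unname(cl[picked]),
                    provenance = if (!is.null(net$provenance))
                      unname(net$provenance[picked]) else NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("modulator_pool", "data.frame")
  out
}
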