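# Weighted gene co-expression analysis: absolute-correlation similarity,
# soft-threshold adjacency, topological overlap, hierarchical module
# detection, module eigengenes, module membership and gene significance.

#' Absolute-correlation similarity matrix
#'
#' \eqn{s_{ij} = |cor(x_i, x_j)|} (Pearson) over samples; the unsigned
#' co-expression similarity.
#'
#' @param X Gene x sample expression matrix with >= 3 samples and per-gene
#'   variance > 0.
#' @return Symmetric gene x gene matrix in [0, 1] with unit diagonal.
#' @export
similarity <- function(X) {
  assert_that(ncol(X) >= 3, "similarity: need at least 3 samples")
  v <- apply(X, 1, stats::var)
  if (any(v == 0))
    stop_value("similarity: zero-variance gene(s): %s",
               paste(utils::head(rownames(X)[v == 0], 5), collapse = ", "))
  s <- abs(stats::cor(t(X)))
  diag(s) <- 1
  s
}

#' Soft-threshold adjacency
#'
#' \eqn{\alpha_{ij} = s_{ij}^\beta}, emphasizing strong correlations while
#' keeping the network weighted.
#'
#' @param S Similarity matrix in [0, 1].
#' @param beta Soft-threshold power, >= 1.
#' @return Adjacency matrix with attribute \code{beta}.
#' @export
adjacency <- function(S, beta) {
  assert_that(is.numeric(beta) && length(beta) == 1 && beta >= 1,
              "adjacency: beta must be >= 1")
  structure(S^beta, beta = beta)
}

#' Pick the soft-threshold power by scale-free topology fit
#'
#' Returns the smallest candidate power for which the connectivity
#' distribution fits a power law with (slope-signed) R^2 at or above
#' \code{rsq_target}; if none qualifies, falls back to \code{default} with a
#' warning.
#'
#' @param S Similarity matrix.
#' @param candidates Candidate powers (default 1:20).
#' @param rsq_target Scale-free fit target (default 0.8).
#' @param default Fallback power (default 6).
#' @param n_breaks Connectivity histogram bins (default 10).
#' @return Selected power (numeric scalar) with attribute \code{fit_table}.
#' @export
pick_soft_threshold <- function(S, candidates = 1:20, rsq_target = 0.8,
                                default = 6, n_breaks = 10) {
  assert_that(length(candidates) > 0, "pick_soft_threshold: no candidates")
  fits <- vapply(candidates, function(b) scale_free_rsq(S^b, n_breaks), 0)
  tab <- data.frame(power = candidates, rsq = fits)
  ok <- which(fits >= rsq_target)
  if (length(ok) == 0) {
    warning(sprintf(
      "no candidate power reached scale-free R^2 >= %.2f; using default %s",
      rsq_target, default))
    return(structure(default, fit_table = tab))
  }
  structure(candidates[min(ok)], fit_table = tab)
}

# signed scale-free fit index: R^2 of log10 p(k) ~ log10 k, negated when the
# slope is positive (scale-free topology requires a decreasing law)
scale_free_rsq <- function(A, n_breaks = 10) {
  diag(A) <- 0
  k <- colSums(A)
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(0)
  cut_k <- cut(k, breaks = n_breaks)
  dk <- tapply(k, cut_k, mean)
  pk <- tabulate(as.integer(cut_k), n_breaks) / length(k)
  keep <- !is.na(dk) & pk > 0 & dk > 0
  if (sum(keep) < 3) return(0)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] > 0) -r2 else r2
}

#' Topological overlap matrix
#'
#' \deqn{\omega_{ij} = (\alpha_{ij} + u_{ij}) / (min(m_i, m_j) + 1 -
#' \alpha_{ij})} with connectivity \eqn{m_i = \sum_{k \ne i} \alpha_{ik}} and
#' shared-neighbor term \eqn{u_{ij} = \sum_{k \ne i,j} \alpha_{ik}
#' \alpha_{kj}}; the diagonal is set to 1 by convention.
#'
#' @param A Symmetric adjacency matrix in [0, 1].
#' @return Topological overlap matrix in [0, 1].
#' @export
tom <- function(A) {
  assert_that(isSymmetric(unname(A)), "tom: adjacency must be symmetric")
  diag(A) <- 0
  m <- colSums(A)
  U <- A %*% A           # diag(A)=0 makes this exclude k in {i, j}
  denom <- outer(m, m, pmin) + 1 - A
  W <- (A + U) / denom
  diag(W) <- 1
  dimnames(W) <- dimnames(A)
  W
}

# WGCNA module color order
module_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue",
                   "darkred", "darkgreen", "darkturquoise", "darkgrey",
                   "orange", "darkorange", "white", "skyblue", "saddlebrown",
                   "steelblue", "paleturquoise", "violet", "darkolivegreen",
                   "darkmagenta")

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' \eqn{1 - \omega}, cut at a fixed fraction of the maximum merge height.
#' Clusters smaller than \code{min_module_size} are merged into "grey"
#' (unassigned); surviving modules are labeled by decreasing size with the
#' conventional color order (turquoise, blue, brown, ...).
#'
#' @param T Topological overlap matrix.
#' @param min_module_size Minimum module size (default 20).
#' @param cut_height Cut as a fraction of the maximum merge height
#'   (default 0.99).
#' @return List of class \code{module_assignment}: \code{colors} (named gene
#'   -> color, "grey" = unassigned), \code{eigengenes} (NULL until
#'   \code{\link{eigengene}} is applied), \code{tree} (the hclust object).
#' @export
detect_modules <- function(T, min_module_size = 20L, cut_height = 0.99) {
  assert_that(min_module_size >= 2, "detect_modules: min_module_size must be >= 2")
  d <- stats::as.dist(1 - T)
  tree <- stats::hclust(d, method = "average")
  h <- cut_height * max(tree$height)
  cl <- stats::cutree(tree, h = h)
  tabs <- sort(table(cl), decreasing = TRUE)
  colors <- stats::setNames(rep("grey", length(cl)), rownames(T))
  ci <- 0L
  for (lab in names(tabs)) {
    if (tabs[[lab]] < min_module_size) next
    ci <- ci + 1L
    col <- if (ci <= length(module_colors)) module_colors[ci] else paste0("module", ci)
    colors[cl == as.integer(lab)] <- col
  }
  structure(list(colors = colors, tree = tree, cut_height = h,
                 min_module_size = min_module_size),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  tb <- sort(table(x$colors[x$colors != "grey"]), decreasing = TRUE)
  cat(sprintf("module_assignment: %d modules over %d genes (%d grey)\n",
              length(tb), length(x$colors), sum(x$colors == "grey")))
  if (length(tb)) print(tb)
  invisible(x)
}

#' Module eigengene
#'
#' First principal component across samples of the per-gene standardized
#' module submatrix, unit norm, with sign oriented so that the mean
#' correlation with member genes is non-negative.
#'
#' @param X_module Gene x sample expression submatrix (>= 2 genes).
#' @return Named numeric sample vector of unit norm.
#' @export
eigengene <- function(X_module) {
  assert_that(nrow(X_module) >= 2, "eigengene: module must have >= 2 genes")
  Z <- t(scale(t(X_module)))
  if (anyNA(Z))
    stop_value("eigengene: zero-variance gene(s): %s",
               paste(utils::head(rownames(X_module)[apply(X_module, 1, stats::var) == 0], 5),
                     collapse = ", "))
  sv <- svd(Z, nu = 0, nv = 1)
  E <- sv$v[, 1]
  if (mean(Z %*% E) < 0) E <- -E
  stats::setNames(E, colnames(X_module))
}

#' Module membership of a gene
#'
#' Pearson correlation of a gene's expression profile with a module
#' eigengene.
#'
#' @param x_i Gene expression vector.
#' @param E Eigengene over the same samples.
#' @return Correlation in [-1, 1].
#' @export
module_membership <- function(x_i, E) {
  assert_that(length(x_i) == length(E), "module_membership: sample sets differ")
  if (stats::var(x_i) == 0 || stats::var(E) == 0)
    stop_value("module_membership: zero-variance input")
  stats::cor(x_i, E)
}

#' Gene significance for the resistant/sensitive trait
#'
#' Absolute point-biserial correlation of each gene's expression with the
#' binary response (resistant = 1, sensitive = 0). A value of 0 means the
#' gene carries no linear association with drug response; higher values mark
#' biologically significant genes.
#'
#' @param X Gene x sample expression matrix.
#' @param labels Named resistant/sensitive vector.
#' @return Named vector of gene significance values in [0, 1].
#' @export
gene_significance <- function(X, labels) {
  check_labels(labels, colnames(X))
  trait <- as.numeric(labels[colnames(X)] == "resistant")
  gs <- abs(as.vector(stats::cor(t(X), trait)))
  gs[is.na(gs)] <- 0    # constant genes carry no association
  stats::setNames(gs, rownames(X))
}
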