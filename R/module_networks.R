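# Module-network learning: per-module regulatory programs (binary regression
# trees over candidate modulator mutation statuses) scored by the
# normal-gamma marginal likelihood, fitted by a classification EM that
# alternates tree learning (M-step) with gene reassignment (E-step).
#
# The model score is
#   log P(C, N) = sum_modules sum_genes sum_leaves lml(values) - penalty * #nodes
# where lml is the normal-gamma log marginal of the gene's expression values
# in the samples routed to a leaf. Scoring each member gene's leaf block
# independently makes the objective additive over genes, so the per-gene
# argmax reassignment and the kept-if-better tree update each provably never
# decrease the score.

#' Normal-gamma prior for leaf expression values
#'
#' Conjugate prior for a Gaussian with unknown mean and precision:
#' \eqn{\tau ~ Gamma(\alpha_0, \beta_0)},
#' \eqn{\mu | \tau ~ N(\mu_0, 1/(\kappa_0 \tau))}. Defaults assume per-gene
#' z-scored expression.
#'
#' @param mu0 Prior mean (default 0).
#' @param kappa0 Prior precision-scaling count (> 0, default 1).
#' @param alpha0 Shape (> 0, default 1).
#' @param beta0 Rate (> 0, default 1).
#' @return List of class \code{ng_prior}.
#' @export
normal_gamma_prior <- function(mu0 = 0, kappa0 = 1, alpha0 = 1, beta0 = 1) {
  assert_that(kappa0 > 0 && alpha0 > 0 && beta0 > 0,
              "normal_gamma_prior: kappa0, alpha0, beta0 must be > 0")
  structure(list(mu0 = mu0, kappa0 = kappa0, alpha0 = alpha0, beta0 = beta0),
            class = "ng_prior")
}

# vectorized log marginal likelihood from sufficient statistics
# (n observations with given mean and centered sum of squares)
lml_stats <- function(n, mean, ss, prior) {
  if (length(n) == 1 && n == 0) return(0)
  k0 <- prior$kappa0; a0 <- prior$alpha0; b0 <- prior$beta0; mu0 <- prior$mu0
  kn <- k0 + n
  an <- a0 + n / 2
  bn <- b0 + 0.5 * ss + k0 * n * (mean - mu0)^2 / (2 * kn)
  out <- lgamma(an) - lgamma(a0) + a0 * log(b0) - an * log(bn) +
    0.5 * (log(k0) - log(kn)) - 0.5 * n * log(2 * pi)
  out[n == 0] <- 0
  out
}

#' Normal-gamma log marginal likelihood of a value vector
#'
#' Closed-form marginal of the data under the conjugate normal-gamma model,
#' via posterior hyperparameter updates. The empty vector scores 0; the
#' score is invariant to the order of the values.
#'
#' @param values Numeric vector (finite values).
#' @param prior A \code{\link{normal_gamma_prior}}.
#' @return Log marginal likelihood (scalar).
#' @export
leaf_log_marginal <- function(values, prior = normal_gamma_prior()) {
  n <- length(values)
  if (n == 0) return(0)
  assert_that(all(is.finite(values)), "leaf_log_marginal: values must be finite")
  m <- mean(values)
  lml_stats(n, m, sum((values - m)^2), prior)
}

# sum over genes of leaf marginals for an expression block (genes x samples
# restricted to one leaf's sample index set)
block_score <- function(X, idx, prior) {
  n <- length(idx)
  if (n == 0) return(0)
  V <- X[, idx, drop = FALSE]
  mu <- rowMeans(V)
  ss <- rowSums((V - mu)^2)
  sum(lml_stats(n, mu, ss, prior))
}

# per-gene vector of leaf marginals summed over a program's leaves
gene_scores_under <- function(X, program, prior) {
  out <- numeric(nrow(X))
  for (idx in program$leaf_samples) {
    n <- length(idx)
    if (n == 0) next
    V <- X[, idx, drop = FALSE]
    mu <- rowMeans(V)
    ss <- rowSums((V - mu)^2)
    out <- out + lml_stats(n, mu, ss, prior)
  }
  stats::setNames(out, rownames(X))
}

collect_leaves <- function(node) {
  if (node$type == "leaf") return(list(node$samples))
  c(collect_leaves(node$no), collect_leaves(node$yes))
}

collect_splits <- function(node) {
  if (node$type == "leaf") return(character(0))
  c(node$modulator, collect_splits(node$no), collect_splits(node$yes))
}

#' Learn a regulatory program (regression tree) for one module
#'
#' Greedy top-down search: at each node every unused candidate modulator's
#' binary mutation-status split is scored, and the split with the largest
#' positive score gain (after subtracting the per-node complexity penalty)
#' is accepted; otherwise the node becomes a leaf. Ties break on modulator
#' id order.
#'
#' @param member_expression Gene x sample matrix of the module's members.
#' @param modulator_status Modulator x sample binary status matrix.
#' @param prior A \code{\link{normal_gamma_prior}}.
#' @param penalty Complexity penalty per decision node.
#' @param max_depth Maximum tree depth (default 3 decision levels).
#' @param min_leaf Minimum samples per leaf (default 5).
#' @return List of class \code{regulatory_program}: \code{tree},
#'   \code{modulators}, \code{n_nodes}, \code{leaf_samples}.
#' @export
learn_tree <- function(member_expression, modulator_status,
                       prior = normal_gamma_prior(), penalty = 0,
                       max_depth = 3L, min_leaf = 5L) {
  X <- member_expression
  assert_that(nrow(X) >= 1, "learn_tree: need at least one member gene")
  assert_that(nrow(modulator_status) >= 1, "learn_tree: need candidate modulators")
  mods <- sort(rownames(modulator_status))
  m <- ncol(X)

  build <- function(idx, used, depth) {
    here <- block_score(X, idx, prior)
    if (depth < max_depth) {
      best <- list(gain = 0)
      for (g in setdiff(mods, used)) {
        on <- idx[modulator_status[g, idx] == 1]
        off <- setdiff(idx, on)
        if (length(on) < min_leaf || length(off) < min_leaf) next
        gain <- block_score(X, on, prior) + block_score(X, off, prior) -
          penalty - here
        if (gain > best$gain + 1e-12) best <- list(gain = gain, g = g,
                                                   on = on, off = off)
      }
      if (best$gain > 0) {
        return(list(type = "split", modulator = best$g,
                    no = build(best$off, c(used, best$g), depth + 1L),
                    yes = build(best$on, c(used, best$g), depth + 1L)))
      }
    }
    list(type = "leaf", samples = idx, n = length(idx))
  }

  tree <- build(seq_len(m), character(0), 0L)
  structure(list(tree = tree,
                 modulators = unique(collect_splits(tree)),
                 n_nodes = length(collect_splits(tree)),
                 leaf_samples = collect_leaves(tree)),
            class = "regulatory_program")
}

# penalized score of one program on a member block
program_score <- function(X, program, prior, penalty) {
  sum(gene_scores_under(X, program, prior)) - penalty * program$n_nodes
}

#' Total model score log P(C, N)
#'
#' Sum over modules and member genes of the normal-gamma leaf marginals of
#' the expression values routed to each leaf, plus the structure term
#' \code{-penalty * total decision nodes}.
#'
#' @param model A \code{module_network} model (or a list with
#'   \code{assignment} and \code{programs}).
#' @param X Gene x sample expression matrix (same scale the model was fitted
#'   on).
#' @param penalty Per-node complexity penalty.
#' @return Numeric scalar score.
#' @export
score_model <- function(model, X, penalty) {
  tot <- 0
  nodes <- 0
  for (q in names(model$programs)) {
    members <- names(model$assignment)[model$assignment == q]
    if (length(members) == 0) next
    tot <- tot + sum(gene_scores_under(X[members, , drop = FALSE],
                                       model$programs[[q]], model$prior))
    nodes <- nodes + model$programs[[q]]$n_nodes
  }
  tot - penalty * nodes
}

#' Reassign genes to the best-predicting module
#'
#' Each gene moves to the module whose learned program gives its expression
#' vector the highest summed leaf marginal; ties break toward the current
#' module, then module order. Genes whose best program score falls below the
#' single-leaf background score stay put, preventing degenerate collapse.
#'
#' @param model A \code{module_network} model.
#' @param X Gene x sample expression matrix.
#' @param prior A \code{\link{normal_gamma_prior}}.
#' @return Named character vector, gene -> module label.
#' @export
reassign_genes <- function(model, X, prior = model$prior) {
  genes <- names(model$assignment)
  Xg <- X[genes, , drop = FALSE]
  qs <- names(model$programs)
  S <- vapply(qs, function(q) gene_scores_under(Xg, model$programs[[q]], prior),
              numeric(length(genes)))
  if (length(genes) == 1L) S <- matrix(S, 1, dimnames = list(genes, qs))
  bg <- vapply(seq_along(genes),
               function(i) leaf_log_marginal(Xg[i, ], prior), 0)
  out <- model$assignment
  for (i in seq_along(genes)) {
    cur <- out[[i]]
    best <- qs[which.max(S[i, ])]
    if (S[i, cur] >= S[i, best] - 1e-12) best <- cur   # tie -> stay
    if (S[i, best] < bg[i]) best <- cur                # background guard
    out[[i]] <- best
  }
  out
}

#' Fit a module-network model by classification EM
#'
#' Starting from co-expression modules, alternates (M-step) learning a
#' regulatory program per module -- keeping the previous program when the
#' freshly learned tree does not improve the penalized score on the current
#' members -- with (E-step) reassigning every gene to its best-predicting
#' module, until the score improves by less than \code{tol} or
#' \code{max_iter} is reached. The score trace is non-decreasing by
#' construction; empty modules are dropped.
#'
#' @param X Gene x sample expression matrix. With \code{scale = TRUE}
#'   (default) genes are z-scored across samples before fitting, matching
#'   the default prior.
#' @param initial_modules A \code{module_assignment} (from
#'   \code{\link{detect_modules}}) or a named gene -> label vector; "grey"
#'   genes are excluded.
#' @param modulator_status Candidate-modulator x sample binary mutation
#'   status matrix (rows from the modulator pool).
#' @param prior A \code{\link{normal_gamma_prior}}.
#' @param penalty Per-node complexity penalty; default
#'   \code{0.5 * log(total observations)} (BIC-flavored).
#' @param max_iter Maximum EM iterations (default 20).
#' @param tol Score-improvement convergence tolerance (default 1e-4).
#' @param max_depth,min_leaf Tree-learning controls.
#' @param scale Z-score genes before fitting (default TRUE).
#' @return Object of class \code{module_network}: \code{assignment},
#'   \code{programs}, \code{score}, \code{trace}, \code{prior},
#'   \code{penalty}, \code{converged}, \code{iterations}.
#' @export
module_network <- function(X, initial_modules, modulator_status,
                           prior = normal_gamma_prior(), penalty = NULL,
                           max_iter = 20L, tol = 1e-4,
                           max_depth = 3L, min_leaf = 5L, scale = TRUE) {
  assignment <- if (inherits(initial_modules, "module_assignment"))
    initial_modules$colors else initial_modules
  assignment <- assignment[assignment != "grey"]
  assert_that(length(assignment) > 0, "module_network: no assigned genes")
  assert_that(nrow(modulator_status) > 0, "module_network: empty modulator pool")
  genes <- intersect(names(assignment), rownames(X))
  assignment <- assignment[genes]
  X <- X[genes, colnames(modulator_status), drop = FALSE]
  if (scale) {
    sds <- apply(X, 1, stats::sd)
    X <- (X - rowMeans(X)) / ifelse(sds > 0, sds, 1)
  }
  if (is.null(penalty)) penalty <- 0.5 * log(length(X))

  model <- list(assignment = assignment, programs = list(), prior = prior,
                penalty = penalty)
  trace <- data.frame(iteration = integer(), step = character(),
                      score = numeric())
  score_prev <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ## M-step: (re)learn trees; keep previous program if better
    labs <- unique(model$assignment)
    programs <- list()
    for (q in labs) {
      members <- names(model$assignment)[model$assignment == q]
      cand <- learn_tree(X[members, , drop = FALSE], modulator_status,
                         prior, penalty, max_depth, min_leaf)
      old <- model$programs[[q]]
      if (!is.null(old) &&
          program_score(X[members, , drop = FALSE], old, prior, penalty) >
            program_score(X[members, , drop = FALSE], cand, prior, penalty)) {
        programs[[q]] <- old
      } else {
        programs[[q]] <- cand
      }
    }
    model$programs <- programs
    s_m <- score_model(model, X, penalty)
    trace <- rbind(trace, data.frame(iteration = it, step = "M", score = s_m))

    ## E-step: reassign genes; drop emptied modules
    model$assignment <- reassign_genes(model, X, prior)
    model$programs <- model$programs[unique(model$assignment)]
    s_e <- score_model(model, X, penalty)
    trace <- rbind(trace, data.frame(iteration = it, step = "E", score = s_e))

    if (is.finite(score_prev) && s_e - score_prev < tol) {
      converged <- TRUE
      score_prev <- s_e
      break
    }
    score_prev <- s_e
  }

  structure(list(assignment = model$assignment, programs = model$programs,
                 prior = prior, penalty = penalty, score = score_prev,
                 trace = trace, converged = converged, iterations = it,
                 modulator_status = modulator_status, scaled = scale,
                 X = X),
            class = "module_network")
}

#' Extract modulators and the modules they regulate
#'
#' All genes appearing in any decision node of the learned programs, each
#' with the set of modules it regulates.
#'
#' @param model A fitted \code{module_network}.
#' @return Named list: modulator gene -> character vector of module labels.
#' @export
extract_modulators <- function(model) {
  pairs <- lapply(names(model$programs), function(q) {
    mods <- model$programs[[q]]$modulators
    if (length(mods) == 0) return(NULL)
    data.frame(modulator = mods, module = q, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, pairs)
  if (is.null(long)) return(stats::setNames(list(), character(0)))
  lapply(split(long$module, long$modulator), unique)
}

#' @export
print.module_network <- function(x, ...) {
  cat(sprintf("module_network: %d modules, %d genes, score %.2f (%s after %d iterations)\n",
              length(x$programs), length(x$assignment), x$score,
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' @export
summary.module_network <- function(object, ...) {
  mods <- extract_modulators(object)
  sizes <- table(object$assignment)
  cat(sprintf("Module-network model: %d modules, %d member genes, %d modulators used\n",
              length(object$programs), length(object$assignment), length(mods)))
  cat(sprintf("Score %.3f, penalty/node %.3f, %d EM iterations (%s)\n",
              object$score, object$penalty, object$iterations,
              if (object$converged) "converged" else "max_iter reached"))
  for (q in names(object$programs)) {
    p <- object$programs[[q]]
    cat(sprintf("  %-12s %3d genes, %d splits: %s\n", q, sizes[[q]],
                p$n_nodes, paste(p$modulators, collapse = ", ")))
  }
  invisible(object)
}

#' @export
logLik.module_network <- function(object, ...) {
  structure(object$score, df = sum(vapply(object$programs, `[[`, 0L, "n_nodes")),
            class = "logLik")
}

#' @export
plot.module_network <- function(x, ...) {
  tr <- x$trace
  graphics::plot(seq_len(nrow(tr)), tr$score, type = "b",
                 pch = ifelse(tr$step == "M", 1, 19),
                 xlab = "EM half-step", ylab = "log P(C, N)",
                 main = "Module-network score trace", ...)
  graphics::legend("bottomright", pch = c(1, 19),
                   legend = c("M-step", "E-step"), bty = "n")
  invisible(x)
}

#' Predict module membership for gene expression profiles
#'
#' Assigns each row of \code{newdata} to the module whose program gives it
#' the highest summed leaf marginal (z-scored first if the model was fitted
#' on z-scored data).
#'
#' @param object A fitted \code{module_network}.
#' @param newdata Gene x sample matrix over the model's samples.
#' @param ... Unused.
#' @return Named character vector, gene -> module label.
#' @export
predict.module_network <- function(object, newdata, ...) {
  X <- newdata[, colnames(object$modulator_status), drop = FALSE]
  if (object$scaled) {
    sds <- apply(X, 1, stats::sd)
    X <- (X - rowMeans(X)) / ifelse(sds > 0, sds, 1)
  }
  qs <- names(object$programs)
  S <- vapply(qs, function(q) gene_scores_under(X, object$programs[[q]],
                                                object$prior),
              numeric(nrow(X)))
  if (nrow(X) == 1L) S <- matrix(S, 1, dimnames = list(rownames(X), qs))
  stats::setNames(qs[apply(S, 1, which.max)], rownames(X))
}
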