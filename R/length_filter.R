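# Gene-length mutation-bias filter: long genes accumulate passenger
# mutations simply because they present a larger target. A monotone spline
# logistic model of mutation status on cDNA length yields a probability
# weight vector (PWV); weighted resampling of per-sample mutation sets then
# measures how often each gene would be "mutated" by length alone, and genes
# whose resampling frequency exceeds a threshold are removed as
# length-explainable.

#' Fit the probability weight vector (PWV) from gene lengths
#'
#' Logistic regression of mutation status on a cubic spline basis of
#' log cDNA length (the covariate is heavily right-skewed) with six interior
#' knots at log-length quantiles, followed by an isotonic (monotone
#' non-decreasing in length) projection of the fitted probabilities. The mean fitted probability equals the observed mutation
#' proportion (canonical-link calibration, preserved by the isotonic
#' projection).
#'
#' \code{mutated_genes} may be a single gene set, or a list of per-sample
#' gene sets, in which case the per-sample indicators are stacked (each gene
#' contributes one binomial observation per sample) and the PWV estimates a
#' per-sample mutation probability -- the form consumed by
#' \code{\link{resample_frequencies}}.
#'
#' @param mutated_genes Character vector of mutated genes, or a list of
#'   per-sample character vectors; all must be contained in \code{universe}.
#' @param universe Character vector of background genes (the tested universe).
#' @param lengths Named numeric vector of cDNA lengths covering the universe.
#' @return Named numeric vector of weights in (0, 1), class \code{pwv}.
#' @export
fit_pwv <- function(mutated_genes, universe, lengths) {
  assert_that(all(universe %in% names(lengths)),
              "fit_pwv: lengths must cover the universe")
  len <- log(lengths[universe])
  if (is.list(mutated_genes)) {
    sets <- lapply(mutated_genes, intersect, universe)
    assert_that(all(vapply(sets, length, 1L) ==
                      vapply(mutated_genes, length, 1L)),
                "fit_pwv: mutated_genes must be subsets of the universe")
    succ <- rowSums(vapply(sets, function(s) universe %in% s,
                           logical(length(universe))))
    trials <- rep(length(sets), length(universe))
  } else {
    assert_that(all(mutated_genes %in% universe),
                "fit_pwv: mutated_genes must be a subset of the universe")
    succ <- as.numeric(universe %in% mutated_genes)
    trials <- rep(1, length(universe))
  }
  tot_succ <- sum(succ); tot_trials <- sum(trials)
  if (tot_succ == 0 || tot_succ == tot_trials)
    stop_value("fit_pwv: degenerate fit (all or no genes mutated)")
  pbar <- tot_succ / tot_trials

  if (diff(range(len)) == 0) {
    w <- rep(pbar, length(universe))
  } else {
    knots <- unique(stats::quantile(len, probs = (1:6) / 7))
    basis <- splines::ns(len, knots = knots)
    fit <- suppressWarnings(
      stats::glm(cbind(succ, trials - succ) ~ basis, family = stats::binomial()))
    p_hat <- stats::fitted(fit)
    ## isotone projection over length order (equal trial weights)
    o <- order(len)
    iso <- stats::isoreg(p_hat[o])$yf
    w <- numeric(length(len))
    w[o] <- iso
    w <- pmin(pmax(w, 1e-12), 1 - 1e-12)
  }
  structure(stats::setNames(w, universe), class = "pwv")
}

#' Weighted resampling frequencies under the PWV null
#'
#' For each replicate and each sample, draws (without replacement) a random
#' gene set of the same size as that sample's observed mutation set, with
#' per-gene selection probability proportional to the PWV. A gene's
#' resampling frequency \code{fre} is the fraction of replicates in which it
#' was drawn, aggregated over samples.
#'
#' With \code{aggregate = "mean"} (default) the per-sample selection
#' frequencies are averaged over samples, so \code{fre} estimates the
#' length-predicted per-sample mutation probability and is directly
#' comparable to the removal threshold. \code{aggregate = "union"} counts a
#' replicate once if the gene appears in any sample's drawn set.
#'
#' @param pwv Weights from \code{\link{fit_pwv}}.
#' @param per_sample_mutations List of per-sample mutated gene sets.
#' @param reps Number of replicates (default 1000).
#' @param seed Integer seed.
#' @param aggregate "mean" (per-sample mean) or "union" (union per replicate).
#' @return List of class \code{resample_result} with elements \code{fre}
#'   (named per-gene frequency in [0, 1]), \code{reps} and \code{aggregate}.
#' @export
resample_frequencies <- function(pwv, per_sample_mutations, reps = 1000L,
                                 seed = 1L, aggregate = c("mean", "union")) {
  aggregate <- match.arg(aggregate)
  assert_that(reps >= 1L, "resample_frequencies: reps must be >= 1")
  genes <- names(pwv)
  n <- length(genes)
  ks <- vapply(per_sample_mutations, function(s) length(intersect(s, genes)), 1L)
  if (any(ks > n))
    stop_value("resample_frequencies: sample mutation count exceeds universe size")
  w <- as.numeric(pwv)
  set.seed(seed)

  if (aggregate == "mean") {
    ## selection frequency depends on the sample only through its draw size,
    ## so draws are shared across samples with equal mutation counts
    kt <- table(ks[ks > 0])
    counts <- matrix(0, n, length(kt))
    kvals <- as.integer(names(kt))
    for (j in seq_along(kvals)) {
      k <- kvals[j]
      cnt <- integer(n)
      for (r in seq_len(reps)) {
        sel <- sample.int(n, k, prob = w)
        cnt[sel] <- cnt[sel] + 1L
      }
      counts[, j] <- cnt / reps
    }
    fre <- as.vector(counts %*% as.numeric(kt)) / length(ks)
  } else {
    cnt <- integer(n)
    for (r in seq_len(reps)) {
      hit <- logical(n)
      for (k in ks[ks > 0]) hit[sample.int(n, k, prob = w)] <- TRUE
      cnt[hit] <- cnt[hit] + 1L
    }
    fre <- cnt / reps
  }
  structure(list(fre = stats::setNames(fre, genes), reps = as.integer(reps),
                 aggregate = aggregate),
            class = "resample_result")
}

#' Remove length-explainable genes by resampling frequency
#'
#' Genes whose \code{fre} strictly exceeds \code{threshold} are treated as
#' explainable by length alone and removed; the remainder is retained as the
#' candidate driver pool. \code{direction = "keep_high"} inverts the rule.
#'
#' @param observed_mutated Character vector of observed mutated genes.
#' @param fre A \code{resample_result} (or named frequency vector).
#' @param threshold Removal threshold on \code{fre} (default 0.05).
#' @param direction "remove_high" (default) or "keep_high".
#' @return Character vector of retained gene ids.
#' @export
filter_by_frequency <- function(observed_mutated, fre, threshold = 0.05,
                                direction = c("remove_high", "keep_high")) {
  direction <- match.arg(direction)
  f <- if (inherits(fre, "resample_result")) fre$fre else fre
  assert_that(all(observed_mutated %in% names(f)),
              "filter_by_frequency: fre must cover all observed mutated genes")
  high <- f[observed_mutated] > threshold
  if (direction == "remove_high") observed_mutated[!high] else observed_mutated[high]
}
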